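# Reduction of a probabilistic motif search to a deterministic k-mer set.
#
# A position probability matrix (PPM) cannot be scored homomorphically at
# practical cost (per-character private value selection would require deep
# circuits), so the motif search is reduced offline: build a PSSM against
# background frequencies, compute the exact null score distribution by
# dynamic programming over discretized scores, enumerate all 4^k k-mers
# with p-values, apply a Benjamini-Hochberg correction, and keep the
# significant k-mers as the exact-match query set for the encrypted search.

ALPHABET <- c("A", "C", "G", "T")

#' Parse motifs from a MEME minimal-format file
#'
#' Reads every `MOTIF` block's letter-probability matrix, plus the
#' file-level background frequencies when present.
#'
#' @param path MEME minimal motif format text file.
#' @return List with `motifs` (a list of `ppm` objects: `motif_id`, `width`,
#'   `matrix` of dimension width x 4 in A,C,G,T order) and `background`
#'   (length-4 numeric or `NULL`).
#' @export
parse_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  background <- NULL
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) > 0 && bg_at[1] < length(lines)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    if (length(toks) >= 8) {
      vals <- suppressWarnings(as.numeric(toks[seq(2, 8, by = 2)]))
      names(vals) <- toks[seq(1, 7, by = 2)]
      background <- unname(vals[ALPHABET])
    }
  }
  motif_at <- grep("^MOTIF\\b", lines)
  if (length(motif_at) == 0) {
    stop("format error: no MOTIF block found in ", path, call. = FALSE)
  }
  motifs <- lapply(motif_at, function(i) {
    id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines)
    hdr <- hdr[hdr > i][1]
    if (is.na(hdr)) {
      stop("format error: MOTIF at line ", i,
           " lacks a letter-probability matrix", call. = FALSE)
    }
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- t(vapply(seq_along(rows), function(ri) {
      vals <- suppressWarnings(
        as.numeric(strsplit(trimws(rows[ri]), "\\s+")[[1]]))
      if (length(vals) != 4 || anyNA(vals)) {
        stop("format error: bad matrix row at line ", hdr + ri, call. = FALSE)
      }
      vals
    }, numeric(4)))
    ppm(mat, motif_id = id)
  })
  list(motifs = motifs, background = background)
}

#' Construct a position probability matrix object
#'
#' @param matrix A width x 4 matrix of probabilities (columns in A,C,G,T
#'   order; rows sum to 1).
#' @param motif_id Identifier string.
#' @return A `ppm` object.
#' @export
ppm <- function(matrix, motif_id = "motif") {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4) {
    stop("format error: PPM must have 4 columns (A,C,G,T)", call. = FALSE)
  }
  if (any(matrix < 0)) {
    stop("format error: PPM entries must be non-negative", call. = FALSE)
  }
  sums <- rowSums(matrix)
  if (any(abs(sums - 1) > 0.02)) {
    stop("format error: PPM row ", which(abs(sums - 1) > 0.02)[1],
         " sums to ", round(sums[which(abs(sums - 1) > 0.02)[1]], 3),
         ", expected 1", call. = FALSE)
  }
  colnames(matrix) <- ALPHABET
  structure(list(motif_id = motif_id, width = nrow(matrix),
                 matrix = matrix / sums),
            class = "ppm")
}

#' Build a discretized position-specific scoring matrix
#'
#' Scores are background-normalized log-likelihood ratios in bits,
#' `score(j, b) = log2(((p_jb + pseudocount * bg_b) / (1 + pseudocount)) /
#' bg_b)`, discretized to integers at `scale` bins per bit so the dynamic
#' program over score sums is exact on the discretized scale.
#'
#' @param ppm A [ppm()] object.
#' @param background Length-4 positive probabilities (A,C,G,T), summing
#'   to 1. Default uniform.
#' @param pseudocount Background-weighted pseudocount added to each
#'   probability (guards zeros; default 0.1).
#' @param scale Integer bins per bit of score (default 1000).
#' @return A `pssm` object with real (`scores`) and integer (`int_scores`)
#'   matrices.
#' @export
build_pssm <- function(ppm, background = rep(0.25, 4), pseudocount = 0.1,
                       scale = 1000) {
  stopifnot(inherits(ppm, "ppm"))
  background <- as.numeric(background)
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("configuration error: background must be 4 positive frequencies ",
         "summing to 1", call. = FALSE)
  }
  p <- sweep(ppm$matrix, 2, pseudocount * background, `+`) / (1 + pseudocount)
  scores <- log2(sweep(p, 2, background, `/`))
  int_scores <- round(scores * scale)
  if (any(!is.finite(int_scores))) {
    # zero probabilities at pseudocount 0 give -Inf log-ratios; on the
    # discretized scale they become a floor far below every finite score,
    # so one impossible letter always outranks any attainable threshold
    floor_int <- min(int_scores[is.finite(int_scores)], 0) - 100 * scale
    int_scores[!is.finite(int_scores)] <- floor_int
  }
  structure(list(motif_id = ppm$motif_id, width = ppm$width,
                 scores = scores,
                 int_scores = int_scores,
                 scale = scale, background = background,
                 pseudocount = pseudocount),
            class = "pssm")
}

#' Exact null score distribution by dynamic programming
#'
#' Convolves per-position score distributions under the background model:
#' `D_0 = {0: 1}`; `D_{j+1}[s + score(j, b)] += D_j[s] * bg_b`. Tail
#' probabilities `P(score >= s)` follow by suffix summation, giving an
#' exact p-value for every attainable discretized score.
#'
#' @param pssm A [build_pssm()] object.
#' @return A `score_distribution` object: tibble (`score_int`, `prob`,
#'   `tail_p`) plus lookup bounds.
#' @export
score_distribution <- function(pssm) {
  stopifnot(inherits(pssm, "pssm"))
  S <- pssm$int_scores
  lo <- sum(apply(S, 1, min))
  hi <- sum(apply(S, 1, max))
  width <- hi - lo + 1L
  # D indexed by offset from the running minimum attainable sum
  D <- 1
  cur_lo <- 0L
  for (j in seq_len(pssm$width)) {
    row <- S[j, ]
    rlo <- min(row)
    new_lo <- cur_lo + rlo
    new_len <- length(D) + (max(row) - rlo)
    Dn <- numeric(new_len)
    for (b in 1:4) {
      sh <- row[b] - rlo
      idx <- seq_along(D) + sh
      Dn[idx] <- Dn[idx] + D * pssm$background[b]
    }
    D <- Dn
    cur_lo <- new_lo
  }
  stopifnot(cur_lo == lo, length(D) == width)
  tail_p <- rev(cumsum(rev(D)))
  structure(list(
    table = tibble::tibble(score_int = lo:hi, prob = D, tail_p = tail_p),
    lo = lo, hi = hi, motif_id = pssm$motif_id, scale = pssm$scale
  ), class = "score_distribution")
}

#' Map discretized scores to exact p-values
#'
#' @param dist A [score_distribution()] object.
#' @param score_int Integer score(s) on the distribution's scale.
#' @return `P(score >= score_int)` under the background model (1 below the
#'   attainable range, 0 above it).
#' @export
score_pvalue <- function(dist, score_int) {
  stopifnot(inherits(dist, "score_distribution"))
  idx <- score_int - dist$lo + 1L
  p <- numeric(length(score_int))
  p[idx < 1] <- 1
  p[idx > nrow(dist$table)] <- 0
  inside <- idx >= 1 & idx <= nrow(dist$table)
  p[inside] <- dist$table$tail_p[idx[inside]]
  p
}

#' Enumerate and score every k-mer of the motif's width
#'
#' Iterates all `4^k` k-mers, computing each one's PSSM score and p-value
#' from the precomputed distribution. Enumeration is exponential in `k`;
#' widths above 12 warn and widths above 16 are refused unless forced.
#'
#' @param pssm,dist Matched [build_pssm()] / [score_distribution()] objects.
#' @param force Allow widths above 16.
#' @return Tibble `kmer`, `score` (bits), `score_int`, `p_value`, with
#'   exactly `4^k` rows.
#' @export
enumerate_and_score <- function(pssm, dist, force = FALSE) {
  k <- pssm$width
  if (k > 16 && !force) {
    stop("refusing to enumerate 4^", k,
         " k-mers (width > 16); use force = TRUE", call. = FALSE)
  }
  if (k > 12) {
    warning("enumerating 4^", k, " k-mers; this may take a while")
  }
  n <- 4^k
  idx <- 0:(n - 1)
  score_int <- numeric(n)
  score <- numeric(n)
  letters_by_pos <- vector("list", k)
  for (j in seq_len(k)) {
    digit <- (idx %/% 4^(k - j)) %% 4
    score_int <- score_int + unname(pssm$int_scores[j, digit + 1])
    score <- score + unname(pssm$scores[j, digit + 1])
    letters_by_pos[[j]] <- ALPHABET[digit + 1]
  }
  tibble::tibble(
    kmer = do.call(paste0, letters_by_pos),
    score = score,
    score_int = score_int,
    p_value = score_pvalue(dist, score_int)
  )
}

#' Benjamini-Hochberg correction over the enumerated k-mers
#'
#' Step-up q-values `q_i = min_{j >= i} (m * p_j / j)`, clipped to 1, over
#' records sorted ascending by p-value (ties broken lexicographically by
#' k-mer for reproducibility). The computation is delegated to
#' `stats::p.adjust(method = "BH")`, which implements exactly this formula.
#'
#' @param records Tibble from [enumerate_and_score()], sorted ascending by
#'   `p_value`.
#' @return The records with a `q_value` column appended.
#' @export
bh_correct <- function(records) {
  if (is.unsorted(records$p_value)) {
    stop("internal error: bh_correct expects records sorted by p_value",
         call. = FALSE)
  }
  records$q_value <- stats::p.adjust(records$p_value, method = "BH")
  records
}

#' Filter significant k-mers and write the query set
#'
#' Writes a plain-text k-mer list (one sequence per line, ready as input to
#' [encrypt_queries()]) and a detailed CSV (`kmer,score,p_value,q_value`)
#' for exactly the significant set.
#'
#' @param records Corrected records from [bh_correct()].
#' @param threshold Significance threshold in `(0, 1]`.
#' @param out_prefix Output path prefix; files are
#'   `<prefix>_kmers.txt` and `<prefix>_details.csv`.
#' @param on `"q_value"` (default) or `"p_value"`.
#' @return Tibble of significant records, invisibly; paths in attributes.
#' @export
filter_and_write <- function(records, threshold, out_prefix,
                             on = c("q_value", "p_value")) {
  on <- match.arg(on)
  if (threshold <= 0 || threshold > 1) {
    stop("configuration error: threshold must be in (0, 1]", call. = FALSE)
  }
  sig <- records[records[[on]] <= threshold, , drop = FALSE]
  txt <- paste0(out_prefix, "_kmers.txt")
  csv <- paste0(out_prefix, "_details.csv")
  writeLines(sig$kmer, txt)
  utils::write.csv(
    sig[, c("kmer", "score", "p_value", "q_value")], csv, row.names = FALSE,
    quote = FALSE)
  attr(sig, "kmers_txt") <- txt
  attr(sig, "details_csv") <- csv
  invisible(sig)
}

#' Full PWM-to-k-mer reduction
#'
#' Convenience pipeline: PSSM construction, exact score distribution,
#' `4^k` enumeration, BH correction, significance filtering, and (when
#' `out_prefix` is given) query-set files.
#'
#' @param motif A [ppm()] object or a MEME file path (first motif used).
#' @param background Length-4 background frequencies; defaults to the MEME
#'   file's background, else uniform.
#' @param pseudocount,scale See [build_pssm()].
#' @param threshold,on See [filter_and_write()].
#' @param out_prefix Optional output prefix for the query-set files.
#' @return A `pwm_kmer_scan` object; [tidy()] returns the full record
#'   table, [glance()] a one-row summary.
#' @export
pwm_to_kmers <- function(motif, background = NULL, pseudocount = 0.1,
                         scale = 1000, threshold = 0.05,
                         on = c("q_value", "p_value"), out_prefix = NULL) {
  on <- match.arg(on)
  if (is.character(motif)) {
    parsed <- parse_meme(motif)
    if (is.null(background)) background <- parsed$background
    motif <- parsed$motifs[[1]]
  }
  if (is.null(background)) background <- rep(0.25, 4)
  pssm <- build_pssm(motif, background, pseudocount, scale)
  dist <- score_distribution(pssm)
  records <- enumerate_and_score(pssm, dist)
  records <- dplyr::arrange(records, .data$p_value, .data$kmer)
  records <- bh_correct(records)
  sig <- records[records[[on]] <= threshold, , drop = FALSE]
  files <- NULL
  if (!is.null(out_prefix)) {
    sig <- filter_and_write(records, threshold, out_prefix, on)
    files <- list(kmers_txt = attr(sig, "kmers_txt"),
                  details_csv = attr(sig, "details_csv"))
  }
  structure(list(pssm = pssm, dist = dist, records = records,
                 significant = tibble::as_tibble(sig),
                 threshold = threshold, on = on, files = files),
            class = "pwm_kmer_scan")
}

#' @export
print.pwm_kmer_scan <- function(x, ...) {
  cat("<pwm_kmer_scan>", x$pssm$motif_id, "| width", x$pssm$width, "|",
      nrow(x$records), "k-mers enumerated |", nrow(x$significant),
      "significant at", x$on, "<=", x$threshold, "\n")
  invisible(x)
}

#' @rdname pwm_to_kmers
#' @param x A `pwm_kmer_scan` object.
#' @param ... Unused.
#' @export
tidy.pwm_kmer_scan <- function(x, ...) x$records

#' @rdname pwm_to_kmers
#' @export
glance.pwm_kmer_scan <- function(x, ...) {
  tibble::tibble(
    motif_id = x$pssm$motif_id,
    width = x$pssm$width,
    n_kmers = nrow(x$records),
    n_significant = nrow(x$significant),
    min_p = min(x$records$p_value),
    min_q = min(x$records$q_value),
    threshold = x$threshold,
    on = x$on
  )
}

#' Plaintext PSSM scan of a sequence (reference oracle)
#'
#' Slides the PSSM over a plaintext sequence and reports every
#' forward-strand window whose discretized score reaches `min_score_int`.
#' Used to validate that the significant-k-mer query set recovers exactly
#' the positions a direct thresholded scan would report.
#'
#' @param sequence Character string.
#' @param pssm A [build_pssm()] object.
#' @param min_score_int Threshold on the discretized score.
#' @return Tibble `position` (0-based), `kmer`, `score_int`.
#' @export
scan_pssm <- function(sequence, pssm, min_score_int) {
  k <- pssm$width
  sym <- encode_symbols(sequence)
  n <- length(sym) - k + 1L
  if (n < 1) {
    return(tibble::tibble(position = integer(0), kmer = character(0),
                          score_int = numeric(0)))
  }
  score <- numeric(n)
  valid <- rep(TRUE, n)
  for (j in seq_len(k)) {
    s <- sym[(j):(j + n - 1L)]
    valid <- valid & s < 4L
    score <- score + pssm$int_scores[j, pmin(s, 3L) + 1L]
  }
  hit <- which(valid & score >= min_score_int)
  tibble::tibble(
    position = hit - 1L,
    kmer = vapply(hit, function(i) decode_symbols(sym[i:(i + k - 1L)]),
                  character(1)),
    score_int = score[hit]
  )
}
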