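# Trusted-side pipeline: one-time input encryption, query encryption, result
# decryption and match extraction, Phred quality filtering, and ground-truth
# verification. Everything touching plaintext or the secret key lives here;
# the deployment directory handed to the server holds only ciphertexts,
# geometry metadata, and the public evaluation keys.

.detect_format <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (length(first) == 0) stop("format error: empty input file", call. = FALSE)
  if (startsWith(first, ">")) return("fasta")
  if (startsWith(first, "@")) return("fastq")
  stop("format error: input is neither FASTA nor FASTQ", call. = FALSE)
}

# concatenate FASTA records with k_max-1 pad symbols between them
.concat_fasta <- function(seqs, k_max) {
  pad <- rep(PAD_SYMBOL, k_max - 1L)
  symbols <- integer(0)
  starts <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    starts[i] <- length(symbols)
    symbols <- c(symbols, encode_symbols(seqs[[i]]))
    if (i < length(seqs)) symbols <- c(symbols, pad)
  }
  list(symbols = symbols,
       records = tibble::tibble(name = names(seqs),
                                concat_start = starts,
                                length = nchar(seqs, type = "chars")))
}

# group whole reads into chunks of packed length <= chunk_size; cuts fall in
# pad runs, so no within-read window ever spans two chunks
.plan_fastq_chunks <- function(layout, k_max, chunk_size, total_len) {
  seg_len <- layout$read_length + (k_max - 1L)
  chunks <- list()
  cur_start <- 0L
  cur_len <- 0L
  ci <- 0L
  for (i in seq_len(nrow(layout))) {
    if (cur_len > 0 && cur_len + seg_len[i] > chunk_size) {
      chunks[[length(chunks) + 1L]] <-
        list(chunk_index = ci, start = cur_start, length = cur_len)
      ci <- ci + 1L
      cur_start <- layout$packed_start[i]
      cur_len <- 0L
    }
    cur_len <- cur_len + seg_len[i]
  }
  chunks[[length(chunks) + 1L]] <-
    list(chunk_index = ci, start = cur_start, length = cur_len)
  chunks
}

.stride_file <- function(dir, ci, bi, j, quality = FALSE) {
  file.path(dir, sprintf("c%d_b%d_%s%d.ct", ci, bi,
                         if (quality) "q" else "s", j))
}

#' One-time encryption of a FASTA genome or FASTQ read set
#'
#' Encodes the input as protocol symbols, partitions it into chunks (256 KB
#' overlapping segments for FASTA; whole-read groups with `k_max - 1` pad
#' guards for FASTQ), transposes each chunk into `k_max` stride vectors per
#' SIMD batch, and encrypts every stride into one batched ciphertext. The
#' deployment directory receives the ciphertexts, a JSON manifest of the
#' geometry, and evaluation keys -- but no plaintext and no secret key.
#'
#' @param path FASTA or FASTQ file.
#' @param ctx,keys Context and full key triple ([he_context()],
#'   [he_keygen()]).
#' @param k_max Maximum k-mer length that will ever be queried against this
#'   deployment.
#' @param chunk_size Chunk length in symbols (default 262144 = 256 KB).
#' @param deploy_dir Output directory (created if needed).
#' @param quality_mode One of `"none"`, `"min"`, `"avg"`, `"sum"`. For
#'   `"avg"`/`"sum"` on FASTQ input, Phred qualities are packed into
#'   parallel stride ciphertexts so the server can compute window quality
#'   sums homomorphically; `"min"` needs no extra ciphertexts (it is
#'   resolved by a client-side plaintext scan at decryption time).
#' @param n_workers Encrypt batches in parallel (result is independent of
#'   the worker count).
#' @return The deployment manifest, invisibly.
#' @export
encrypt_input <- function(path, ctx, keys, k_max = 16L,
                          chunk_size = 262144L, deploy_dir,
                          quality_mode = c("none", "min", "avg", "sum"),
                          n_workers = 1L) {
  quality_mode <- match.arg(quality_mode)
  .check_ctx(ctx)
  .check_keys(keys, ctx$id)
  if (k_max < 1) stop("configuration error: k_max must be >= 1", call. = FALSE)
  if (k_max * 16 >= ctx$t) {
    stop("configuration error: k_max * 16 must stay below the plaintext ",
         "modulus (SSD wraparound)", call. = FALSE)
  }
  fmt <- .detect_format(path)
  dir.create(deploy_dir, showWarnings = FALSE, recursive = TRUE)
  chunks_dir <- file.path(deploy_dir, "chunks")
  dir.create(chunks_dir, showWarnings = FALSE)

  quality <- NULL
  if (fmt == "fasta") {
    seqs <- read_fasta(path)
    cc <- .concat_fasta(seqs, k_max)
    symbols <- cc$symbols
    records <- cc$records
    chunks <- chunk_symbols(symbols, chunk_size, k_max)
    src_type <- "fasta"
  } else {
    reads <- read_fastq(path)
    packed <- pack_fastq(reads, k_max)
    symbols <- packed$symbols
    quality <- packed$quality
    records <- tibble::tibble(name = packed$layout$read_id,
                              concat_start = packed$layout$packed_start,
                              length = packed$layout$read_length)
    plan <- .plan_fastq_chunks(packed$layout, k_max, chunk_size,
                               length(symbols))
    chunks <- lapply(plan, function(p) {
      list(chunk_index = p$chunk_index, start = p$start, length = p$length,
           symbols = symbols[(p$start + 1L):(p$start + p$length)])
    })
    src_type <- "fastq"
  }
  want_quality <- src_type == "fastq" && quality_mode %in% c("avg", "sum")

  batch_rows <- list()
  for (ch in chunks) {
    batches <- build_strides(ch$symbols, k_max, ctx$slot_count,
                             chunk_index = ch$chunk_index,
                             chunk_start = ch$start)
    qbatches <- if (want_quality) {
      qs <- quality[(ch$start + 1L):min(ch$start + length(ch$symbols),
                                        length(quality))]
      qs <- c(qs, rep(0L, length(ch$symbols) - length(qs)))
      build_strides(qs, k_max, ctx$slot_count,
                    chunk_index = ch$chunk_index, chunk_start = ch$start,
                    pad_value = 0L)
    }
    worker <- function(b) {
      batch <- batches[[b]]
      for (j in seq_len(k_max)) {
        ct <- he_encrypt(batch$strides[j, ], ctx, keys)
        he_save_cipher(ct, .stride_file(chunks_dir, batch$chunk_index,
                                        batch$batch_index, j - 1L))
      }
      if (want_quality) {
        qb <- qbatches[[b]]
        for (j in seq_len(k_max)) {
          ct <- he_encrypt(qb$strides[j, ], ctx, keys)
          he_save_cipher(ct, .stride_file(chunks_dir, qb$chunk_index,
                                          qb$batch_index, j - 1L,
                                          quality = TRUE))
        }
      }
      NULL
    }
    if (n_workers > 1L) {
      parallel::mclapply(seq_along(batches), worker, mc.cores = n_workers)
    } else {
      lapply(seq_along(batches), worker)
    }
    batch_rows <- c(batch_rows, lapply(batches, function(b) {
      tibble::tibble(chunk_index = b$chunk_index,
                     batch_index = b$batch_index,
                     window_start = b$window_start,
                     n_windows = b$n_windows)
    }))
  }

  he_save_keys(keys, ctx, file.path(deploy_dir, "evalkeys.bin"),
               which = "eval")
  manifest <- list(
    format_version = 1L,
    backend = ctx$backend,
    params = ctx$params[c("poly_degree", "plain_modulus", "coeff_bits",
                          "security_bits")],
    k_max = as.integer(k_max),
    chunk_size = as.integer(chunk_size),
    quality_strides = want_quality,
    source = list(type = src_type,
                  digest = unname(tools::md5sum(path))),
    records = dplyr::bind_rows(records),
    batches = dplyr::bind_rows(batch_rows)
  )
  .track_io(jsonlite::write_json(manifest,
                                 file.path(deploy_dir, "manifest.json"),
                                 auto_unbox = TRUE, digits = NA,
                                 pretty = TRUE))
  invisible(manifest)
}

#' Read a deployment or query manifest back as typed tibbles
#' @param dir Deployment or queries directory.
#' @return The manifest list with `records` and `batches` as tibbles.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) {
    stop("missing manifest: ", path, call. = FALSE)
  }
  m <- .track_io(jsonlite::read_json(path, simplifyVector = TRUE))
  if (!is.null(m$records)) m$records <- tibble::as_tibble(m$records)
  if (!is.null(m$batches)) m$batches <- tibble::as_tibble(m$batches)
  if (!is.null(m$queries)) m$queries <- tibble::as_tibble(m$queries)
  m
}

#' Encrypt a k-mer query set
#'
#' Each of the `k` characters of a query is encrypted into its own
#' ciphertext with the character's encoded value replicated across all SIMD
#' slots, so one homomorphic subtraction aligns the character against every
#' window position at once.
#'
#' @param kmers Character vector of queries over A/C/G/T, each of length at
#'   most `k_max`.
#' @param ctx,keys Context and keys.
#' @param k_max The deployment's maximum k-mer length.
#' @param queries_dir Output directory.
#' @return The query manifest (tibble `query_id`, `seq`, `k`), invisibly.
#' @export
encrypt_queries <- function(kmers, ctx, keys, k_max, queries_dir) {
  .check_ctx(ctx)
  .check_keys(keys, ctx$id)
  kmers <- toupper(kmers)
  bad <- grepl("[^ACGT]", kmers)
  if (any(bad)) {
    stop("query error: k-mers must be over {A,C,G,T} (got ",
         kmers[which(bad)[1]], ")", call. = FALSE)
  }
  if (any(nchar(kmers) > k_max)) {
    stop("query error: k-mer longer than k_max = ", k_max, call. = FALSE)
  }
  if (any(nchar(kmers) < 1)) {
    stop("query error: empty k-mer", call. = FALSE)
  }
  dir.create(queries_dir, showWarnings = FALSE, recursive = TRUE)
  queries <- tibble::tibble(query_id = paste0("q", seq_along(kmers)),
                            seq = kmers, k = nchar(kmers))
  for (i in seq_along(kmers)) {
    sym <- encode_symbols(kmers[i])
    for (j in seq_along(sym)) {
      ct <- he_encrypt(rep(sym[j], ctx$slot_count), ctx, keys)
      he_save_cipher(ct, file.path(queries_dir,
                                   sprintf("%s_j%d.ct", queries$query_id[i],
                                           j - 1L)))
    }
  }
  .track_io(jsonlite::write_json(list(format_version = 1L, queries = queries),
                                 file.path(queries_dir, "manifest.json"),
                                 auto_unbox = TRUE, digits = NA,
                                 pretty = TRUE))
  invisible(queries)
}

.result_file <- function(results_dir, qid, ci, bi, quality = FALSE) {
  file.path(results_dir, sprintf("%s_c%d_b%d%s.bin", qid, ci, bi,
                                 if (quality) "_qual" else ""))
}

#' Decrypt server results and extract match records
#'
#' Decrypts every (query, batch) result vector, identifies slots equal to
#' zero among the batch's valid windows, maps each such slot back through
#' the chunk/batch geometry to a record coordinate or `(read, offset)`
#' pair, and deduplicates windows seen through two overlapping chunks. When
#' the server also produced window quality sums, `sum_q`/`avg_q` are
#' attached.
#'
#' @param results_dir Directory written by [process_all()].
#' @param deploy_dir,queries_dir The client-populated directories.
#' @param ctx,keys Context and full keys (the secret key is required).
#' @return A tibble with columns `query_id`, `query_seq`, `k`,
#'   `source_record`, `position` (0-based), `ssd`, `min_q`, `avg_q`,
#'   `sum_q`, `pass_filter`.
#' @export
decrypt_and_extract <- function(results_dir, deploy_dir, queries_dir,
                                ctx, keys) {
  .check_ctx(ctx)
  .check_keys(keys, ctx$id, need_secret = TRUE)
  manifest <- read_manifest(deploy_dir)
  queries <- read_manifest(queries_dir)$queries
  empty_records <- tibble::tibble(
    query_id = character(0), query_seq = character(0), k = integer(0),
    source_record = character(0), position = integer(0), ssd = numeric(0),
    min_q = numeric(0), avg_q = numeric(0), sum_q = numeric(0),
    pass_filter = logical(0))
  if (is.null(queries) || nrow(queries) == 0) return(empty_records)
  b <- manifest$batches
  expected <- tidyr::crossing(qid = queries$query_id,
                              dplyr::select(b, "chunk_index", "batch_index"))
  files <- .result_file(results_dir, expected$qid, expected$chunk_index,
                        expected$batch_index)
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    stop("incomplete-results error: missing ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (qi in seq_len(nrow(queries))) {
    qid <- queries$query_id[qi]
    k <- queries$k[qi]
    for (bi in seq_len(nrow(b))) {
      ct <- he_load_cipher(.result_file(results_dir, qid, b$chunk_index[bi],
                                        b$batch_index[bi]), ctx)
      vals <- he_decrypt(ct, ctx, keys)
      zero_slots <- which(vals == 0 & seq_along(vals) <= b$n_windows[bi]) - 1L
      if (length(zero_slots) == 0) next
      qual_path <- .result_file(results_dir, qid, b$chunk_index[bi],
                                b$batch_index[bi], quality = TRUE)
      sums <- if (file.exists(qual_path)) {
        he_decrypt(he_load_cipher(qual_path, ctx), ctx, keys)
      }
      pos <- b$window_start[bi] + zero_slots
      rows[[length(rows) + 1L]] <- tibble::tibble(
        query_id = qid, query_seq = queries$seq[qi], k = k,
        position = as.integer(pos),
        ssd = 0,
        sum_q = if (is.null(sums)) NA_real_ else sums[zero_slots + 1L]
      )
    }
  }
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) {
    return(tibble::tibble(query_id = character(0), query_seq = character(0),
                          k = integer(0), source_record = character(0),
                          position = integer(0), ssd = numeric(0),
                          min_q = numeric(0), avg_q = numeric(0),
                          sum_q = numeric(0), pass_filter = logical(0)))
  }
  res <- dplyr::distinct(res, .data$query_id, .data$position,
                         .keep_all = TRUE)
  src <- purrr::map2_dfr(res$position, res$k, function(p, k) {
    map_coordinate_to_source(manifest, p, k)
  })
  res$source_record <- src$record
  res$position <- src$offset
  res <- dplyr::filter(res, !is.na(.data$source_record))
  dplyr::transmute(
    res,
    query_id = .data$query_id, query_seq = .data$query_seq, k = .data$k,
    source_record = .data$source_record, position = .data$position,
    ssd = .data$ssd, min_q = NA_real_,
    avg_q = .data$sum_q / .data$k, sum_q = .data$sum_q,
    pass_filter = NA
  )
}

#' Phred-quality filtering of FASTQ match records
#'
#' Three modes over the `k` bases of each match: `"min"` requires every
#' base to reach the threshold and is computed by a client-side scan of the
#' plaintext qualities (a non-linear aggregate the server cannot evaluate
#' at depth 1); `"sum"` keeps matches whose window quality sum reaches the
#' threshold; `"avg"` keeps matches with mean quality at or above the
#' threshold, compared in integer arithmetic as
#' `sum >= ceiling(k * threshold)`. Sums come from the server's homomorphic
#' window sums when present, otherwise from the plaintext qualities.
#'
#' @param records Match records from [decrypt_and_extract()].
#' @param mode `"min"`, `"avg"`, or `"sum"`.
#' @param threshold Quality threshold (Phred units; per-base for
#'   `"min"`/`"avg"`, total for `"sum"`).
#' @param reads Tibble `read_id`, `sequence`, `quality` (or a FASTQ path);
#'   required for `"min"` and as fallback for the other modes.
#' @param keep_all Return all records annotated with `pass_filter` instead
#'   of survivors only.
#' @return Filtered (or annotated) match records.
#' @export
filter_by_quality <- function(records, mode = c("min", "avg", "sum"),
                              threshold, reads = NULL, keep_all = FALSE) {
  mode <- match.arg(mode)
  if (nrow(records) == 0) {
    records$pass_filter <- logical(0)
    return(records)
  }
  if (is.character(reads)) reads <- read_fastq(reads)
  need_plain <- mode == "min" || all(is.na(records$sum_q))
  if (need_plain && is.null(reads)) {
    stop("configuration error: '", mode, "' filtering needs plaintext ",
         "qualities (supply `reads`)", call. = FALSE)
  }
  if (!is.null(reads)) {
    qual_of <- stats::setNames(reads$quality, reads$read_id)
    window_q <- purrr::pmap(list(records$source_record, records$position,
                                 records$k), function(r, p, k) {
      utf8ToInt(substr(qual_of[[r]], p + 1L, p + k)) - 33L
    })
    records$min_q <- purrr::map_dbl(window_q, min)
    plain_sum <- purrr::map_dbl(window_q, sum)
    records$sum_q <- ifelse(is.na(records$sum_q), plain_sum, records$sum_q)
    records$avg_q <- records$sum_q / records$k
  }
  records$pass_filter <- switch(
    mode,
    min = records$min_q >= threshold,
    sum = records$sum_q >= threshold,
    avg = records$sum_q >= ceiling(records$k * threshold)
  )
  if (keep_all) records else dplyr::filter(records, .data$pass_filter)
}

#' Verify encrypted-search results against a plaintext ground truth
#'
#' Runs an independent plaintext search ([naive_kmer_search()]) over the
#' original input and compares the match sets. A correct build reports zero
#' discrepancies; the check requires plaintext access and is therefore
#' opt-in.
#'
#' @param path Original FASTA/FASTQ input.
#' @param kmers The plaintext query k-mers.
#' @param records Match records from [decrypt_and_extract()].
#' @return List with `ok`, `false_positives`, `false_negatives`, and a
#'   `per_query` count table.
#' @export
verify_against_plaintext <- function(path, kmers, records) {
  fmt <- .detect_format(path)
  seqs <- if (fmt == "fasta") {
    read_fasta(path)
  } else {
    r <- read_fastq(path)
    stats::setNames(r$sequence, r$read_id)
  }
  truth <- naive_kmer_search(seqs, kmers)
  got <- dplyr::distinct(tibble::tibble(
    query_seq = records$query_seq %||% character(0),
    record = records$source_record %||% character(0),
    position = records$position %||% integer(0)
  ))
  fp <- dplyr::anti_join(got, truth,
                         by = c("query_seq", "record", "position"))
  fn <- dplyr::anti_join(truth, got,
                         by = c("query_seq", "record", "position"))
  per_query <- dplyr::full_join(
    dplyr::count(truth, .data$query_seq, name = "n_expected"),
    dplyr::count(got, .data$query_seq, name = "n_found"),
    by = "query_seq"
  )
  per_query[is.na(per_query)] <- 0L
  list(ok = nrow(fp) == 0 && nrow(fn) == 0,
       false_positives = fp, false_negatives = fn, per_query = per_query)
}

#' Write match records as a results TSV
#' @param records Match records tibble.
#' @param path Output path.
#' @param one_based Also emit a human-readable 1-based position column.
#' @export
write_results_tsv <- function(records, path, one_based = FALSE) {
  out <- records
  if (one_based) out$position_1based <- out$position + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
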