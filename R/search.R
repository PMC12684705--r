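# One-shot orchestration of the full protocol: keygen -> one-time input
# encryption -> query encryption -> untrusted evaluation -> decryption and
# match extraction, with per-phase timing and optional plaintext
# verification. Staged use (separate client/server invocations over a
# shared filesystem) goes through the individual functions or the CLI; this
# wrapper composes exactly those stages.

#' Private exact k-mer search over an encrypted genome or read set
#'
#' @param input Path to a FASTA or FASTQ file.
#' @param queries Character vector of k-mers (A/C/G/T), or a path to a
#'   plain-text k-mer list such as the one written by [pwm_to_kmers()].
#' @param backend `"clear"` (reference arithmetic oracle) or `"bgv"` (real
#'   lattice encryption).
#' @param params A [crypto_params()] object; defaults to the standard
#'   degree-8192 profile.
#' @param k_max Maximum queryable k-mer length the deployment is encrypted
#'   for.
#' @param chunk_size Chunk length in symbols.
#' @param quality_mode `"none"`, `"min"`, `"avg"` or `"sum"` (FASTQ only).
#' @param quality_threshold Threshold for the chosen quality mode.
#' @param workdir Directory for the deploy/queries/results tree; a
#'   temporary directory by default.
#' @param seed Optional seed for key generation and encryption randomness.
#' @param n_workers Parallel workers for encryption and evaluation.
#' @param verify Also run the plaintext ground-truth comparison (requires
#'   plaintext access; intended for validation, not production).
#' @return A `kmer_search_result`: `matches` (tibble), `phases` (timing
#'   report), `verification` (or `NULL`), `dirs`.
#' @examples
#' \donttest{
#' fa <- tempfile(fileext = ".fa")
#' make_genome(2000, plants = data.frame(seq = "ACGTACGTACGT", position = 100),
#'             path = fa, seed = 7)
#' res <- kmer_search(fa, c("ACGTACGTACGT", "TTTTTTTT"),
#'                    params = crypto_params(poly_degree = 1024),
#'                    backend = "clear", seed = 7)
#' res$matches
#' }
#' @export
kmer_search <- function(input, queries, backend = c("clear", "bgv"),
                        params = NULL, k_max = 16L, chunk_size = 262144L,
                        quality_mode = c("none", "min", "avg", "sum"),
                        quality_threshold = NULL, workdir = NULL,
                        seed = NULL, n_workers = 1L, verify = FALSE) {
  backend <- match.arg(backend)
  quality_mode <- match.arg(quality_mode)
  if (is.null(params)) params <- crypto_params()
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (length(queries) == 1 && file.exists(queries) &&
      !grepl("^[ACGTacgt]+$", queries)) {
    queries <- readLines(queries, warn = FALSE)
    queries <- queries[nzchar(queries)]
  }
  workdir <- workdir %||% tempfile("cryptomer")
  dirs <- list(deploy = file.path(workdir, "deploy"),
               queries = file.path(workdir, "queries"),
               results = file.path(workdir, "results"))
  ctx <- he_context(params, backend)
  keys <- he_keygen(ctx)

  enc <- timed_phase("encrypt", {
    encrypt_input(input, ctx, keys, k_max = k_max, chunk_size = chunk_size,
                  deploy_dir = dirs$deploy, quality_mode = quality_mode,
                  n_workers = n_workers)
    encrypt_queries(queries, ctx, keys, k_max, dirs$queries)
  })
  ev <- timed_phase("evaluate", {
    process_all(dirs$deploy, dirs$queries, dirs$results,
                n_workers = n_workers)
  })
  dec <- timed_phase("decrypt", {
    decrypt_and_extract(dirs$results, dirs$deploy, dirs$queries, ctx, keys)
  })
  matches <- dec$result
  if (quality_mode != "none" && nrow(matches) > 0 &&
      .detect_format(input) == "fastq") {
    matches <- filter_by_quality(matches, mode = quality_mode,
                                 threshold = quality_threshold,
                                 reads = input, keep_all = TRUE)
  }
  verification <- NULL
  if (verify) {
    # ground truth concerns exact matching; quality filtering only annotates
    verification <- verify_against_plaintext(input, queries, matches)
  }
  structure(
    list(matches = matches,
         phases = phase_report(list(enc$report, ev$report, dec$report)),
         verification = verification,
         dirs = dirs, backend = backend, k_max = k_max,
         n_queries = length(queries)),
    class = "kmer_search_result"
  )
}

#' @export
print.kmer_search_result <- function(x, ...) {
  cat("<kmer_search_result>", x$backend, "backend |", x$n_queries,
      "queries |", nrow(x$matches), "matches\n")
  if (!is.null(x$verification)) {
    cat("  verification:",
        if (x$verification$ok) "OK (no discrepancies)" else
          paste(nrow(x$verification$false_positives), "FP,",
                nrow(x$verification$false_negatives), "FN"), "\n")
  }
  invisible(x)
}

#' Tidiers for search results
#'
#' `tidy()` returns the match records; `glance()` a one-row summary with
#' phase timings.
#'
#' @param x A `kmer_search_result`.
#' @param ... Unused.
#' @export
tidy.kmer_search_result <- function(x, ...) x$matches

#' @rdname tidy.kmer_search_result
#' @export
glance.kmer_search_result <- function(x, ...) {
  tibble::tibble(
    backend = x$backend,
    n_queries = x$n_queries,
    n_matches = nrow(x$matches),
    verified_ok = if (is.null(x$verification)) NA else x$verification$ok,
    encrypt_s = x$phases$wall_s[x$phases$phase == "encrypt"],
    evaluate_s = x$phases$wall_s[x$phases$phase == "evaluate"],
    decrypt_s = x$phases$wall_s[x$phases$phase == "decrypt"]
  )
}

#' Plot match positions along their source records
#'
#' @param object A `kmer_search_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kmer_search_result <- function(object, ...) {
  m <- object$matches
  if (nrow(m) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no matches") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(m, ggplot2::aes(x = .data$position,
                                  y = .data$source_record,
                                  colour = .data$query_seq)) +
    ggplot2::geom_point(shape = 124, size = 4) +
    ggplot2::labs(x = "position (0-based)", y = NULL, colour = "query") +
    ggplot2::theme_minimal()
}

#' Plot a motif score distribution and its significance region
#'
#' @param object A `score_distribution`.
#' @param ... Unused.
#' @return A ggplot of tail probability against discretized score.
#' @export
autoplot.score_distribution <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$score_int / object$scale,
                               y = .data$tail_p)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "PSSM score (bits)",
                  y = "P(score >= s) under background") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
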