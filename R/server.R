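# Untrusted-side evaluator. Touches only ciphertexts, geometry metadata and
# the public evaluation keys; the code path has no access to plaintext
# inputs, plaintext queries, or the secret key.

#' Homomorphic sum-of-squared-differences for one (batch, query) pair
#'
#' For a query of length `k`, iterates j = 0..k-1: subtracts the j-th
#' encrypted query character from the j-th genome stride ciphertext,
#' squares the difference (with immediate relinearization), and adds it to
#' an accumulating sum. Slot `i` of the result decrypts to
#' `sum_j (C[i+j] - K[j])^2`, which is zero iff the window equals the
#' query. Only the first `k` strides are touched, and the circuit has
#' multiplicative depth exactly one.
#'
#' @param stride_cts List of at least `k` stride `cipher_vec`s (stride j at
#'   index j+1).
#' @param query_cts List of `k` constant-slot query `cipher_vec`s.
#' @param keys Evaluation keys (relinearization material only).
#' @return A `cipher_vec` encrypting the per-window SSD vector.
#' @export
evaluate_ssd <- function(stride_cts, query_cts, keys) {
  k <- length(query_cts)
  if (k < 1) stop("evaluation error: empty query", call. = FALSE)
  if (length(stride_cts) < k) {
    stop("evaluation error: query length ", k, " exceeds available strides ",
         length(stride_cts), call. = FALSE)
  }
  acc <- NULL
  for (j in seq_len(k)) {
    d <- he_sub(stride_cts[[j]], query_cts[[j]])
    sq <- he_square_relin(d, keys)
    acc <- if (is.null(acc)) sq else he_add(acc, sq)
  }
  acc
}

#' Homomorphic window quality sums
#'
#' Adds the first `k` quality stride ciphertexts, so slot `i` decrypts to
#' the sum of Phred qualities over the window's `k` bases. Additions only:
#' zero multiplicative depth.
#'
#' @param quality_cts List of at least `k` quality stride `cipher_vec`s.
#' @param k Window length.
#' @return A `cipher_vec` of window quality sums.
#' @export
evaluate_quality_sum <- function(quality_cts, k) {
  if (length(quality_cts) < k) {
    stop("configuration error: quality strides absent or fewer than k",
         call. = FALSE)
  }
  Reduce(he_add, quality_cts[seq_len(k)])
}

#' Evaluate all (batch, query) pairs of a deployment
#'
#' Reads the deployment and query manifests, checks completeness of the
#' inputs, evaluates the SSD ciphertext for every (batch, query) pair (and
#' window quality sums where the deployment carries quality strides), and
#' writes one result file per pair plus a completion manifest with
#' per-phase timings. Output content is independent of `n_workers` and of
#' processing order; reruns overwrite results idempotently.
#'
#' @param deploy_dir,queries_dir Directories populated by the client.
#' @param results_dir Output directory (created if needed).
#' @param n_workers Number of parallel workers over batches.
#' @return The completion manifest, invisibly.
#' @export
process_all <- function(deploy_dir, queries_dir, results_dir,
                        n_workers = 1L) {
  manifest <- read_manifest(deploy_dir)
  qman <- read_manifest(queries_dir)
  queries <- qman$queries
  params <- do.call(crypto_params, manifest$params)
  ctx <- he_context(params, backend = manifest$backend)
  keys <- he_load_keys(file.path(deploy_dir, "evalkeys.bin"), ctx)
  chunks_dir <- file.path(deploy_dir, "chunks")
  b <- manifest$batches
  k_max <- manifest$k_max
  if (is.null(queries) || nrow(queries) == 0) {
    dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)
    completion <- list(format_version = 1L, n_queries = 0L,
                       n_batches = nrow(b), outputs = character(0),
                       timings = list(wall_s = 0, io_s = 0, compute_s = 0,
                                      peak_rss_mb = peak_rss_kb() / 1024))
    .track_io(jsonlite::write_json(completion,
                                   file.path(results_dir, "manifest.json"),
                                   auto_unbox = TRUE, digits = NA,
                                   pretty = TRUE))
    return(invisible(completion))
  }

  # completeness check before any work
  need <- character(0)
  for (bi in seq_len(nrow(b))) {
    need <- c(need, .stride_file(chunks_dir, b$chunk_index[bi],
                                 b$batch_index[bi], seq_len(k_max) - 1L))
  }
  for (qi in seq_len(nrow(queries))) {
    need <- c(need, file.path(queries_dir,
                              sprintf("%s_j%d.ct", queries$query_id[qi],
                                      seq_len(queries$k[qi]) - 1L)))
  }
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    stop("partial deployment: missing ",
         paste(utils::head(basename(missing), 10), collapse = ", "),
         if (length(missing) > 10) " ..." else "", call. = FALSE)
  }

  dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)
  query_cts <- lapply(seq_len(nrow(queries)), function(qi) {
    lapply(seq_len(queries$k[qi]), function(j) {
      he_load_cipher(file.path(queries_dir,
                               sprintf("%s_j%d.ct", queries$query_id[qi],
                                       j - 1L)), ctx)
    })
  })

  eval_batch <- function(bi) {
    ci <- b$chunk_index[bi]
    bix <- b$batch_index[bi]
    max_k <- max(queries$k)
    strides <- lapply(seq_len(max_k), function(j) {
      he_load_cipher(.stride_file(chunks_dir, ci, bix, j - 1L), ctx)
    })
    qstrides <- NULL
    if (isTRUE(manifest$quality_strides)) {
      qstrides <- lapply(seq_len(max_k), function(j) {
        he_load_cipher(.stride_file(chunks_dir, ci, bix, j - 1L,
                                    quality = TRUE), ctx)
      })
    }
    outs <- character(0)
    for (qi in seq_len(nrow(queries))) {
      k <- queries$k[qi]
      res <- evaluate_ssd(strides, query_cts[[qi]], keys)
      f <- .result_file(results_dir, queries$query_id[qi], ci, bix)
      he_save_cipher(res, f)
      outs <- c(outs, basename(f))
      if (!is.null(qstrides)) {
        qs <- evaluate_quality_sum(qstrides, k)
        fq <- .result_file(results_dir, queries$query_id[qi], ci, bix,
                           quality = TRUE)
        he_save_cipher(qs, fq)
        outs <- c(outs, basename(fq))
      }
    }
    outs
  }

  timed <- timed_phase("evaluate", {
    if (n_workers > 1L) {
      parallel::mclapply(seq_len(nrow(b)), eval_batch, mc.cores = n_workers)
    } else {
      lapply(seq_len(nrow(b)), eval_batch)
    }
  })
  completion <- list(
    format_version = 1L,
    n_queries = nrow(queries),
    n_batches = nrow(b),
    outputs = sort(unlist(timed$result)),
    timings = as.list(timed$report[1, c("wall_s", "io_s", "compute_s",
                                        "peak_rss_mb")])
  )
  .track_io(jsonlite::write_json(completion,
                                 file.path(results_dir, "manifest.json"),
                                 auto_unbox = TRUE, digits = NA,
                                 pretty = TRUE))
  invisible(completion)
}
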