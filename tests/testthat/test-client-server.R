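# Protocol tests: deployment geometry, SSD semantics, end-to-end match
# extraction against the plaintext oracle, quality filtering, determinism,
# error surfaces, and server-side privacy hygiene. Protocol logic runs on
# the clear backend (the deterministic oracle); dedicated tests cross-check
# the lattice backend elsewhere.

local_pipeline <- function(genome_length = 3000, plants = NULL, queries,
                           k_max = 16L, chunk_size = 262144L,
                           backend = "clear", params = toy_params(),
                           seed = 7, ...) {
  fa <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  make_genome(genome_length, plants = plants, path = fa, seed = seed)
  kmer_search(fa, queries, backend = backend, params = params, k_max = k_max,
              chunk_size = chunk_size, seed = seed, verify = TRUE, ...)
}

test_that("deployment geometry: batches x k_max stride ciphertexts, no plaintext, no secret key", {
  fa <- withr::local_tempfile(fileext = ".fa")
  make_genome(1024, path = fa, seed = 1)
  ctx <- clear_ctx()
  keys <- he_keygen(ctx, seed = 1)
  deploy <- withr::local_tempdir()
  k_max <- 16L
  m <- encrypt_input(fa, ctx, keys, k_max = k_max, deploy_dir = deploy)
  # 1024 symbols +15 tail pads -> 1024 windows -> 1 batch of 1024 slots
  expect_equal(nrow(m$batches), 1L)
  cts <- list.files(file.path(deploy, "chunks"), pattern = "\\.ct$")
  expect_length(cts, nrow(m$batches) * k_max)
  # artifact audit: no plaintext sequence files, and keys are eval-only
  expect_false(any(grepl("\\.(fa|fasta|fastq|txt)$",
                         list.files(deploy, recursive = TRUE))))
  ek <- he_load_keys(file.path(deploy, "evalkeys.bin"), ctx)
  expect_false(ek$has_secret)
})

test_that("evaluate_ssd computes the per-window sum of squared differences at depth 1", {
  ctx <- clear_ctx()
  keys <- he_keygen(ctx, seed = 2)
  sym <- encode_symbols("ACGTACGTTT")
  k <- 4L
  batch <- build_strides(sym, k_max = k, slot_count = ctx$slot_count)[[1]]
  strides <- lapply(seq_len(k), function(j)
    he_encrypt(batch$strides[j, ], ctx, keys))
  enc_query <- function(q) {
    lapply(encode_symbols(q), function(s)
      he_encrypt(rep(s, ctx$slot_count), ctx, keys))
  }
  res <- evaluate_ssd(strides, enc_query("ACGA"), keys)
  vals <- he_decrypt(res, ctx, keys)
  # window "ACGT" vs query "ACGA": (3-0)^2 = 9
  expect_equal(vals[1], 9)
  expect_equal(vals[seq_len(batch$n_windows)],
               ssd_oracle(sym, encode_symbols("ACGA")))
  expect_equal(he_mult_depth(res), 1L)
  expect_equal(res$size, 2L)

  # exact match yields zero; padded slots never do
  res2 <- he_decrypt(evaluate_ssd(strides, enc_query("ACGT"), keys),
                     ctx, keys)
  expect_equal(which(res2[seq_len(batch$n_windows)] == 0), c(1, 5))
  expect_true(all(res2[(batch$n_windows + 1):ctx$slot_count] >= 1))
})

test_that("end-to-end match sets equal the naive plaintext search, including chunk overlaps", {
  # plant sits astride the chunk boundary at position 120 (chunk size 128)
  res <- local_pipeline(
    genome_length = 400,
    plants = data.frame(seq = "ACGTTTGCAC", position = c(20, 118)),
    queries = c("ACGTTTGCAC", "GGGGGGGG"),
    k_max = 8 + 4, chunk_size = 128, seed = 13
  )
  expect_true(res$verification$ok)
  # the overlap-straddling occurrence is reported exactly once
  expect_equal(sum(res$matches$position == 118), 1L)
})

test_that("multi-record FASTA coordinates are per-record and never cross records", {
  fa <- withr::local_tempfile(fileext = ".fa")
  g1 <- make_genome(200, plants = data.frame(seq = "TTACGGAT", position = 190),
                    seed = 5)
  g2 <- make_genome(150, plants = data.frame(seq = "TTACGGAT", position = 3),
                    seed = 6)
  writeLines(c(">recA", g1$sequence, ">recB", g2$sequence), fa)
  res <- kmer_search(fa, "TTACGGAT", backend = "clear",
                     params = toy_params(), k_max = 10, verify = TRUE)
  expect_true(res$verification$ok)
  expect_setequal(
    paste(res$matches$source_record, res$matches$position),
    c("recA 190", "recB 3"))
})

test_that("query validation rejects bad alphabets, lengths, and k > k_max", {
  ctx <- clear_ctx()
  keys <- he_keygen(ctx)
  qdir <- withr::local_tempdir()
  expect_error(encrypt_queries("ACN", ctx, keys, 8, qdir), "query error")
  expect_error(encrypt_queries("ACGTACGTA", ctx, keys, 8, qdir),
               "longer than k_max")
  expect_error(encrypt_queries("", ctx, keys, 8, qdir), "query error")
  q <- encrypt_queries("ACG", ctx, keys, 8, qdir)
  ct <- he_load_cipher(file.path(qdir, "q1_j2.ct"), ctx)
  expect_true(all(he_decrypt(ct, ctx, keys) == 2))
})

test_that("missing inputs and missing results raise actionable errors", {
  fa <- withr::local_tempfile(fileext = ".fa")
  make_genome(500, path = fa, seed = 3)
  ctx <- clear_ctx()
  keys <- he_keygen(ctx, seed = 3)
  dirs <- list(deploy = withr::local_tempdir(),
               queries = withr::local_tempdir(),
               results = withr::local_tempdir())
  encrypt_input(fa, ctx, keys, k_max = 8, deploy_dir = dirs$deploy)
  encrypt_queries(c("ACGT", "GGTT"), ctx, keys, 8, dirs$queries)

  # partial deployment: a deleted stride aborts the server before any work
  victim <- file.path(dirs$deploy, "chunks", "c0_b0_s3.ct")
  file.rename(victim, paste0(victim, ".bak"))
  expect_error(process_all(dirs$deploy, dirs$queries, dirs$results),
               "partial deployment.*c0_b0_s3")
  file.rename(paste0(victim, ".bak"), victim)

  process_all(dirs$deploy, dirs$queries, dirs$results)
  # a deleted result file is named in the incomplete-results error
  unlink(file.path(dirs$results, "q2_c0_b0.bin"))
  expect_error(
    decrypt_and_extract(dirs$results, dirs$deploy, dirs$queries, ctx, keys),
    "incomplete-results.*q2_c0_b0")
})

test_that("server output is independent of worker count and rerun-idempotent", {
  fa <- withr::local_tempfile(fileext = ".fa")
  make_genome(2500, plants = data.frame(seq = "ACGGTTCA"), path = fa,
              seed = 17)
  ctx <- clear_ctx()
  keys <- he_keygen(ctx, seed = 17)
  deploy <- withr::local_tempdir()
  qdir <- withr::local_tempdir()
  encrypt_input(fa, ctx, keys, k_max = 8, deploy_dir = deploy)
  encrypt_queries(c("ACGGTTCA", "TTTT", "CCAG"), ctx, keys, 8, qdir)
  extract <- function(n_workers) {
    rdir <- withr::local_tempdir(.local_envir = parent.frame())
    process_all(deploy, qdir, rdir, n_workers = n_workers)
    decrypt_and_extract(rdir, deploy, qdir, ctx, keys)
  }
  r1 <- extract(1)
  r2 <- extract(2)
  expect_equal(r1, r2)
  # rerun into the same directory overwrites and refreshes the manifest
  rdir <- withr::local_tempdir()
  m1 <- process_all(deploy, qdir, rdir)
  m2 <- process_all(deploy, qdir, rdir)
  expect_equal(m1$outputs, m2$outputs)
  expect_equal(r1, decrypt_and_extract(rdir, deploy, qdir, ctx, keys))
})

test_that("server runs without plaintext, secret keys, or query plaintext present", {
  fa <- withr::local_tempfile(fileext = ".fa")
  g <- make_genome(800, plants = data.frame(seq = "ACCGGTTA", position = 321),
                   path = fa, seed = 19)
  ctx <- bgv_ctx()
  keys <- he_keygen(ctx, seed = 19)
  deploy <- withr::local_tempdir()
  qdir <- withr::local_tempdir()
  rdir <- withr::local_tempdir()
  encrypt_input(fa, ctx, keys, k_max = 8, deploy_dir = deploy)
  encrypt_queries("ACCGGTTA", ctx, keys, 8, qdir)
  unlink(fa)  # the plaintext is gone before the server ever runs
  # server-visible directories hold no secret key material
  for (d in c(deploy, qdir)) {
    for (f in list.files(d, recursive = TRUE, full.names = TRUE)) {
      if (grepl("evalkeys", f)) {
        expect_false(he_load_keys(f, ctx)$has_secret)
      }
    }
  }
  process_all(deploy, qdir, rdir)
  rec <- decrypt_and_extract(rdir, deploy, qdir, ctx, keys)
  expect_true(321L %in% rec$position)
})

test_that("FASTQ pipeline: matches stay within reads and quality filters mirror plaintext", {
  fq <- withr::local_tempfile(fileext = ".fq")
  set.seed(23)
  r <- make_reads(30, 50,
                  plants = data.frame(seq = "ACGTTGCAAT",
                                      read = c(2, 9, 20),
                                      offset = c(0, 17, 40)),
                  quality_mean = 28, quality_sd = 8, path = fq, seed = 23)
  res <- kmer_search(fq, "ACGTTGCAAT", backend = "clear",
                     params = toy_params(), k_max = 12,
                     quality_mode = "sum", quality_threshold = 280,
                     seed = 23, verify = TRUE)
  expect_true(res$verification$ok)
  m <- res$matches
  expect_gte(nrow(m), 3)
  # every reported window lies wholly inside its read
  lens <- stats::setNames(nchar(r$reads$sequence), r$reads$read_id)
  expect_true(all(m$position + m$k <= lens[m$source_record]))

  # the three modes agree with a direct plaintext computation
  qual_of <- stats::setNames(r$reads$quality, r$reads$read_id)
  wq <- lapply(seq_len(nrow(m)), function(i) {
    utf8ToInt(substr(qual_of[[m$source_record[i]]], m$position[i] + 1,
                     m$position[i] + m$k[i])) - 33L
  })
  for (mode in c("min", "avg", "sum")) {
    thr <- c(min = 20, avg = 27, sum = 280)[[mode]]
    got <- filter_by_quality(m, mode = mode, threshold = thr,
                             reads = r$reads, keep_all = TRUE)
    want <- switch(mode,
                   min = vapply(wq, min, 0) >= thr,
                   avg = vapply(wq, sum, 0) >= ceiling(m$k * thr),
                   sum = vapply(wq, sum, 0) >= thr)
    expect_equal(got$pass_filter, want)
  }
  # server-side homomorphic sums equal the plaintext window sums
  expect_equal(m$sum_q, vapply(wq, sum, 0))
})

test_that("empty query sets and absent matches are graceful", {
  fa <- withr::local_tempfile(fileext = ".fa")
  make_genome(300, path = fa, seed = 29)
  ctx <- clear_ctx()
  keys <- he_keygen(ctx, seed = 29)
  dirs <- list(deploy = withr::local_tempdir(),
               queries = withr::local_tempdir(),
               results = withr::local_tempdir())
  encrypt_input(fa, ctx, keys, k_max = 8, deploy_dir = dirs$deploy)
  encrypt_queries(character(0), ctx, keys, 8, dirs$queries)
  cm <- process_all(dirs$deploy, dirs$queries, dirs$results)
  expect_equal(cm$n_queries, 0L)
  expect_equal(
    nrow(decrypt_and_extract(dirs$results, dirs$deploy, dirs$queries,
                             ctx, keys)), 0L)
  # absent query: empty record list, verification still clean
  res <- kmer_search(fa, "GGGGGGGGGGGG", backend = "clear",
                     params = toy_params(), k_max = 12, verify = TRUE)
  expect_equal(nrow(res$matches), 0L)
  expect_true(res$verification$ok)
})
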