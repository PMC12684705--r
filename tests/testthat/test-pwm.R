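# PWM -> k-mer reduction: MEME parsing, PSSM construction, the exact
# dynamic-programming score distribution against brute-force enumeration,
# BH correction against the step-up formula, and the query-set files.

test_that("MEME minimal format parsing extracts motifs and background", {
  m1 <- matrix(c(1, 0, 0, 0,
                 0, 0.5, 0.5, 0,
                 0.25, 0.25, 0.25, 0.25,
                 0, 0, 0, 1), nrow = 4, byrow = TRUE)
  m2 <- matrix(rep(0.25, 8), nrow = 2)
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(f, list(MOTIF_A = m1, MOTIF_B = m2),
             background = c(0.3, 0.2, 0.2, 0.3))
  parsed <- parse_meme(f)
  expect_length(parsed$motifs, 2)
  expect_equal(parsed$motifs[[1]]$width, 4L)
  expect_equal(parsed$motifs[[1]]$matrix[1, ], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(parsed$background, c(0.3, 0.2, 0.2, 0.3))

  bad <- matrix(c(0.4, 0.2, 0.1, 0.1), nrow = 1)
  f2 <- withr::local_tempfile(fileext = ".meme")
  write_meme(f2, list(BAD = bad))
  expect_error(parse_meme(f2), "format error")
})

test_that("PSSM scores are background log-ratios in bits", {
  uniform <- ppm(matrix(0.25, nrow = 3, ncol = 4))
  p0 <- build_pssm(uniform, pseudocount = 0)
  expect_true(all(p0$scores == 0))

  certain <- ppm(matrix(c(1, 0, 0, 0), nrow = 1))
  p1 <- build_pssm(certain, pseudocount = 0)
  expect_equal(unname(p1$scores[1, "A"]), 2)        # log2(1 / 0.25)
  expect_equal(unname(p1$scores[1, "C"]), -Inf)
  p2 <- build_pssm(certain, pseudocount = 0.1)
  expect_true(all(is.finite(p2$scores)))
  expect_error(build_pssm(uniform, background = c(0.5, 0.5, 0, 0)),
               "configuration error")
})

test_that("DP score distribution equals brute-force enumeration for k <= 6", {
  # worked example: width 1, scores {A: 2, C/G/T: 0}, uniform background
  p <- build_pssm(ppm(matrix(c(1, 0, 0, 0), nrow = 1)), pseudocount = 0,
                  scale = 1)
  d <- score_distribution(p)
  expect_equal(score_pvalue(d, 2), 0.25)
  expect_equal(score_pvalue(d, 3), 0)   # above the attainable range
  expect_equal(score_pvalue(d, d$lo), 1)  # whole mass at the bottom

  set.seed(53)
  for (k in c(2, 4, 6)) {
    pp <- random_ppm(k)
    bg <- stats::rgamma(4, 2)
    bg <- bg / sum(bg)
    pssm <- build_pssm(pp, background = bg, scale = 50)
    dist <- score_distribution(pssm)
    expect_equal(sum(dist$table$prob), 1, tolerance = 1e-9)
    expect_true(all(diff(dist$table$tail_p) <= 1e-12))
    probe <- sort(sample(dist$lo:dist$hi, min(25, dist$hi - dist$lo + 1)))
    expect_equal(score_pvalue(dist, probe), brute_force_tail(pssm, probe),
                 tolerance = 1e-9)
  }
})

test_that("enumeration yields exactly 4^k records with anti-monotone p-values", {
  set.seed(59)
  pssm <- build_pssm(random_ppm(2))
  dist <- score_distribution(pssm)
  rec <- enumerate_and_score(pssm, dist)
  expect_equal(nrow(rec), 16L)
  expect_equal(anyDuplicated(rec$kmer), 0L)
  expect_equal(rec$kmer[which.max(rec$score_int)],
               rec$kmer[which.min(rec$p_value)])
  # higher score implies smaller-or-equal p-value
  o <- order(rec$score_int)
  expect_true(all(diff(rec$p_value[o]) <= 1e-12))
  # per-k-mer p-values equal the brute-force tails
  expect_equal(rec$p_value, brute_force_tail(pssm, rec$score_int),
               tolerance = 1e-9)
  # width guard
  wide <- build_pssm(random_ppm(17))
  expect_error(enumerate_and_score(wide, dist), "refusing")
})

test_that("BH correction equals the step-up formula", {
  rec <- tibble::tibble(kmer = c("AA", "AC", "AG", "AT"),
                        p_value = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(bh_correct(rec)$q_value, rep(0.04, 4))
  expect_equal(bh_correct(tibble::tibble(p_value = rep(1, 5)))$q_value,
               rep(1, 5))
  expect_equal(bh_correct(tibble::tibble(p_value = 0.2))$q_value, 0.2)
  expect_error(bh_correct(tibble::tibble(p_value = c(0.5, 0.1))),
               "internal error")
  # random vectors against a literal implementation of the step-up rule
  set.seed(61)
  for (rep in 1:5) {
    p <- sort(stats::runif(sample(3:40, 1)))
    m <- length(p)
    manual <- rev(cummin(rev(pmin(1, m * p / seq_len(m)))))
    expect_equal(bh_correct(tibble::tibble(p_value = p))$q_value, manual)
  }
})

test_that("significance filtering writes matching txt and CSV query sets", {
  set.seed(67)
  scan <- pwm_to_kmers(random_ppm(3), threshold = 1.0,
                       out_prefix = file.path(withr::local_tempdir(), "m"))
  expect_equal(nrow(scan$significant), 64L)  # threshold 1 keeps all 4^3
  txt <- readLines(scan$files$kmers_txt)
  csv <- utils::read.csv(scan$files$details_csv)
  expect_setequal(txt, csv$kmer)
  expect_equal(length(txt), 64L)
  # q-values are non-decreasing with p in the detail file ordering
  expect_true(all(diff(csv$q_value) >= -1e-12))

  # a threshold below the smallest q yields a valid empty query set
  minq <- min(scan$records$q_value)
  scan2 <- pwm_to_kmers(random_ppm(3), threshold = minq / 2,
                        out_prefix = file.path(withr::local_tempdir(), "m"))
  expect_equal(nrow(scan2$significant), 0L)
  expect_equal(length(readLines(scan2$files$kmers_txt)), 0L)

  g <- glance(scan)
  expect_equal(g$n_kmers, 64L)
  expect_equal(nrow(tidy(scan)), 64L)
})

test_that("significant k-mers correspond exactly to a score threshold on the scan", {
  # an informative motif: significance at q <= alpha is equivalent to a
  # score cutoff, because p (hence q) is monotone in the discretized score
  set.seed(71)
  m <- matrix(c(0.85, 0.05, 0.05, 0.05,
                0.05, 0.85, 0.05, 0.05,
                0.05, 0.05, 0.85, 0.05,
                0.05, 0.05, 0.05, 0.85,
                0.85, 0.05, 0.05, 0.05,
                0.05, 0.05, 0.85, 0.05), nrow = 6, byrow = TRUE)
  scan <- pwm_to_kmers(ppm(m), threshold = 0.001, on = "p_value")
  expect_gt(nrow(scan$significant), 0)
  s_star <- min(scan$significant$score_int)
  in_set <- scan$records$score_int >= s_star
  expect_equal(sort(scan$records$kmer[in_set]), sort(scan$significant$kmer))
})
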