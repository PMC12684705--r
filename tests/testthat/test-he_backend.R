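# The homomorphic backend contract: encrypt/decrypt roundtrips, slot-wise
# arithmetic mod t, relinearized squaring, noise accounting, and the
# equivalence of the lattice backend with the clear reference backend.

test_that("encrypt/decrypt roundtrips are the identity on [0, t) for both backends", {
  set.seed(11)
  for (backend in c("clear", "bgv")) {
    ctx <- he_context(toy_params(), backend)
    keys <- he_keygen(ctx, seed = 11)
    expect_equal(ctx$slot_count, 1024)

    v <- sample(0:(ctx$t - 1), ctx$slot_count, replace = TRUE)
    expect_equal(he_decrypt(he_encrypt(v, ctx, keys), ctx, keys),
                 as.numeric(v))
    expect_equal(he_decrypt(he_encrypt(rep(0, 8), ctx, keys), ctx, keys),
                 rep(0, ctx$slot_count))
    # short vectors are right-padded with zeros
    got <- he_decrypt(he_encrypt(c(0, 1, 2, 3, 4), ctx, keys), ctx, keys)
    expect_equal(got[1:5], c(0, 1, 2, 3, 4))
    expect_true(all(got[-(1:5)] == 0))

    expect_error(he_encrypt(c(0, ctx$t), ctx, keys), "encoding error")
    expect_error(he_encrypt(rep(0, ctx$slot_count + 1), ctx, keys),
                 "encoding error")
  }
})

test_that("context creation validates degree and batching compatibility", {
  expect_error(crypto_params(poly_degree = 1000), "configuration error")
  expect_error(crypto_params(poly_degree = 512), "configuration error")
  # 65539 is prime but 65539 - 1 is not divisible by 2*8192
  expect_error(crypto_params(poly_degree = 8192, plain_modulus = 65539),
               "batching")
  # oversized custom chain downgrades the claimed security with a warning
  expect_warning(crypto_params(poly_degree = 1024, coeff_bits = c(55, 55)),
                 "security")
  p <- toy_params()
  expect_true(bgv_ctx(p)$slot_count == p$poly_degree)
})

test_that("homomorphic add/sub/square agree with the clear oracle slot-for-slot", {
  set.seed(21)
  cctx <- clear_ctx()
  bctx <- bgv_ctx()
  ckeys <- he_keygen(cctx, seed = 21)
  bkeys <- he_keygen(bctx, seed = 21)
  t <- cctx$t
  for (rep in 1:5) {
    a <- sample(0:4, cctx$slot_count, replace = TRUE)
    b <- sample(0:3, cctx$slot_count, replace = TRUE)
    c <- sample(0:50, cctx$slot_count, replace = TRUE)
    run <- function(ctx, keys) {
      ea <- he_encrypt(a, ctx, keys)
      eb <- he_encrypt(b, ctx, keys)
      ec <- he_encrypt(c, ctx, keys)
      he_decrypt(he_add(he_square_relin(he_sub(ea, eb), keys), ec),
                 ctx, keys)
    }
    want <- ((a - b)^2 + c) %% t
    expect_equal(run(cctx, ckeys), want)
    expect_equal(run(bctx, bkeys), want)
  }
})

test_that("self-subtraction is zero and the worst squared difference is 16", {
  ctx <- bgv_ctx()
  keys <- he_keygen(ctx, seed = 5)
  x <- he_encrypt(sample(0:4, ctx$slot_count, replace = TRUE), ctx, keys)
  expect_true(all(he_decrypt(he_sub(x, x), ctx, keys) == 0))
  # pad symbol 4 against query symbol 0: the largest per-slot contribution
  d <- he_sub(he_encrypt(rep(4, 8), ctx, keys),
              he_encrypt(rep(0, 8), ctx, keys))
  sq <- he_decrypt(he_square_relin(d, keys), ctx, keys)
  expect_equal(sq[1:8], rep(16, 8))
  expect_equal(he_square_relin(d, keys)$size, 2L)
})

test_that("noise budget: fresh degree-8192 budget exceeds 100 bits and decreases monotonically", {
  ctx <- he_context(paper_params(), "bgv")
  keys <- he_keygen(ctx, seed = 7)
  a <- he_encrypt(sample(0:4, ctx$slot_count, replace = TRUE), ctx, keys)
  b <- he_encrypt(sample(0:3, ctx$slot_count, replace = TRUE), ctx, keys)
  b0 <- he_noise_budget(a, keys)
  expect_gt(b0, 100)
  d <- he_sub(a, b)
  b1 <- he_noise_budget(d, keys)
  sq <- he_square_relin(d, keys)
  b2 <- he_noise_budget(sq, keys)
  acc <- he_add(sq, sq)
  b3 <- he_noise_budget(acc, keys)
  expect_true(b1 <= b0 && b2 <= b1 && b3 <= b2)
  expect_gt(b3, 0)
  # clear backend is noiseless
  cctx <- clear_ctx()
  ckeys <- he_keygen(cctx)
  expect_identical(he_noise_budget(he_encrypt(1, cctx, ckeys), ckeys), Inf)
})

test_that("a depth-2 expression still matches the clear oracle at degree 8192", {
  set.seed(31)
  ctx <- he_context(paper_params(), "bgv")
  keys <- he_keygen(ctx, seed = 31)
  a <- sample(0:4, ctx$slot_count, replace = TRUE)
  b <- sample(0:3, ctx$slot_count, replace = TRUE)
  d <- he_sub(he_encrypt(a, ctx, keys), he_encrypt(b, ctx, keys))
  sq2 <- he_square_relin(he_square_relin(d, keys), keys)
  expect_equal(he_mult_depth(sq2), 2L)
  expect_equal(he_decrypt(sq2, ctx, keys), ((a - b)^4) %% ctx$t)
  expect_gt(he_noise_budget(sq2, keys), 0)
})

test_that("key hygiene: wrong keys garble, eval-only keys cannot decrypt", {
  ctx <- bgv_ctx()
  k1 <- he_keygen(ctx, seed = 1)
  k2 <- he_keygen(ctx, seed = 2)
  v <- sample(0:100, ctx$slot_count, replace = TRUE)
  ct <- he_encrypt(v, ctx, k1)
  expect_false(identical(he_decrypt(ct, ctx, k2), as.numeric(v)))

  path <- withr::local_tempfile()
  he_save_keys(k1, ctx, path, which = "eval")
  ek <- he_load_keys(path, ctx)
  expect_false(ek$has_secret)
  expect_error(he_decrypt(ct, ctx, ek), "secret")
  # but evaluation with eval-only keys matches full-key evaluation
  sq <- he_square_relin(ct, ek)
  expect_equal(he_decrypt(sq, ctx, k1), (v^2) %% ctx$t)
})

test_that("ciphertext and key serialization roundtrip on both backends", {
  for (backend in c("clear", "bgv")) {
    ctx <- he_context(toy_params(), backend)
    keys <- he_keygen(ctx, seed = 3)
    v <- sample(0:4, ctx$slot_count, replace = TRUE)
    ct <- he_square_relin(he_encrypt(v, ctx, keys), keys)
    f <- withr::local_tempfile()
    he_save_cipher(ct, f)
    ct2 <- he_load_cipher(f, ctx)
    expect_equal(ct2$depth, 1L)
    expect_equal(he_decrypt(ct2, ctx, keys), (v^2) %% ctx$t)

    kf <- withr::local_tempfile()
    he_save_keys(keys, ctx, kf, which = "all")
    keys2 <- he_load_keys(kf, ctx)
    expect_true(keys2$has_secret)
    expect_equal(he_decrypt(ct, ctx, keys2), (v^2) %% ctx$t)
  }
})
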