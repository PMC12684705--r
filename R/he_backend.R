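# Homomorphic-encryption backend surface: one contract, two implementations.
#
# "bgv"   -- the real lattice scheme (RNS-BGV with CRT batching, in src/).
# "clear" -- a reference backend performing identical slot-wise arithmetic
#            mod t on plain integer vectors. It provides no secrecy and
#            exists as a deterministic oracle: every protocol computation on
#            the BGV backend must decrypt to exactly what the clear backend
#            produces.

# SEAL-style 128-bit coefficient-modulus budgets per ring degree; a default
# chain at each degree stays within the budget.
.default_coeff_chains <- list(
  `1024` = c(27L),
  `2048` = c(54L),
  `4096` = c(36L, 36L, 37L),
  `8192` = c(43L, 43L, 44L, 44L, 44L),
  `16384` = c(48L, 48L, 48L, 49L, 49L, 49L, 49L, 49L)
)

#' Cryptographic parameter set
#'
#' Bundles the ring dimension (= SIMD slot count under batching), the
#' plaintext modulus `t`, and the coefficient-modulus chain of the BGV
#' scheme. The defaults reproduce a standard 128-bit-security profile:
#' degree 8192, a batching-friendly 20-bit plaintext prime
#' (`t == 1 (mod 2 * poly_degree)`), and a coefficient chain totalling
#' ~218 bits.
#'
#' @param poly_degree Power-of-two ring dimension, at least 1024. Equals the
#'   number of plaintext slots per ciphertext.
#' @param plain_modulus_bits Bit length of the plaintext prime searched for
#'   when `plain_modulus` is not given.
#' @param plain_modulus Optional explicit plaintext prime; must satisfy
#'   `plain_modulus == 1 (mod 2 * poly_degree)`.
#' @param coeff_bits Optional integer vector of per-prime bit sizes for the
#'   ciphertext modulus chain; defaults to the standard chain for the
#'   degree. Chains exceeding the 128-bit-security budget are allowed for
#'   test profiles but mark the parameter set as offering no claimed
#'   security.
#' @param security_bits Claimed security level of the default chains
#'   (informational; set to 0 for oversized custom chains).
#' @return An object of class `crypto_params`.
#' @examples
#' crypto_params(poly_degree = 1024)
#' @export
crypto_params <- function(poly_degree = 8192,
                          plain_modulus_bits = 20,
                          plain_modulus = NULL,
                          coeff_bits = NULL,
                          security_bits = 128) {
  if (length(poly_degree) != 1 || is.na(poly_degree) || poly_degree < 1024 ||
      bitwAnd(as.integer(poly_degree), as.integer(poly_degree) - 1L) != 0L) {
    stop("configuration error: poly_degree must be a power of two >= 1024",
         call. = FALSE)
  }
  poly_degree <- as.integer(poly_degree)
  if (is.null(coeff_bits)) {
    coeff_bits <- .default_coeff_chains[[as.character(poly_degree)]]
    if (is.null(coeff_bits)) {
      stop("configuration error: no default coefficient chain for degree ",
           poly_degree, "; supply coeff_bits", call. = FALSE)
    }
  }
  coeff_bits <- as.integer(coeff_bits)
  budget <- sum(.default_coeff_chains[[as.character(poly_degree)]] %||% 0L)
  if (sum(coeff_bits) > budget && isTRUE(security_bits > 0)) {
    warning("coefficient chain (", sum(coeff_bits),
            " bits) exceeds the 128-bit-security budget for degree ",
            poly_degree, "; claimed security set to 0", call. = FALSE)
    security_bits <- 0
  }
  if (is.null(plain_modulus)) {
    plain_modulus <- bgv_find_plain_modulus(poly_degree, plain_modulus_bits)
  } else {
    plain_modulus <- as.numeric(plain_modulus)
    if (!bgv_is_prime(plain_modulus) ||
        plain_modulus %% (2 * poly_degree) != 1) {
      stop("configuration error: plain_modulus must be a prime equal to 1 ",
           "(mod 2 * poly_degree) to support batching", call. = FALSE)
    }
  }
  structure(
    list(poly_degree = poly_degree,
         plain_modulus = plain_modulus,
         coeff_bits = coeff_bits,
         security_bits = security_bits),
    class = "crypto_params"
  )
}

#' @export
print.crypto_params <- function(x, ...) {
  cat("<crypto_params> degree", x$poly_degree,
      "| t =", format(x$plain_modulus, scientific = FALSE),
      sprintf("(%d bits)", ceiling(log2(x$plain_modulus))),
      "| coeff chain", paste(x$coeff_bits, collapse = "+"),
      sprintf("= %d bits", sum(x$coeff_bits)),
      "| security", x$security_bits, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create a homomorphic-encryption context
#'
#' @param params A [crypto_params()] object.
#' @param backend `"bgv"` for the lattice scheme or `"clear"` for the
#'   reference backend computing identical slot-wise arithmetic mod `t`.
#' @return An `he_context` exposing `slot_count` and the plaintext modulus.
#' @examples
#' ctx <- he_context(crypto_params(poly_degree = 1024), backend = "clear")
#' ctx$slot_count
#' @export
he_context <- function(params, backend = c("clear", "bgv")) {
  backend <- match.arg(backend)
  stopifnot(inherits(params, "crypto_params"))
  handle <- NULL
  if (backend == "bgv") {
    handle <- bgv_context_new(params$poly_degree, params$plain_modulus,
                              params$coeff_bits)
  }
  structure(
    list(backend = backend,
         params = params,
         slot_count = params$poly_degree,
         t = params$plain_modulus,
         handle = handle,
         id = paste0(backend, "-", params$poly_degree, "-",
                     format(params$plain_modulus, scientific = FALSE), "-",
                     paste(params$coeff_bits, collapse = "."))),
    class = "he_context"
  )
}

#' @export
print.he_context <- function(x, ...) {
  cat("<he_context>", x$backend, "backend,", x$slot_count, "slots, t =",
      format(x$t, scientific = FALSE), "\n")
  invisible(x)
}

#' Generate a key triple (secret, public, relinearization)
#'
#' All three keys are generated together from one context. On the clear
#' backend the keys are sentinels and encryption/decryption are the identity
#' mod `t`; the eval-only variant still refuses to decrypt, mirroring the
#' BGV access structure so protocol tests exercise identical key hygiene on
#' both backends.
#'
#' @param ctx An [he_context()].
#' @param seed Optional integer; makes key generation reproducible.
#' @return An `he_keys` object with `has_secret = TRUE`.
#' @export
he_keygen <- function(ctx, seed = NULL) {
  stopifnot(inherits(ctx, "he_context"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  handle <- if (ctx$backend == "bgv") bgv_keygen(ctx$handle) else "clear-keys"
  structure(
    list(backend = ctx$backend, ctx_id = ctx$id, handle = handle,
         has_secret = TRUE, has_relin = TRUE),
    class = "he_keys"
  )
}

.check_ctx <- function(ctx) {
  if (!inherits(ctx, "he_context")) stop("not an he_context", call. = FALSE)
}
.check_pair <- function(a, b) {
  if (!inherits(a, "cipher_vec") || !inherits(b, "cipher_vec")) {
    stop("usage error: expected cipher_vec operands", call. = FALSE)
  }
  if (a$ctx_id != b$ctx_id) {
    stop("usage error: ciphertexts come from different contexts",
         call. = FALSE)
  }
}
.check_keys <- function(keys, ctx_id, need_secret = FALSE) {
  if (!inherits(keys, "he_keys")) stop("not an he_keys object", call. = FALSE)
  if (keys$ctx_id != ctx_id) {
    stop("usage error: keys come from a different context", call. = FALSE)
  }
  if (need_secret && !isTRUE(keys$has_secret)) {
    stop("keys lack the secret key (evaluation-only keys cannot decrypt)",
         call. = FALSE)
  }
}

.new_cipher <- function(ctx, handle, depth = 0L, size = 2L) {
  structure(
    list(backend = ctx$backend, ctx_id = ctx$id, ctx = ctx,
         slot_count = ctx$slot_count, t = ctx$t,
         handle = handle, size = size, depth = depth),
    class = "cipher_vec"
  )
}

#' @export
print.cipher_vec <- function(x, ...) {
  cat("<cipher_vec>", x$backend, "|", x$slot_count, "slots | size", x$size,
      "| mult depth", x$depth, "\n")
  invisible(x)
}

#' Encrypt an integer vector into one batched ciphertext
#'
#' Entries must lie in `[0, t)`; vectors shorter than the slot count are
#' right-padded with zeros.
#'
#' @param v Integer (or integer-valued numeric) vector, length at most
#'   `ctx$slot_count`.
#' @param ctx,keys Context and keys from [he_context()] / [he_keygen()].
#' @return A `cipher_vec`.
#' @export
he_encrypt <- function(v, ctx, keys) {
  .check_ctx(ctx)
  .check_keys(keys, ctx$id)
  v <- as.numeric(v)
  if (length(v) > ctx$slot_count) {
    stop("encoding error: vector longer than slot count", call. = FALSE)
  }
  if (anyNA(v) || any(v < 0) || any(v >= ctx$t) || any(v != floor(v))) {
    stop("encoding error: entries must be integers in [0, plain_modulus)",
         call. = FALSE)
  }
  v <- c(v, rep(0, ctx$slot_count - length(v)))
  handle <- if (ctx$backend == "bgv") {
    bgv_encrypt(ctx$handle, keys$handle, v)
  } else {
    v
  }
  .new_cipher(ctx, handle)
}

#' Decrypt a batched ciphertext
#'
#' @inheritParams he_encrypt
#' @param ct A `cipher_vec`.
#' @return Numeric vector of length `slot_count` with entries in `[0, t)`.
#' @export
he_decrypt <- function(ct, ctx, keys) {
  .check_ctx(ctx)
  stopifnot(inherits(ct, "cipher_vec"))
  if (ct$ctx_id != ctx$id) {
    stop("usage error: ciphertext from a different context", call. = FALSE)
  }
  .check_keys(keys, ctx$id, need_secret = TRUE)
  if (ctx$backend == "bgv") {
    bgv_decrypt(ctx$handle, keys$handle, ct$handle)
  } else {
    ct$handle
  }
}

#' Slot-wise homomorphic subtraction, addition, and relinearized squaring
#'
#' Decrypted results equal the slot-wise `(a - b) mod t`, `(a + b) mod t`
#' and `a^2 mod t`. Squaring relinearizes immediately, so the ciphertext
#' size returns to 2 and the recorded multiplicative depth increases by one.
#'
#' @param a,b `cipher_vec` operands from the same context.
#' @param keys Keys carrying relinearization material (evaluation keys are
#'   sufficient; no secret key is required).
#' @return A `cipher_vec`.
#' @export
he_sub <- function(a, b) {
  .check_pair(a, b)
  ctx <- a$ctx
  handle <- if (ctx$backend == "bgv") {
    bgv_add(ctx$handle, a$handle, b$handle, TRUE)
  } else {
    (a$handle - b$handle) %% ctx$t
  }
  .new_cipher(ctx, handle, depth = max(a$depth, b$depth))
}

#' @rdname he_sub
#' @export
he_add <- function(a, b) {
  .check_pair(a, b)
  ctx <- a$ctx
  handle <- if (ctx$backend == "bgv") {
    bgv_add(ctx$handle, a$handle, b$handle, FALSE)
  } else {
    (a$handle + b$handle) %% ctx$t
  }
  .new_cipher(ctx, handle, depth = max(a$depth, b$depth))
}

#' @rdname he_sub
#' @export
he_square_relin <- function(a, keys) {
  stopifnot(inherits(a, "cipher_vec"))
  ctx <- a$ctx
  .check_keys(keys, ctx$id)
  if (a$size != 2L) {
    stop("usage error: squaring expects a size-2 ciphertext", call. = FALSE)
  }
  handle <- if (ctx$backend == "bgv") {
    bgv_square_relin(ctx$handle, keys$handle, a$handle)
  } else {
    (a$handle * a$handle) %% ctx$t
  }
  .new_cipher(ctx, handle, depth = a$depth + 1L, size = 2L)
}

#' Remaining invariant noise budget of a ciphertext, in bits
#'
#' Decryption is guaranteed correct while the budget is strictly positive.
#' The clear backend is noiseless and returns `Inf`.
#'
#' @param ct A `cipher_vec`.
#' @param keys Keys holding the secret key (needed to measure noise).
#' @return Non-negative number of bits (or `Inf` on the clear backend).
#' @export
he_noise_budget <- function(ct, keys) {
  stopifnot(inherits(ct, "cipher_vec"))
  if (ct$backend == "clear") return(Inf)
  .check_keys(keys, ct$ctx_id, need_secret = TRUE)
  bgv_noise_budget(ct$ctx$handle, keys$handle, ct$handle)
}

#' Multiplicative depth recorded along a ciphertext's computation path
#'
#' Every [he_square_relin()] increments the depth; additions and
#' subtractions propagate the maximum of their operands. This instruments
#' the circuit so the depth-1 property of the SSD evaluation can be asserted
#' without inspecting ciphertext internals.
#'
#' @param ct A `cipher_vec`.
#' @return Integer depth (0 for a fresh ciphertext).
#' @export
he_mult_depth <- function(ct) {
  stopifnot(inherits(ct, "cipher_vec"))
  ct$depth
}

# --------------------------------------------------------------------------
# Serialization: backend-native binary blobs behind a tiny common header
# --------------------------------------------------------------------------

.backend_code <- c(clear = 0L, bgv = 1L)

#' Save / load ciphertexts and keys
#'
#' Ciphertext files carry a small header (backend, slot count, size,
#' recorded depth) followed by a backend-native payload. Key files come in
#' two flavours: `which = "all"` (secret + public + relinearization keys;
#' client-side only) and `which = "eval"` (relinearization keys only, safe
#' to hand to the untrusted server). Loading an eval-only key file yields
#' keys with `has_secret = FALSE` that refuse to decrypt.
#'
#' @param ct A `cipher_vec`.
#' @param path File path.
#' @param ctx Context the blob belongs to.
#' @param keys An `he_keys` object.
#' @param which `"all"` or `"eval"`.
#' @return `he_load_cipher()` returns a `cipher_vec`; `he_load_keys()`
#'   returns an `he_keys`; the savers return `path` invisibly.
#' @export
he_save_cipher <- function(ct, path) {
  stopifnot(inherits(ct, "cipher_vec"))
  payload <- if (ct$backend == "bgv") {
    bgv_serialize_cipher(ct$ctx$handle, ct$handle)
  } else {
    writeBin(ct$handle, raw(), size = 8)
  }
  .track_io({
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(1130655299L, 1L), con)  # magic "CMER"-ish, version
    writeBin(as.integer(c(.backend_code[[ct$backend]], ct$slot_count,
                          ct$size, ct$depth, length(payload))), con)
    writeBin(payload, con)
  })
  invisible(path)
}

#' @rdname he_save_cipher
#' @export
he_load_cipher <- function(path, ctx) {
  .check_ctx(ctx)
  .track_io({
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- readBin(con, "integer", 2)
    if (hdr[1] != 1130655299L) stop("not a cryptomer ciphertext file: ", path,
                                    call. = FALSE)
    meta <- readBin(con, "integer", 5)
    payload <- readBin(con, "raw", meta[5])
  })
  backend <- names(.backend_code)[match(meta[1], .backend_code)]
  if (backend != ctx$backend) {
    stop("usage error: ciphertext written by the ", backend,
         " backend, context is ", ctx$backend, call. = FALSE)
  }
  if (meta[2] != ctx$slot_count) {
    stop("usage error: slot count mismatch", call. = FALSE)
  }
  handle <- if (backend == "bgv") {
    bgv_deserialize_cipher(ctx$handle, payload)
  } else {
    readBin(payload, "numeric", meta[2], size = 8)
  }
  .new_cipher(ctx, handle, depth = meta[4], size = meta[3])
}

#' @rdname he_save_cipher
#' @export
he_save_keys <- function(keys, ctx, path, which = c("all", "eval")) {
  which <- match.arg(which)
  .check_ctx(ctx)
  .check_keys(keys, ctx$id, need_secret = (which == "all"))
  payload <- if (ctx$backend == "bgv") {
    bgv_serialize_keys(ctx$handle, keys$handle, which)
  } else {
    as.raw(if (which == "all") 1L else 0L)
  }
  .track_io({
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(1130655300L, 1L), con)
    writeBin(as.integer(c(.backend_code[[keys$backend]],
                          if (which == "all") 1L else 0L,
                          length(payload))), con)
    writeBin(payload, con)
  })
  invisible(path)
}

#' @rdname he_save_cipher
#' @export
he_load_keys <- function(path, ctx) {
  .check_ctx(ctx)
  .track_io({
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- readBin(con, "integer", 2)
    if (hdr[1] != 1130655300L) stop("not a cryptomer key file: ", path,
                                    call. = FALSE)
    meta <- readBin(con, "integer", 3)
    payload <- readBin(con, "raw", meta[3])
  })
  backend <- names(.backend_code)[match(meta[1], .backend_code)]
  if (backend != ctx$backend) {
    stop("usage error: keys written by the ", backend, " backend",
         call. = FALSE)
  }
  full <- meta[2] == 1L
  handle <- if (backend == "bgv") {
    bgv_deserialize_keys(ctx$handle, payload)
  } else {
    "clear-keys"
  }
  structure(
    list(backend = backend, ctx_id = ctx$id, handle = handle,
         has_secret = full, has_relin = TRUE),
    class = "he_keys"
  )
}
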