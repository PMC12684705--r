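# Shared test fixtures: parameter profiles and tiny in-code inputs.
#
# The toy BGV profile (degree 1024, two 55-bit primes) trades security for
# speed: it supports the full depth-1 SSD circuit with the default 20-bit
# plaintext modulus, which the 27-bit secure chain at this degree cannot.
# All protocol logic is parameterized by slot_count, so geometry behaves
# identically at any degree.

toy_params <- function() {
  crypto_params(poly_degree = 1024, coeff_bits = c(55L, 55L),
                security_bits = 0)
}

paper_params <- function() crypto_params(poly_degree = 8192)

clear_ctx <- function(params = toy_params()) he_context(params, "clear")

bgv_ctx <- function(params = toy_params()) he_context(params, "bgv")

# plaintext sliding-window SSD oracle over encoded symbols
ssd_oracle <- function(symbols, query_symbols) {
  k <- length(query_symbols)
  n <- length(symbols) - k + 1
  vapply(seq_len(n), function(i) {
    sum((symbols[i:(i + k - 1)] - query_symbols)^2)
  }, numeric(1))
}

# write a minimal MEME file for parser tests
write_meme <- function(path, matrices, background = NULL) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "")
  if (!is.null(background)) {
    lines <- c(lines, "Background letter frequencies",
               paste("A", background[1], "C", background[2],
                     "G", background[3], "T", background[4]), "")
  }
  for (nm in names(matrices)) {
    m <- matrices[[nm]]
    lines <- c(lines,
               paste("MOTIF", nm),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(m)),
               apply(m, 1, function(r) paste(format(r, nsmall = 3),
                                             collapse = " ")),
               "")
  }
  writeLines(lines, path)
  path
}

random_kmer <- function(k) {
  paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
}

# random PPM generator and the exhaustive 4^k scoring oracle used to
# cross-check the dynamic-programming score distribution
random_ppm <- function(k) {
  m <- matrix(stats::rgamma(4 * k, shape = 0.8), nrow = k)
  ppm(m / rowSums(m))
}

# independent oracle: exhaustive enumeration of all 4^k sequences
brute_force_tail <- function(pssm, score_int) {
  k <- pssm$width
  grid <- as.matrix(expand.grid(rep(list(1:4), k)))
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    sum(pssm$int_scores[cbind(seq_len(k), grid[i, ])])
  }, numeric(1))
  probs <- vapply(seq_len(nrow(grid)), function(i) {
    prod(pssm$background[grid[i, ]])
  }, numeric(1))
  vapply(score_int, function(s) sum(probs[scores >= s]), numeric(1))
}

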