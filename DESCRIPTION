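Package: cryptomer
Title: Private Exact k-mer Search over Homomorphically Encrypted Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Client/server protocol for exact k-mer search on encrypted
    genomes and sequencing reads. A trusted client encodes FASTA/FASTQ input
    into SIMD-batched stride vectors and encrypts them once under a leveled
    BGV homomorphic encryption scheme (implemented from scratch with
    residue-number-system arithmetic and number-theoretic transforms); an
    untrusted server answers k-mer queries by evaluating an encrypted
    sum-of-squared-differences per sliding window, so that a zero slot
    certifies an exact match and only the client can decrypt. Includes a
    position-weight-matrix to k-mer reduction (exact score distribution by
    dynamic programming, p-values, Benjamini-Hochberg q-values) for private
    motif searches, Phred-quality filtering of read matches, and a
    reproducible synthetic-fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    optparse,
    Biostrings,
    BiocGenerics,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
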