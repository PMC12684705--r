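# cryptomer

Private exact k-mer search over homomorphically encrypted genomes and
sequencing reads, in R.

## The problem

Outsourcing genomic data to a cloud server is routine, but a genome is
about the most identifying dataset a person has, and the *queries* run
against it (disease alleles, pathogen signatures, binding motifs) can be
just as sensitive. `cryptomer` implements a single-client / single-server
protocol for the honest-but-curious setting: the client encrypts a FASTA
genome or FASTQ read set **once**, ships only ciphertexts to the server,
and thereafter asks exact k-mer queries that the server answers without
ever seeing the sequence, the query, or the result. Only the client's
secret key can decrypt anything.

## The method

The protocol rests on three ingredients:

**1. Leveled BGV encryption with SIMD batching.** The package contains a
from-scratch implementation of the integer BGV scheme over
R\_q = Z\_q\[x\]/(x^n + 1) (residue-number-system arithmetic, negacyclic
number-theoretic transforms per CRT prime, relinearization by RNS
decomposition). With a plaintext prime t ≡ 1 (mod 2n), one ciphertext
carries n = 8192 independent Z\_t slots, and every homomorphic operation
acts on all slots at once. A "clear" reference backend performs the
identical slot-wise arithmetic mod t in plaintext and serves as the
deterministic oracle the lattice backend is tested against.

**2. Stride encoding.** Bases A,C,G,T map to 0,1,2,3; padding and unknown
characters to 4. A chunk of the input is transposed into k\_max *stride
vectors* — stride j holds the j-th character of every sliding window — so
the whole chunk's windows line up across SIMD slots. Each stride is one
ciphertext. FASTQ reads are packed with k\_max − 1 pad symbols between
reads, so no window can straddle a read boundary.

**3. An encrypted sum-of-squared-differences (SSD) equality test.** For a
query K of length k (each character encrypted with its value replicated
across all slots), the server computes, entirely on ciphertexts,

    SSD_i = Σ_{j=0}^{k-1} ( C_{i+j} − K_j )²     for every window i at once,

with one subtraction, one relinearized squaring and one addition per
character: multiplicative depth 1. Since symbols lie in {0..4} and queries
in {0..3}, each term is at most 16 and SSD ≤ 16·k\_max ≪ t, so no modular
wraparound can create a false zero: **SSD\_i = 0 ⟺ window i equals the
query**. The client decrypts, reads off the zero slots, and maps them back
to genomic coordinates or (read, offset) pairs. Phred-quality filtering of
FASTQ matches is supported in three modes (`min` via a client-side
plaintext scan; `sum`/`avg` from homomorphic window quality sums computed
server-side at depth 0).

**Motif searches** reduce to the same machinery: `pwm_to_kmers()` builds a
PSSM from a MEME-format probability matrix, computes the exact null score
distribution by dynamic programming over discretized scores, enumerates
all 4^k k-mers with p-values, applies a Benjamini–Hochberg correction, and
writes the significant k-mers as a ready-to-encrypt query list.

## Worked example

```r
library(cryptomer)

fa <- tempfile(fileext = ".fa")
make_genome(20000, gc_content = 0.45,
            plants = data.frame(seq = c("ACGTTGCAGGTA", "TTGACCGA"),
                                position = c(1500, 9000)),
            path = fa, seed = 42)

res <- kmer_search(fa, c("ACGTTGCAGGTA", "TTGACCGA", "CCCCCCCCCC"),
                   backend = "bgv", k_max = 16, seed = 42, verify = TRUE)
res
#> <kmer_search_result> bgv backend | 3 queries | 2 matches
#>   verification: OK (no discrepancies)

res$matches[, c("query_id", "query_seq", "k", "source_record", "position", "ssd")]
#> # A tibble: 2 × 6
#>   query_id query_seq        k source_record    position   ssd
#>   <chr>    <chr>        <int> <chr>               <int> <dbl>
#> 1 q1       ACGTTGCAGGTA    12 synthetic_genome     1500     0
#> 2 q2       TTGACCGA         8 synthetic_genome     9000     0

glance(res)
#> # A tibble: 1 × 7
#>   backend n_queries n_matches verified_ok encrypt_s evaluate_s decrypt_s
#>   <chr>       <int>     <int> <lgl>           <dbl>      <dbl>     <dbl>
#> 1 bgv             3         2 TRUE             6.62       7.79     0.261
```

The two planted k-mers are recovered at exactly their planted 0-based
positions with decrypted SSD 0; the absent query returns nothing; and the
opt-in verification confirms the encrypted result set equals an
independent plaintext search (`Biostrings::vmatchPattern`) exactly. A
`ssd` of 0 is the match certificate — any mismatch in any of the k
positions contributes at least 1.

For staged, two-party operation over a shared filesystem, the same stages
are available as command-line tools installed under `exec/`:

```sh
cryptomer-client keygen           --config run.yaml
cryptomer-client encrypt          --config run.yaml genome.fa
cryptomer-client encrypt-queries  --config run.yaml kmers.txt
cryptomer-server                  --config run.yaml         # untrusted side
cryptomer-client decrypt          --config run.yaml
cryptomer-client pwm2kmers --meme motif.meme --q-threshold 0.05 --out-prefix motif
```

## Scope and caveats

- Exact matching only (no mismatches or indels), forward strand by
  default; reverse-complement searches are expressed by expanding the
  query set client-side.
- Queries are limited to the `k_max` the deployment was encrypted for.
- Randomness comes from R's RNG for reproducibility; this is a research
  implementation of the scheme, not an audited cryptographic library.
- The methods vignette (`vignettes/private-kmer-search.Rmd`) documents the
  model, parameter choices, noise accounting and limitations in detail.
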