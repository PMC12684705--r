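---
title: "Private k-mer search: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Private k-mer search: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptomer)
```

This vignette is the package's own account of the science behind it: the
threat model and protocol, the encryption scheme and its noise behaviour,
the encoding geometry, the motif reduction, the parameters a user can
turn, and the limits of what the test suite demonstrates.

## Threat model and protocol shape

The setting is a single trusted client and a single *honest-but-curious*
server: the server executes the protocol faithfully but may inspect
everything it stores or computes. The client encrypts its genome or read
set once, uploads ciphertexts plus geometry metadata, and later submits
encrypted k-mer queries. The server returns encrypted per-window scores;
the client alone can decrypt. The server never holds the secret key, the
plaintext sequence, or the plaintext queries — the deployment directory
contains stride ciphertexts, a JSON manifest of chunk/batch geometry, and
*evaluation-only* keys (relinearization material), which is public by
construction. All communication is through a shared filesystem; there is
no network protocol.

## The encryption scheme

The package implements the leveled BGV scheme over
$R_q = \mathbb{Z}_q[x]/(x^n+1)$ from scratch (no FHE library exists for
R). Design points that matter to a user:

- **Batching.** The plaintext modulus $t$ is a prime with
  $t \equiv 1 \pmod{2n}$, so $x^n + 1$ splits completely mod $t$ and one
  ciphertext holds $n$ independent $\mathbb{Z}_t$ slots. Encoding/decoding
  is a negacyclic NTT mod $t$; slot-wise products correspond to
  polynomial products, which is all the protocol needs (no slot rotations
  are used anywhere).
- **RNS arithmetic.** $q$ is a product of distinct NTT-friendly primes;
  all ciphertext arithmetic is component-wise per prime with ciphertexts
  held in the NTT (evaluation) domain. Relinearization after squaring uses
  RNS-decomposition key switching: the quadratic ciphertext component is
  decomposed into its per-prime residues (centered), each multiplied
  against a key-switching key encrypting $f_i \cdot s^2$ where $f_i$ is
  the CRT idempotent of prime $i$. Decryption and noise measurement
  reconstruct coefficients exactly via Garner's mixed-radix algorithm, so
  the reported *invariant noise budget* is an exact measurement, not an
  estimate.
- **BGV vs BFV.** Both schemes give exact integer arithmetic mod $t$; they
  differ in where the plaintext sits in the ciphertext (least- vs
  most-significant digit). We chose the BGV (lsb) form because its
  multiplication is plain polynomial multiplication mod $q$, which stays
  simple and exact in RNS, whereas BFV multiplication needs rounded
  scaling by $t/q$ (substantially more machinery for no semantic
  difference at depth 1). The backend surface is scheme-agnostic: a
  `cipher_vec` is an opaque handle with slot-wise add/sub/square semantics
  mod $t$.
- **Randomness.** Secrets and encryption randomness (ternary secrets and
  ephemerals, rounded-Gaussian errors with $\sigma = 3.2$) are drawn from
  R's RNG so that runs are reproducible under `set.seed()`. That is the
  right trade-off for a research artifact and the wrong one for
  production cryptography; an audited deployment would swap in a CSPRNG.

### Parameters

`crypto_params()` bundles the tunables:

| parameter | default | meaning |
|---|---|---|
| `poly_degree` | 8192 | ring dimension = SIMD slot count; power of two ≥ 1024 |
| `plain_modulus_bits` | 20 | bit length of the batching prime $t$ |
| `coeff_bits` | 43+43+44+44+44 (≈218 bits) | ciphertext modulus chain |
| `security_bits` | 128 | claimed security of the default chains |

The default chains mirror the standard 128-bit-security coefficient
budgets per degree (27 bits at 1024 up to 218 bits at 8192). A 20-bit $t$
comfortably holds the largest possible SSD value: symbols are in
$\{0..4\}$, query characters in $\{0..3\}$, so one squared difference is
at most $16$ and a full window sum at most $16\,k_{\max} = 512$ for
$k_{\max} = 32$ — no wraparound, hence no false zeros.

### Noise accounting

The SSD circuit is *depth 1*: each query character costs one homomorphic
subtraction, one squaring with immediate relinearization, and one
addition into the accumulator; no product ever feeds another product.
Measured at the default degree-8192 parameters, a fresh ciphertext has a
budget of ~187 bits and a complete $k=16$ SSD result retains ~142 bits —
decryption correctness holds with an enormous margin, and the test suite
asserts budget > 0 plus exact agreement with the clear-backend oracle
rather than a particular figure, since the exact number depends on key
material. Relinearization is applied immediately after every squaring,
keeping ciphertexts at size 2 and making noise growth per character
additive.

The **test profile** used throughout the suite is degree 1024 with a
custom 2×55-bit chain (claimed security 0 — a toy). The secure 27-bit
chain at this degree cannot hold a 20-bit plaintext modulus, and all
protocol logic is parameterized by `slot_count`, so geometry and
semantics are identical at every degree; scheme-level correctness at the
production degree is covered by dedicated tests.

## Encoding geometry

- **Alphabet**: A,C,G,T (case-folded, so soft-masked lowercase encodes
  normally) map to 0–3; IUPAC ambiguity codes, gaps, and padding map to
  the non-nucleotide symbol 4. Queries are restricted to A/C/G/T, so any
  window containing symbol 4 mismatches every query in that position —
  padded slots, inter-record gaps and read boundaries can never produce a
  zero SSD. This single invariant carries most of the protocol's
  correctness weight.
- **Chunking (FASTA)**: the concatenated input (records joined by
  $k_{\max}-1$ pads) is cut into 256 KB chunks overlapping by exactly
  $k_{\max}-1$ symbols — the minimum overlap such that every window of
  length ≤ $k_{\max}$ lies wholly inside some chunk. A window seen through
  two chunks maps to the same absolute coordinate and is deduplicated at
  decryption. A chunk of $L$ symbols has $L - k_{\max} + 1$ windows (the
  final chunk is right-padded with $k_{\max}-1$ pads so trailing windows
  for $k < k_{\max}$ exist).
- **Read packing (FASTQ)**: whole reads are concatenated with
  $k_{\max}-1$ pads between and after them; chunk boundaries fall only at
  read boundaries, so no overlap is needed and no within-read window ever
  spans chunks. Phred+33 is assumed (universal in modern FASTQ).
- **Batches**: each chunk's windows are segmented into groups of
  `slot_count`; one batch = $k_{\max}$ stride ciphertexts. Coordinates are
  0-based half-open throughout; the TSV writer can add a 1-based column
  for human consumption.

## Quality filtering

Three window-quality modes for FASTQ matches: `min` requires every base
to reach the threshold and is computed by a client-side scan of the
plaintext qualities at decryption time — a minimum is a non-linear
aggregate that would need unbounded multiplicative depth server-side.
`sum` and `avg` use server-side homomorphic window sums over parallel
quality stride ciphertexts (additions only, depth 0); `avg` is compared
in integer arithmetic as $\text{sum} \ge \lceil k \cdot \tau \rceil$ to
avoid floating point on decrypted integers.

## The motif reduction

Scoring a position weight matrix directly under encryption would require
a private table lookup per character per window — a cascade of deep
homomorphic multiplications — so the probabilistic search is reduced
offline to a deterministic one:

1. **PSSM**: $\mathrm{score}(j,b) = \log_2 \frac{(p_{jb} + c\,g_b)/(1+c)}{g_b}$
   against background frequencies $g$ with pseudocount $c$ (default 0.1,
   the usual background-weighted convention). Scores are in bits (the
   motif-scanning convention) and discretized at `scale` bins per bit
   (default 1000), making the dynamic program exact on the discretized
   scale. Letters with zero probability at pseudocount 0 are clamped to a
   floor 100 bits below the smallest finite score, which no attainable
   threshold can reach.
2. **Exact null distribution**: a convolution DP over positions gives the
   full distribution of scores under the background model; suffix sums
   yield $P(\text{score} \ge s)$ — an exact p-value for every k-mer.
3. **Enumeration and FDR**: all $4^k$ k-mers are scored and assigned
   p-values (guarded at $k \le 16$, warning above 12), sorted by p-value
   with lexicographic tie-breaks for reproducibility, and corrected by
   the Benjamini–Hochberg step-up rule (via `stats::p.adjust`, which the
   tests cross-check against the literal formula). The significant set —
   by q-value by default, by p-value optionally — is written as a
   plain-text query list plus a detail CSV.

Because the p-value is monotone in the discretized score (and tied
p-values receive tied q-values), the significant set is exactly
$\{\text{score} \ge s^\*\}$ for a cutoff $s^\*$; searching those k-mers
therefore recovers precisely the windows a direct thresholded PSSM scan
would report on the forward strand, which the test suite verifies
end-to-end. Forward strand only: strand expansion belongs to the query
layer, like reverse-complement handling for plain k-mers. The background
must be supplied a priori — the client cannot measure composition on a
genome it only holds encrypted — so significance is computed under an
assumed model (uniform by default), a known limitation of the reduction.

## What the synthetic fixtures do and do not show

`make_genome()`/`make_reads()` produce i.i.d. backgrounds at a chosen GC
content with planted occurrences at known positions, and truncated-normal
per-base qualities (mean 30, sd 5, clamped to [2, 41] by default — a
reasonable modern short-read profile; sd is widened in tests that need
filter failures). They are deterministic under a seed and carry exact
ground truth. They do **not** model sequencing error, indels, repeat
structure, or position-dependent quality decay. For this protocol that is
a smaller gap than it would be elsewhere — exact matching is insensitive
to compositional structure, and correctness is always checked against a
full plaintext scan of the same input rather than the plant list — but
runtime-relevant properties of real genomes (repeat-driven match density,
very long chromosomes) are exercised only at reduced scale. Tests run
genomes of 10–100 kb and read sets of tens of reads, sizes chosen so the
full property suites run in minutes; the geometry is identical at any
scale because everything is parameterized by `slot_count` and
`chunk_size`.

## Numerical and degenerate-input choices

- Window counts use the standard $L - k + 1$; slot coordinates outside a
  batch's valid windows are an error, and padded slots decrypt to
  nonzero SSD by construction.
- Integer comparisons throughout the decrypted path (SSD equality to 0,
  quality sums); the only floating point is in the motif statistics,
  where the DP is exact on discretized scores and probabilities are
  accumulated in double precision (validated to 1e-9 against exhaustive
  enumeration).
- Empty query sets, absent matches, chunk-sized inputs, single reads, and
  queries at exactly $k_{\max}$ are all defined and tested; a chunk
  shorter than $k_{\max}$ is skipped with a warning; `chunk_size` must
  exceed $k_{\max}$.
- Reported match records carry the raw decrypted SSD value (0 for a
  match). A zero SSD coincides with zero Hamming distance; nonzero SSD
  values are not Hamming distances and are not interpreted further.

## Known limitations

- The server learns ciphertext *shapes*: the number of chunks/batches,
  $k_{\max}$, the number and lengths of queries. It learns nothing about
  their content, and result ciphertexts are indistinguishable whether or
  not matches exist.
- No server-side skipping of match-free regions: the client decrypts one
  result vector per (batch, query). Homomorphic zero-tests could build a
  coarse index server-side at extra depth; out of scope here.
- Exact matching only; $k \le k_{\max}$ fixed at encryption time; smaller
  $k$ queries pay redundant storage — the $k_{\max}$ dial trades
  ciphertext size for query flexibility.
- The clear backend is an arithmetic oracle, not an encryption: it
  provides no secrecy and exists so every protocol computation can be
  checked deterministically and cheaply against the lattice backend.
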