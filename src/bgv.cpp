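// Leveled BGV homomorphic encryption over Z_t with SIMD batching.
//
// From-scratch implementation of the integer BGV scheme in the ring
// R_q = Z_q[x]/(x^n + 1), with:
//   * q a product of distinct NTT-friendly primes (residue number system),
//   * negacyclic number-theoretic transforms per RNS prime,
//   * CRT batching over a plaintext prime t = 1 (mod 2n), so one ciphertext
//     carries n independent Z_t slots,
//   * public-key encryption, lsb plaintext encoding (c0 + c1 s = m + t e),
//   * relinearization by RNS-decomposition key switching,
//   * Garner mixed-radix CRT reconstruction for decryption and for exact
//     measurement of the remaining invariant noise budget.
//
// Randomness is drawn from R's RNG so that keygen/encryption are
// reproducible under set.seed(); this is a research implementation, not a
// hardened cryptographic library.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <cmath>

using namespace Rcpp;

typedef uint64_t u64;
typedef int64_t i64;
typedef unsigned __int128 u128;

static inline u64 addmod_u(u64 a, u64 b, u64 m) {
  u64 s = a + b;           // a,b < m < 2^60: no overflow
  return s >= m ? s - m : s;
}
static inline u64 submod_u(u64 a, u64 b, u64 m) {
  return a >= b ? a - b : a + m - b;
}
static inline u64 mulmod_u(u64 a, u64 b, u64 m) {
  return (u64)(((u128)a * b) % m);
}
static u64 powmod_u(u64 a, u64 e, u64 m) {
  u64 r = 1 % m;
  a %= m;
  while (e) {
    if (e & 1) r = mulmod_u(r, a, m);
    a = mulmod_u(a, a, m);
    e >>= 1;
  }
  return r;
}

// deterministic Miller-Rabin, valid for all 64-bit n
static bool is_prime_u64(u64 n) {
  if (n < 2) return false;
  for (u64 p : {2ULL, 3ULL, 5ULL, 7ULL, 11ULL, 13ULL, 17ULL, 19ULL, 23ULL,
                29ULL, 31ULL, 37ULL}) {
    if (n % p == 0) return n == p;
  }
  u64 d = n - 1;
  int r = 0;
  while ((d & 1) == 0) { d >>= 1; ++r; }
  for (u64 a : {2ULL, 3ULL, 5ULL, 7ULL, 11ULL, 13ULL, 17ULL, 19ULL, 23ULL,
                29ULL, 31ULL, 37ULL}) {
    u64 x = powmod_u(a, d, n);
    if (x == 1 || x == n - 1) continue;
    bool comp = true;
    for (int i = 1; i < r; ++i) {
      x = mulmod_u(x, x, n);
      if (x == n - 1) { comp = false; break; }
    }
    if (comp) return false;
  }
  return true;
}

static u64 inv_mod(u64 a, u64 m) { return powmod_u(a % m, m - 2, m); } // m prime

// ---------------------------------------------------------------------------
// Negacyclic NTT tables (Longa-Naehrig style, bit-reversed twiddle tables)
// ---------------------------------------------------------------------------

struct NttTab {
  u64 p = 0;
  size_t n = 0;
  std::vector<u64> psi_br, ipsi_br;
  u64 n_inv = 0;
};

static size_t bitrev(size_t x, int bits) {
  size_t r = 0;
  for (int i = 0; i < bits; ++i) { r = (r << 1) | (x & 1); x >>= 1; }
  return r;
}

// primitive 2n-th root of unity mod p (p = 1 mod 2n, 2n a power of two)
static u64 find_psi(u64 p, size_t n) {
  u64 exp = (p - 1) / (2 * (u64)n);
  for (u64 g = 2;; ++g) {
    u64 r = powmod_u(g, exp, p);
    if (r != 1 && powmod_u(r, (u64)n, p) == p - 1) return r;
    if (g > 10000) stop("failed to find primitive root");
  }
}

static NttTab make_ntt_tab(u64 p, size_t n) {
  NttTab T;
  T.p = p;
  T.n = n;
  int lg = 0;
  while (((size_t)1 << lg) < n) ++lg;
  u64 psi = find_psi(p, n);
  u64 ipsi = inv_mod(psi, p);
  T.psi_br.resize(n);
  T.ipsi_br.resize(n);
  u64 cur = 1, icur = 1;
  std::vector<u64> pw(n), ipw(n);
  for (size_t i = 0; i < n; ++i) {
    pw[i] = cur; ipw[i] = icur;
    cur = mulmod_u(cur, psi, p);
    icur = mulmod_u(icur, ipsi, p);
  }
  for (size_t i = 0; i < n; ++i) {
    T.psi_br[i] = pw[bitrev(i, lg)];
    T.ipsi_br[i] = ipw[bitrev(i, lg)];
  }
  T.n_inv = inv_mod((u64)n, p);
  return T;
}

static void ntt_fwd(std::vector<u64>& a, const NttTab& T) {
  const u64 p = T.p;
  size_t n = T.n, t = n;
  for (size_t m = 1; m < n; m <<= 1) {
    t >>= 1;
    for (size_t i = 0; i < m; ++i) {
      size_t j1 = 2 * i * t, j2 = j1 + t;
      u64 S = T.psi_br[m + i];
      for (size_t j = j1; j < j2; ++j) {
        u64 U = a[j];
        u64 V = mulmod_u(a[j + t], S, p);
        a[j] = addmod_u(U, V, p);
        a[j + t] = submod_u(U, V, p);
      }
    }
  }
}

static void ntt_inv(std::vector<u64>& a, const NttTab& T) {
  const u64 p = T.p;
  size_t n = T.n, t = 1;
  for (size_t m = n; m > 1; m >>= 1) {
    size_t j1 = 0, h = m >> 1;
    for (size_t i = 0; i < h; ++i) {
      size_t j2 = j1 + t;
      u64 S = T.ipsi_br[h + i];
      for (size_t j = j1; j < j2; ++j) {
        u64 U = a[j], V = a[j + t];
        a[j] = addmod_u(U, V, p);
        a[j + t] = mulmod_u(submod_u(U, V, p), S, p);
      }
      j1 += 2 * t;
    }
    t <<= 1;
  }
  for (size_t j = 0; j < n; ++j) a[j] = mulmod_u(a[j], T.n_inv, p);
}

// ---------------------------------------------------------------------------
// Context
// ---------------------------------------------------------------------------

struct BgvCtx {
  size_t n = 0;
  u64 t = 0;
  std::vector<u64> qs;
  NttTab ttab;
  std::vector<NttTab> qtabs;
  std::vector<u64> t_mod_q;               // t mod q_j
  std::vector<std::vector<u64>> Pmat;     // Pmat[i][j] = prod_{l<i} q_l mod q_j
  std::vector<u64> invP;                  // (Pmat[j][j])^{-1} mod q_j
  std::vector<u64> Pt;                    // prod_{l<i} q_l mod t
  std::vector<long double> Pld;           // prod_{l<i} q_l (float magnitude)
  std::vector<u64> halfq_dig;             // mixed-radix digits of (q-1)/2
  double logq2 = 0;
};

typedef std::vector<std::vector<u64>> RnsPoly; // [prime][coeff], NTT domain

struct BgvKeys {
  bool has_secret = false, has_public = false, has_relin = false;
  RnsPoly s;
  RnsPoly pk0, pk1;
  std::vector<RnsPoly> rk0, rk1; // decomposition index -> RnsPoly
};

struct BgvCipher {
  std::vector<RnsPoly> parts; // size 2 (c0,c1) or 3
};

// mixed-radix (Garner) digits of the CRT value with residues r[]
static void garner_digits(const BgvCtx& C, const std::vector<u64>& r,
                          std::vector<u64>& v) {
  size_t L = C.qs.size();
  for (size_t j = 0; j < L; ++j) {
    u64 qj = C.qs[j];
    u64 u = r[j] % qj;
    for (size_t i = 0; i < j; ++i)
      u = submod_u(u, mulmod_u(v[i] % qj, C.Pmat[i][j], qj), qj);
    v[j] = mulmod_u(u, C.invP[j], qj);
  }
}

// x <= (q-1)/2 given mixed-radix digits of x (most significant digit last)
static bool le_halfq(const BgvCtx& C, const std::vector<u64>& v) {
  size_t L = C.qs.size();
  for (size_t j = L; j-- > 0;) {
    if (v[j] < C.halfq_dig[j]) return true;
    if (v[j] > C.halfq_dig[j]) return false;
  }
  return true;
}

static BgvCtx* make_ctx(size_t n, u64 t, const std::vector<int>& coeff_bits) {
  BgvCtx* C = new BgvCtx();
  C->n = n;
  C->t = t;
  u64 two_n = 2 * (u64)n;
  // deterministic prime search per requested bit size, descending
  std::vector<u64> used;
  used.push_back(t);
  for (int b : coeff_bits) {
    if (b < 21 || b > 60) { delete C; stop("coefficient prime bits must be in [21, 60]"); }
    u64 hi = ((u64)1 << b) - 1;
    u64 k = (hi - 1) / two_n;
    u64 p = 0;
    for (; k > 0; --k) {
      u64 cand = k * two_n + 1;
      if (cand < ((u64)1 << (b - 1))) break;
      bool dup = false;
      for (u64 u : used) if (u == cand) dup = true;
      if (!dup && is_prime_u64(cand)) { p = cand; break; }
    }
    if (p == 0) { delete C; stop("no NTT prime of requested size"); }
    used.push_back(p);
    C->qs.push_back(p);
  }
  C->ttab = make_ntt_tab(t, n);
  size_t L = C->qs.size();
  for (size_t j = 0; j < L; ++j) {
    C->qtabs.push_back(make_ntt_tab(C->qs[j], n));
    C->t_mod_q.push_back(t % C->qs[j]);
    C->logq2 += std::log2((double)C->qs[j]);
  }
  // Garner precomputation
  C->Pmat.assign(L, std::vector<u64>(L));
  C->invP.resize(L);
  C->Pt.resize(L);
  C->Pld.resize(L);
  for (size_t i = 0; i < L; ++i) {
    for (size_t j = 0; j < L; ++j) {
      u64 prod = 1 % C->qs[j];
      for (size_t l = 0; l < i; ++l) prod = mulmod_u(prod, C->qs[l] % C->qs[j], C->qs[j]);
      C->Pmat[i][j] = prod;
    }
    C->invP[i] = inv_mod(C->Pmat[i][i], C->qs[i]);
    u64 pt = 1 % t;
    long double pld = 1.0L;
    for (size_t l = 0; l < i; ++l) { pt = mulmod_u(pt, C->qs[l] % t, t); pld *= (long double)C->qs[l]; }
    C->Pt[i] = pt;
    C->Pld[i] = pld;
  }
  // digits of (q-1)/2: residue mod q_j is (q_j - 1)/2
  std::vector<u64> hr(L);
  for (size_t j = 0; j < L; ++j) hr[j] = (C->qs[j] - 1) / 2;
  C->halfq_dig.resize(L);
  garner_digits(*C, hr, C->halfq_dig);
  return C;
}

// ---------------------------------------------------------------------------
// Sampling (R RNG)
// ---------------------------------------------------------------------------

static u64 sample_uniform(u64 m) {
  // two 32-bit draws; modulo bias is negligible for m >= 2^20
  u64 a = (u64)(unif_rand() * 4294967296.0);
  u64 b = (u64)(unif_rand() * 4294967296.0);
  if (a >= 4294967296ULL) a = 4294967295ULL;
  if (b >= 4294967296ULL) b = 4294967295ULL;
  return ((a << 32) | b) % m;
}

static void sample_ternary(std::vector<i64>& c) {
  for (size_t i = 0; i < c.size(); ++i) {
    double u = unif_rand();
    c[i] = u < 1.0 / 3.0 ? -1 : (u < 2.0 / 3.0 ? 0 : 1);
  }
}

static void sample_gauss(std::vector<i64>& c) {
  for (size_t i = 0; i < c.size(); ++i)
    c[i] = (i64)std::llround(norm_rand() * 3.2);
}

// signed coefficient vector -> RNS poly in NTT domain
static RnsPoly to_rns_ntt(const BgvCtx& C, const std::vector<i64>& c) {
  size_t L = C.qs.size();
  RnsPoly P(L, std::vector<u64>(C.n));
  for (size_t j = 0; j < L; ++j) {
    u64 qj = C.qs[j];
    for (size_t i = 0; i < C.n; ++i) {
      i64 x = c[i];
      P[j][i] = x >= 0 ? (u64)x % qj : qj - ((u64)(-x) % qj);
      if (P[j][i] == qj) P[j][i] = 0;
    }
    ntt_fwd(P[j], C.qtabs[j]);
  }
  return P;
}

static void poly_axpy(const BgvCtx& C, RnsPoly& acc, const RnsPoly& a,
                      const RnsPoly& b) {
  // acc += a (.) b, pointwise per prime
  for (size_t j = 0; j < C.qs.size(); ++j) {
    u64 qj = C.qs[j];
    for (size_t i = 0; i < C.n; ++i)
      acc[j][i] = addmod_u(acc[j][i], mulmod_u(a[j][i], b[j][i], qj), qj);
  }
}

// ---------------------------------------------------------------------------
// Exported API
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double bgv_find_plain_modulus(int n, int bits) {
  if (bits < 15 || bits > 30) stop("plain modulus bits must be in [15, 30]");
  u64 two_n = 2 * (u64)n;
  u64 lo = (u64)1 << (bits - 1);
  u64 k = lo / two_n + 1;
  for (;; ++k) {
    u64 cand = k * two_n + 1;
    if (cand >= ((u64)1 << bits)) stop("no batching prime of requested size");
    if (is_prime_u64(cand)) return (double)cand;
  }
}

// [[Rcpp::export]]
bool bgv_is_prime(double x) { return is_prime_u64((u64)x); }

// [[Rcpp::export]]
SEXP bgv_context_new(int n, double t, IntegerVector coeff_bits) {
  if (n < 1024 || (n & (n - 1)) != 0) stop("poly_degree must be a power of two >= 1024");
  u64 tt = (u64)t;
  if (!is_prime_u64(tt) || tt % (2 * (u64)n) != 1)
    stop("plain_modulus must be a prime = 1 (mod 2*poly_degree) for batching");
  std::vector<int> cb(coeff_bits.begin(), coeff_bits.end());
  BgvCtx* C = make_ctx((size_t)n, tt, cb);
  for (u64 q : C->qs) {
    if (q <= tt) { delete C; stop("coefficient primes must exceed plain_modulus"); }
  }
  XPtr<BgvCtx> p(C, true);
  return p;
}

// [[Rcpp::export]]
List bgv_context_info(SEXP ctx) {
  XPtr<BgvCtx> C(ctx);
  NumericVector qs(C->qs.size());
  for (size_t i = 0; i < C->qs.size(); ++i) qs[i] = (double)C->qs[i];
  return List::create(_["n"] = (double)C->n, _["t"] = (double)C->t,
                      _["q_primes"] = qs, _["log2_q"] = C->logq2);
}

// [[Rcpp::export]]
SEXP bgv_keygen(SEXP ctx) {
  XPtr<BgvCtx> C(ctx);
  size_t L = C->qs.size(), n = C->n;
  BgvKeys* K = new BgvKeys();
  std::vector<i64> sc(n), ec(n);
  sample_ternary(sc);
  K->s = to_rns_ntt(*C, sc);
  // public key: pk1 = a (uniform), pk0 = -(a s + t e)
  sample_gauss(ec);
  RnsPoly E = to_rns_ntt(*C, ec);
  K->pk1.assign(L, std::vector<u64>(n));
  K->pk0.assign(L, std::vector<u64>(n));
  for (size_t j = 0; j < L; ++j) {
    u64 qj = C->qs[j], tj = C->t_mod_q[j];
    for (size_t i = 0; i < n; ++i) K->pk1[j][i] = sample_uniform(qj);
    for (size_t i = 0; i < n; ++i) {
      u64 v = addmod_u(mulmod_u(K->pk1[j][i], K->s[j][i], qj),
                       mulmod_u(tj, E[j][i], qj), qj);
      K->pk0[j][i] = v == 0 ? 0 : qj - v;
    }
  }
  // relinearization keys (RNS decomposition): for decomposition index i,
  //   rk0_i = -(a_i s + t e_i) + f_i s^2   with f_i = 1 mod q_i, 0 mod q_j
  for (size_t d = 0; d < L; ++d) {
    std::vector<i64> ek(n);
    sample_gauss(ek);
    RnsPoly Ek = to_rns_ntt(*C, ek);
    RnsPoly a(L, std::vector<u64>(n)), k0(L, std::vector<u64>(n));
    for (size_t j = 0; j < L; ++j) {
      u64 qj = C->qs[j], tj = C->t_mod_q[j];
      for (size_t i = 0; i < n; ++i) a[j][i] = sample_uniform(qj);
      for (size_t i = 0; i < n; ++i) {
        u64 v = addmod_u(mulmod_u(a[j][i], K->s[j][i], qj),
                         mulmod_u(tj, Ek[j][i], qj), qj);
        v = v == 0 ? 0 : qj - v;
        if (j == d) {
          u64 s2 = mulmod_u(K->s[j][i], K->s[j][i], qj);
          v = addmod_u(v, s2, qj);
        }
        k0[j][i] = v;
      }
    }
    K->rk1.push_back(a);
    K->rk0.push_back(k0);
  }
  K->has_secret = K->has_public = K->has_relin = true;
  XPtr<BgvKeys> p(K, true);
  return p;
}

// [[Rcpp::export]]
SEXP bgv_encrypt(SEXP ctx, SEXP keys, NumericVector slots) {
  XPtr<BgvCtx> C(ctx);
  XPtr<BgvKeys> K(keys);
  if (!K->has_public) stop("keys lack a public key");
  size_t n = C->n, L = C->qs.size();
  if ((size_t)slots.size() > n) stop("vector longer than slot count");
  // encode: slot values -> plaintext polynomial (inverse NTT mod t)
  std::vector<u64> pm(n, 0);
  for (size_t i = 0; i < (size_t)slots.size(); ++i) {
    double v = slots[i];
    if (ISNAN(v) || v < 0 || v >= (double)C->t)
      stop("slot values must be integers in [0, plain_modulus)");
    pm[i] = (u64)v;
  }
  ntt_inv(pm, C->ttab);
  std::vector<i64> pmc(n), uc(n), e1(n), e2(n);
  for (size_t i = 0; i < n; ++i) pmc[i] = (i64)pm[i];
  sample_ternary(uc);
  sample_gauss(e1);
  sample_gauss(e2);
  RnsPoly PM = to_rns_ntt(*C, pmc), U = to_rns_ntt(*C, uc),
          E1 = to_rns_ntt(*C, e1), E2 = to_rns_ntt(*C, e2);
  BgvCipher* ct = new BgvCipher();
  ct->parts.assign(2, RnsPoly(L, std::vector<u64>(n)));
  for (size_t j = 0; j < L; ++j) {
    u64 qj = C->qs[j], tj = C->t_mod_q[j];
    for (size_t i = 0; i < n; ++i) {
      u64 c0 = addmod_u(mulmod_u(K->pk0[j][i], U[j][i], qj),
                        mulmod_u(tj, E1[j][i], qj), qj);
      ct->parts[0][j][i] = addmod_u(c0, PM[j][i], qj);
      ct->parts[1][j][i] = addmod_u(mulmod_u(K->pk1[j][i], U[j][i], qj),
                                    mulmod_u(tj, E2[j][i], qj), qj);
    }
  }
  XPtr<BgvCipher> p(ct, true);
  return p;
}

// noisy plaintext residues [c0 + c1 s (+ c2 s^2)]_q, coefficient domain
static std::vector<std::vector<u64>> noisy_plain(const BgvCtx& C,
                                                 const BgvKeys& K,
                                                 const BgvCipher& ct) {
  size_t L = C.qs.size(), n = C.n;
  std::vector<std::vector<u64>> d(L, std::vector<u64>(n));
  for (size_t j = 0; j < L; ++j) {
    u64 qj = C.qs[j];
    for (size_t i = 0; i < n; ++i) {
      u64 v = addmod_u(ct.parts[0][j][i],
                       mulmod_u(ct.parts[1][j][i], K.s[j][i], qj), qj);
      if (ct.parts.size() == 3) {
        u64 s2 = mulmod_u(K.s[j][i], K.s[j][i], qj);
        v = addmod_u(v, mulmod_u(ct.parts[2][j][i], s2, qj), qj);
      }
      d[j][i] = v;
    }
    ntt_inv(d[j], C.qtabs[j]);
  }
  return d;
}

// [[Rcpp::export]]
NumericVector bgv_decrypt(SEXP ctx, SEXP keys, SEXP cipher) {
  XPtr<BgvCtx> C(ctx);
  XPtr<BgvKeys> K(keys);
  XPtr<BgvCipher> ct(cipher);
  if (!K->has_secret) stop("keys lack the secret key");
  size_t L = C->qs.size(), n = C->n;
  std::vector<std::vector<u64>> d = noisy_plain(*C, *K, *ct);
  std::vector<u64> r(L), v(L), m(n);
  for (size_t i = 0; i < n; ++i) {
    for (size_t j = 0; j < L; ++j) r[j] = d[j][i];
    garner_digits(*C, r, v);
    if (le_halfq(*C, v)) {
      u64 acc = 0;
      for (size_t j = 0; j < L; ++j)
        acc = addmod_u(acc, mulmod_u(v[j] % C->t, C->Pt[j], C->t), C->t);
      m[i] = acc;
    } else {
      for (size_t j = 0; j < L; ++j) r[j] = r[j] == 0 ? 0 : C->qs[j] - r[j];
      garner_digits(*C, r, v);
      u64 acc = 0;
      for (size_t j = 0; j < L; ++j)
        acc = addmod_u(acc, mulmod_u(v[j] % C->t, C->Pt[j], C->t), C->t);
      m[i] = acc == 0 ? 0 : C->t - acc;
    }
  }
  // decode: plaintext polynomial -> slots (forward NTT mod t)
  ntt_fwd(m, C->ttab);
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = (double)m[i];
  return out;
}

// [[Rcpp::export]]
double bgv_noise_budget(SEXP ctx, SEXP keys, SEXP cipher) {
  XPtr<BgvCtx> C(ctx);
  XPtr<BgvKeys> K(keys);
  XPtr<BgvCipher> ct(cipher);
  if (!K->has_secret) stop("keys lack the secret key");
  size_t L = C->qs.size(), n = C->n;
  std::vector<std::vector<u64>> d = noisy_plain(*C, *K, *ct);
  std::vector<u64> r(L), v(L);
  long double maxmag = 1.0L;
  for (size_t i = 0; i < n; ++i) {
    for (size_t j = 0; j < L; ++j) r[j] = d[j][i];
    garner_digits(*C, r, v);
    if (!le_halfq(*C, v)) {
      for (size_t j = 0; j < L; ++j) r[j] = r[j] == 0 ? 0 : C->qs[j] - r[j];
      garner_digits(*C, r, v);
    }
    long double mag = 0.0L;
    for (size_t j = 0; j < L; ++j) mag += (long double)v[j] * C->Pld[j];
    if (mag > maxmag) maxmag = mag;
  }
  double b = C->logq2 - 1.0 - (double)std::log2((double)maxmag);
  if (b < 0) b = 0;
  return std::floor(b);
}

// [[Rcpp::export]]
SEXP bgv_add(SEXP ctx, SEXP a, SEXP b, bool subtract) {
  XPtr<BgvCtx> C(ctx);
  XPtr<BgvCipher> A(a), B(b);
  if (A->parts.size() != 2 || B->parts.size() != 2)
    stop("add/sub expects relinearized (size-2) ciphertexts");
  size_t L = C->qs.size(), n = C->n;
  BgvCipher* R = new BgvCipher();
  R->parts.assign(2, RnsPoly(L, std::vector<u64>(n)));
  for (size_t part = 0; part < 2; ++part)
    for (size_t j = 0; j < L; ++j) {
      u64 qj = C->qs[j];
      for (size_t i = 0; i < n; ++i)
        R->parts[part][j][i] =
            subtract ? submod_u(A->parts[part][j][i], B->parts[part][j][i], qj)
                     : addmod_u(A->parts[part][j][i], B->parts[part][j][i], qj);
    }
  XPtr<BgvCipher> p(R, true);
  return p;
}

// [[Rcpp::export]]
SEXP bgv_square_relin(SEXP ctx, SEXP keys, SEXP a) {
  XPtr<BgvCtx> C(ctx);
  XPtr<BgvKeys> K(keys);
  XPtr<BgvCipher> A(a);
  if (!K->has_relin) stop("keys lack relinearization keys");
  if (A->parts.size() != 2) stop("square expects a size-2 ciphertext");
  size_t L = C->qs.size(), n = C->n;
  // tensor square: (c0^2, 2 c0 c1, c1^2), pointwise in NTT domain
  RnsPoly d0(L, std::vector<u64>(n)), d1(L, std::vector<u64>(n)),
      d2(L, std::vector<u64>(n));
  for (size_t j = 0; j < L; ++j) {
    u64 qj = C->qs[j];
    for (size_t i = 0; i < n; ++i) {
      u64 c0 = A->parts[0][j][i], c1 = A->parts[1][j][i];
      d0[j][i] = mulmod_u(c0, c0, qj);
      u64 x = mulmod_u(c0, c1, qj);
      d1[j][i] = addmod_u(x, x, qj);
      d2[j][i] = mulmod_u(c1, c1, qj);
    }
  }
  // key switch d2 from s^2 to s via RNS decomposition
  for (size_t dcomp = 0; dcomp < L; ++dcomp) {
    std::vector<u64> coef = d2[dcomp];
    ntt_inv(coef, C->qtabs[dcomp]);
    u64 qd = C->qs[dcomp];
    // centered lift of the residue polynomial, re-reduced mod every prime
    RnsPoly Dp(L, std::vector<u64>(n));
    for (size_t j = 0; j < L; ++j) {
      u64 qj = C->qs[j];
      for (size_t i = 0; i < n; ++i) {
        u64 c = coef[i];
        if (c <= (qd - 1) / 2) {
          Dp[j][i] = c % qj;
        } else {
          u64 mag = qd - c;
          u64 mm = mag % qj;
          Dp[j][i] = mm == 0 ? 0 : qj - mm;
        }
      }
      ntt_fwd(Dp[j], C->qtabs[j]);
    }
    poly_axpy(*C, d0, Dp, K->rk0[dcomp]);
    poly_axpy(*C, d1, Dp, K->rk1[dcomp]);
  }
  BgvCipher* R = new BgvCipher();
  R->parts.push_back(d0);
  R->parts.push_back(d1);
  XPtr<BgvCipher> p(R, true);
  return p;
}

// [[Rcpp::export]]
int bgv_cipher_size(SEXP cipher) {
  XPtr<BgvCipher> ct(cipher);
  return (int)ct->parts.size();
}

// ---------------------------------------------------------------------------
// Serialization (little-endian u64 payloads)
// ---------------------------------------------------------------------------

static void push_u64(std::vector<uint8_t>& buf, u64 x) {
  for (int i = 0; i < 8; ++i) buf.push_back((uint8_t)(x >> (8 * i)));
}
static u64 read_u64(const uint8_t* p) {
  u64 x = 0;
  for (int i = 0; i < 8; ++i) x |= (u64)p[i] << (8 * i);
  return x;
}

static void push_poly(std::vector<uint8_t>& buf, const RnsPoly& P) {
  for (const auto& v : P)
    for (u64 x : v) push_u64(buf, x);
}
static RnsPoly read_poly(const uint8_t*& p, size_t L, size_t n) {
  RnsPoly P(L, std::vector<u64>(n));
  for (size_t j = 0; j < L; ++j)
    for (size_t i = 0; i < n; ++i) { P[j][i] = read_u64(p); p += 8; }
  return P;
}

// [[Rcpp::export]]
RawVector bgv_serialize_cipher(SEXP ctx, SEXP cipher) {
  XPtr<BgvCtx> C(ctx);
  XPtr<BgvCipher> ct(cipher);
  size_t L = C->qs.size(), n = C->n;
  std::vector<uint8_t> buf;
  push_u64(buf, 0x42475643u); // "BGVC"
  push_u64(buf, (u64)n);
  push_u64(buf, (u64)L);
  push_u64(buf, (u64)ct->parts.size());
  for (const auto& part : ct->parts) push_poly(buf, part);
  return RawVector(buf.begin(), buf.end());
}

// [[Rcpp::export]]
SEXP bgv_deserialize_cipher(SEXP ctx, RawVector raw) {
  XPtr<BgvCtx> C(ctx);
  size_t L = C->qs.size(), n = C->n;
  if ((size_t)raw.size() < 32) stop("truncated ciphertext blob");
  const uint8_t* p = (const uint8_t*)RAW(raw);
  if (read_u64(p) != 0x42475643u) stop("not a ciphertext blob");
  p += 8;
  if (read_u64(p) != (u64)n) stop("ciphertext degree does not match context");
  p += 8;
  if (read_u64(p) != (u64)L) stop("ciphertext RNS size does not match context");
  p += 8;
  size_t sz = (size_t)read_u64(p);
  p += 8;
  if ((size_t)raw.size() != 32 + sz * L * n * 8) stop("ciphertext blob size mismatch");
  BgvCipher* ct = new BgvCipher();
  for (size_t s = 0; s < sz; ++s) ct->parts.push_back(read_poly(p, L, n));
  XPtr<BgvCipher> xp(ct, true);
  return xp;
}

// which: "all" (secret+public+relin) or "eval" (relin only, server-safe)
// [[Rcpp::export]]
RawVector bgv_serialize_keys(SEXP ctx, SEXP keys, std::string which) {
  XPtr<BgvCtx> C(ctx);
  XPtr<BgvKeys> K(keys);
  size_t L = C->qs.size(), n = C->n;
  bool full = which == "all";
  if (!full && which != "eval") stop("which must be 'all' or 'eval'");
  std::vector<uint8_t> buf;
  push_u64(buf, 0x42475648u); // "BGVK"
  push_u64(buf, (u64)n);
  push_u64(buf, (u64)L);
  push_u64(buf, full ? 1 : 0);
  if (full) {
    push_poly(buf, K->s);
    push_poly(buf, K->pk0);
    push_poly(buf, K->pk1);
  }
  for (size_t d = 0; d < L; ++d) {
    push_poly(buf, K->rk0[d]);
    push_poly(buf, K->rk1[d]);
  }
  return RawVector(buf.begin(), buf.end());
}

// [[Rcpp::export]]
SEXP bgv_deserialize_keys(SEXP ctx, RawVector raw) {
  XPtr<BgvCtx> C(ctx);
  size_t L = C->qs.size(), n = C->n;
  const uint8_t* p = (const uint8_t*)RAW(raw);
  if ((size_t)raw.size() < 32 || read_u64(p) != 0x42475648u)
    stop("not a key blob");
  p += 8;
  if (read_u64(p) != (u64)n) stop("key degree does not match context");
  p += 8;
  if (read_u64(p) != (u64)L) stop("key RNS size does not match context");
  p += 8;
  bool full = read_u64(p) == 1;
  p += 8;
  size_t need = 32 + (full ? 3 : 0) * L * n * 8 + 2 * L * L * n * 8;
  if ((size_t)raw.size() != need) stop("key blob size mismatch");
  BgvKeys* K = new BgvKeys();
  if (full) {
    K->s = read_poly(p, L, n);
    K->pk0 = read_poly(p, L, n);
    K->pk1 = read_poly(p, L, n);
    K->has_secret = K->has_public = true;
  }
  for (size_t d = 0; d < L; ++d) {
    K->rk0.push_back(read_poly(p, L, n));
    K->rk1.push_back(read_poly(p, L, n));
  }
  K->has_relin = true;
  XPtr<BgvKeys> xp(K, true);
  return xp;
}

// [[Rcpp::export]]
bool bgv_keys_have_secret(SEXP keys) {
  XPtr<BgvKeys> K(keys);
  return K->has_secret;
}
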