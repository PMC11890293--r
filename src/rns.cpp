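// Exact arithmetic for R_q = Z_q[x]/(x^n + 1) with q a product of
// word-sized NTT-friendly primes (residue number system).  All values are
// carried to R as numeric matrices (rows = primes, columns = coefficients);
// every entry is an integer < 2^53 and therefore exact in a double.
//
// Multi-precision steps (base extension between RNS bases, gadget digit
// extraction, decryption scaling, noise measurement) go through Garner's
// mixed-radix reconstruction so they are exact, never floating-point
// estimates.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <map>
#include <cmath>

using namespace Rcpp;

typedef uint64_t u64;
typedef unsigned __int128 u128;

static inline u64 addmod(u64 a, u64 b, u64 p) { u64 s = a + b; return s >= p ? s - p : s; }
static inline u64 submod(u64 a, u64 b, u64 p) { return a >= b ? a - b : a + p - b; }
static inline u64 mulmod(u64 a, u64 b, u64 p) { return (u64)((u128)a * b % p); }

static u64 powmod(u64 a, u64 e, u64 p) {
  u64 r = 1; a %= p;
  while (e) { if (e & 1) r = mulmod(r, a, p); a = mulmod(a, a, p); e >>= 1; }
  return r;
}
static u64 invmod(u64 a, u64 p) { return powmod(a % p, p - 2, p); } // p prime

// ---------------------------------------------------------------------------
// Primality (deterministic Miller-Rabin, valid far beyond 2^53)

static bool miller_rabin(u64 n) {
  if (n < 2) return false;
  for (u64 p : {2ULL, 3ULL, 5ULL, 7ULL, 11ULL, 13ULL, 17ULL, 19ULL, 23ULL, 29ULL, 31ULL, 37ULL}) {
    if (n % p == 0) return n == p;
  }
  u64 d = n - 1; int s = 0;
  while ((d & 1) == 0) { d >>= 1; ++s; }
  for (u64 a : {2ULL, 3ULL, 5ULL, 7ULL, 11ULL, 13ULL, 17ULL, 19ULL, 23ULL, 29ULL, 31ULL, 37ULL}) {
    u64 x = powmod(a, d, n);
    if (x == 1 || x == n - 1) continue;
    bool comp = true;
    for (int r = 1; r < s; ++r) {
      x = mulmod(x, x, n);
      if (x == n - 1) { comp = false; break; }
    }
    if (comp) return false;
  }
  return true;
}

// [[Rcpp::export]]
bool cpp_is_prime(double x) { return miller_rabin((u64)llround(x)); }

// Largest `count` primes p < 2^bits with p = 1 (mod twon), skipping `avoid`.
// [[Rcpp::export]]
NumericVector cpp_find_primes_below(double bits, double twon, int count, NumericVector avoid) {
  u64 m = (u64)llround(twon);
  u64 top = (u64)1 << (int)llround(bits);
  // largest x <= top with x = 1 (mod m); m is a power of two dividing top,
  // so this is top - m + 1 < top
  u64 p = top - ((top - 1) % m);
  std::vector<u64> found;
  std::vector<u64> av;
  for (double a : avoid) av.push_back((u64)llround(a));
  while ((int)found.size() < count) {
    if (p < m + 2) stop("prime search exhausted");
    bool skip = false;
    for (u64 a : av) if (a == p) skip = true;
    if (!skip && miller_rabin(p)) found.push_back(p);
    p -= m;
  }
  NumericVector out(count);
  for (int i = 0; i < count; ++i) out[i] = (double)found[i];
  return out;
}

// Smallest prime p >= start with p = 1 (mod twon).
// [[Rcpp::export]]
double cpp_next_prime_congruent(double start, double twon) {
  u64 m = (u64)llround(twon);
  u64 s = (u64)llround(start);
  u64 p = s + ((s % m <= 1) ? (1 - s % m) : (m + 1 - s % m));
  while (!miller_rabin(p)) p += m;
  if (p >= ((u64)1 << 53)) stop("prime search left exact-double range");
  return (double)p;
}

// ---------------------------------------------------------------------------
// Negacyclic NTT with cached tables per (prime, n)

struct NttTables {
  std::vector<u64> psi_rev, ipsi_rev;
  u64 ninv;
};

static std::map<std::pair<u64, int>, NttTables> g_ntt_cache;

static u64 find_psi(u64 p, int n) {
  // primitive 2n-th root of unity mod p (n a power of two, p = 1 mod 2n)
  if ((p - 1) % (2 * (u64)n) != 0)
    stop("parameter set has no 2n-th primitive root of unity (need p = 1 mod 2n)");
  u64 exp = (p - 1) / (2 * (u64)n);
  for (u64 g = 2;; ++g) {
    u64 cand = powmod(g, exp, p);
    if (powmod(cand, (u64)n, p) == p - 1) return cand;
    if (g > 10000) stop("failed to find primitive root");
  }
}

static const NttTables& get_tables(u64 p, int n) {
  auto key = std::make_pair(p, n);
  auto it = g_ntt_cache.find(key);
  if (it != g_ntt_cache.end()) return it->second;
  NttTables tb;
  u64 psi = find_psi(p, n);
  u64 ipsi = invmod(psi, p);
  int lg = 0; while ((1 << lg) < n) ++lg;
  tb.psi_rev.resize(n); tb.ipsi_rev.resize(n);
  u64 w = 1, iw = 1;
  for (int i = 0; i < n; ++i) {
    int r = 0;
    for (int b = 0; b < lg; ++b) if (i & (1 << b)) r |= 1 << (lg - 1 - b);
    tb.psi_rev[r] = w; tb.ipsi_rev[r] = iw;
    w = mulmod(w, psi, p); iw = mulmod(iw, ipsi, p);
  }
  tb.ninv = invmod((u64)n, p);
  auto res = g_ntt_cache.emplace(key, std::move(tb));
  return res.first->second;
}

static void ntt_fwd(u64* a, int n, const NttTables& tb, u64 p) {
  int t = n;
  for (int m = 1; m < n; m <<= 1) {
    t >>= 1;
    for (int i = 0; i < m; ++i) {
      int j1 = 2 * i * t, j2 = j1 + t;
      u64 S = tb.psi_rev[m + i];
      for (int j = j1; j < j2; ++j) {
        u64 U = a[j], V = mulmod(a[j + t], S, p);
        a[j] = addmod(U, V, p); a[j + t] = submod(U, V, p);
      }
    }
  }
}

static void ntt_inv(u64* a, int n, const NttTables& tb, u64 p) {
  int t = 1;
  for (int m = n; m > 1; m >>= 1) {
    int j1 = 0, h = m >> 1;
    for (int i = 0; i < h; ++i) {
      int j2 = j1 + t;
      u64 S = tb.ipsi_rev[h + i];
      for (int j = j1; j < j2; ++j) {
        u64 U = a[j], V = a[j + t];
        a[j] = addmod(U, V, p);
        a[j + t] = mulmod(submod(U, V, p), S, p);
      }
      j1 += 2 * t;
    }
    t <<= 1;
  }
  for (int j = 0; j < n; ++j) a[j] = mulmod(a[j], tb.ninv, p);
}

static std::vector<u64> primes_vec(const NumericVector& primes) {
  std::vector<u64> p(primes.size());
  for (int i = 0; i < primes.size(); ++i) p[i] = (u64)llround(primes[i]);
  return p;
}

// [[Rcpp::export]]
NumericMatrix cpp_ntt(NumericMatrix x, NumericVector primes, bool inverse) {
  int k = x.nrow(), n = x.ncol();
  if (k != primes.size()) stop("row/prime mismatch");
  std::vector<u64> p = primes_vec(primes);
  NumericMatrix out(k, n);
  std::vector<u64> buf(n);
  for (int r = 0; r < k; ++r) {
    const NttTables& tb = get_tables(p[r], n);
    for (int c = 0; c < n; ++c) buf[c] = (u64)llround(x(r, c));
    if (inverse) ntt_inv(buf.data(), n, tb, p[r]);
    else ntt_fwd(buf.data(), n, tb, p[r]);
    for (int c = 0; c < n; ++c) out(r, c) = (double)buf[c];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_pointwise_mul(NumericMatrix a, NumericMatrix b, NumericVector primes) {
  int k = a.nrow(), n = a.ncol();
  if (b.nrow() != k || b.ncol() != n) stop("dimension mismatch");
  std::vector<u64> p = primes_vec(primes);
  NumericMatrix out(k, n);
  for (int r = 0; r < k; ++r)
    for (int c = 0; c < n; ++c)
      out(r, c) = (double)mulmod((u64)llround(a(r, c)), (u64)llround(b(r, c)), p[r]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_negacyclic_mul(NumericMatrix a, NumericMatrix b, NumericVector primes) {
  int k = a.nrow(), n = a.ncol();
  if (b.nrow() != k || b.ncol() != n) stop("dimension mismatch");
  std::vector<u64> p = primes_vec(primes);
  NumericMatrix out(k, n);
  std::vector<u64> ba(n), bb(n);
  for (int r = 0; r < k; ++r) {
    const NttTables& tb = get_tables(p[r], n);
    for (int c = 0; c < n; ++c) { ba[c] = (u64)llround(a(r, c)); bb[c] = (u64)llround(b(r, c)); }
    ntt_fwd(ba.data(), n, tb, p[r]); ntt_fwd(bb.data(), n, tb, p[r]);
    for (int c = 0; c < n; ++c) ba[c] = mulmod(ba[c], bb[c], p[r]);
    ntt_inv(ba.data(), n, tb, p[r]);
    for (int c = 0; c < n; ++c) out(r, c) = (double)ba[c];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_mat_add(NumericMatrix a, NumericMatrix b, NumericVector primes) {
  int k = a.nrow(), n = a.ncol();
  std::vector<u64> p = primes_vec(primes);
  NumericMatrix out(k, n);
  for (int r = 0; r < k; ++r)
    for (int c = 0; c < n; ++c)
      out(r, c) = (double)addmod((u64)llround(a(r, c)), (u64)llround(b(r, c)), p[r]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_mat_sub(NumericMatrix a, NumericMatrix b, NumericVector primes) {
  int k = a.nrow(), n = a.ncol();
  std::vector<u64> p = primes_vec(primes);
  NumericMatrix out(k, n);
  for (int r = 0; r < k; ++r)
    for (int c = 0; c < n; ++c)
      out(r, c) = (double)submod((u64)llround(a(r, c)), (u64)llround(b(r, c)), p[r]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_mat_neg(NumericMatrix a, NumericVector primes) {
  int k = a.nrow(), n = a.ncol();
  std::vector<u64> p = primes_vec(primes);
  NumericMatrix out(k, n);
  for (int r = 0; r < k; ++r)
    for (int c = 0; c < n; ++c)
      out(r, c) = (double)submod(0, (u64)llround(a(r, c)), p[r]);
  return out;
}

// scalar may be length 1 (integer, possibly negative, |s| < 2^53) or
// length k (per-prime residues)
// [[Rcpp::export]]
NumericMatrix cpp_scalar_mul(NumericMatrix a, NumericVector s, NumericVector primes) {
  int k = a.nrow(), n = a.ncol();
  std::vector<u64> p = primes_vec(primes);
  std::vector<u64> sr(k);
  if (s.size() == 1) {
    long long v = (long long)llround(s[0]);
    for (int r = 0; r < k; ++r) {
      long long m = v % (long long)p[r];
      if (m < 0) m += (long long)p[r];
      sr[r] = (u64)m;
    }
  } else if (s.size() == k) {
    for (int r = 0; r < k; ++r) sr[r] = (u64)llround(s[r]);
  } else stop("scalar length must be 1 or k");
  NumericMatrix out(k, n);
  for (int r = 0; r < k; ++r)
    for (int c = 0; c < n; ++c)
      out(r, c) = (double)mulmod((u64)llround(a(r, c)), sr[r], p[r]);
  return out;
}

// ---------------------------------------------------------------------------
// Garner mixed-radix machinery

struct MixedCtx {
  std::vector<u64> p;
  std::vector<std::vector<u64>> inv;   // inv[j][i] = p_j^{-1} mod p_i (j < i)
  std::vector<u64> half;               // limbs of floor(prod/2)
  std::vector<u64> prod;               // limbs of prod
  double bits;                         // exact bit length of prod
};

static std::map<std::vector<u64>, MixedCtx> g_mixed_cache;

static void limbs_muladd(std::vector<u64>& L, u64 m, u64 add) {
  u128 carry = add;
  for (size_t i = 0; i < L.size(); ++i) {
    u128 cur = (u128)L[i] * m + carry;
    L[i] = (u64)cur; carry = cur >> 64;
  }
  while (carry) { L.push_back((u64)carry); carry >>= 64; }
}

static int limbs_cmp(const std::vector<u64>& a, const std::vector<u64>& b) {
  size_t n = std::max(a.size(), b.size());
  for (size_t i = n; i-- > 0;) {
    u64 x = i < a.size() ? a[i] : 0, y = i < b.size() ? b[i] : 0;
    if (x != y) return x < y ? -1 : 1;
  }
  return 0;
}

static void limbs_sub(std::vector<u64>& a, const std::vector<u64>& b) { // a -= b, a >= b
  u64 borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    u64 y = i < b.size() ? b[i] : 0;
    u64 t = a[i] - y;
    u64 b1 = a[i] < y ? 1 : 0;
    u64 t2 = t - borrow;
    u64 b2 = t < borrow ? 1 : 0;
    a[i] = t2;
    borrow = b1 | b2;
  }
}

static const MixedCtx& get_mixed(const std::vector<u64>& p) {
  auto it = g_mixed_cache.find(p);
  if (it != g_mixed_cache.end()) return it->second;
  MixedCtx cx; cx.p = p;
  int k = p.size();
  cx.inv.assign(k, std::vector<u64>(k, 0));
  for (int j = 0; j < k; ++j)
    for (int i = j + 1; i < k; ++i)
      cx.inv[j][i] = invmod(p[j] % p[i], p[i]);
  cx.prod.assign(1, 1);
  for (int i = 0; i < k; ++i) limbs_muladd(cx.prod, p[i], 0);
  cx.half = cx.prod;
  // floor(prod/2): shift right by one bit
  for (size_t i = 0; i + 1 < cx.half.size(); ++i)
    cx.half[i] = (cx.half[i] >> 1) | (cx.half[i + 1] << 63);
  cx.half.back() >>= 1;
  // exact-ish bit length
  int top = cx.prod.size() - 1;
  while (top > 0 && cx.prod[top] == 0) --top;
  double b = 64.0 * top + std::log2((double)cx.prod[top] + 1.0);
  cx.bits = b;
  auto res = g_mixed_cache.emplace(p, std::move(cx));
  return res.first->second;
}

// mixed-radix digits a[] of the canonical representative
static inline void garner_digits(const MixedCtx& cx, const u64* x, u64* a) {
  int k = cx.p.size();
  for (int i = 0; i < k; ++i) {
    u64 t = x[i];
    for (int j = 0; j < i; ++j) {
      t = submod(t, a[j] % cx.p[i], cx.p[i]);
      t = mulmod(t, cx.inv[j][i], cx.p[i]);
    }
    a[i] = t;
  }
}

// canonical value mod m from mixed-radix digits (Horner, innermost first)
static inline u64 mixed_eval_mod(const MixedCtx& cx, const u64* a, u64 m,
                                 const u64* p_mod_m) {
  int k = cx.p.size();
  u64 val = a[k - 1] % m;
  for (int i = k - 2; i >= 0; --i)
    val = addmod(mulmod(val, p_mod_m[i], m), a[i] % m, m);
  return val;
}

static void limbs_from_digits(const MixedCtx& cx, const u64* a, std::vector<u64>& L) {
  int k = cx.p.size();
  L.assign(1, a[k - 1]);
  for (int i = k - 2; i >= 0; --i) limbs_muladd(L, cx.p[i], a[i]);
}

// is canonical value (given as mixed-radix digits) > prod/2 ?
static bool digits_above_half(const MixedCtx& cx, const u64* a, std::vector<u64>& scratch) {
  limbs_from_digits(cx, a, scratch);
  return limbs_cmp(scratch, cx.half) > 0;
}

// ---------------------------------------------------------------------------
// Base extension (exact, centered representative)

// [[Rcpp::export]]
NumericMatrix cpp_lift(NumericMatrix x, NumericVector from, NumericVector to) {
  std::vector<u64> pf = primes_vec(from), pt = primes_vec(to);
  const MixedCtx& cx = get_mixed(pf);
  int k = pf.size(), kt = pt.size(), n = x.ncol();
  if (x.nrow() != k) stop("row/prime mismatch");
  std::vector<std::vector<u64>> pmod(kt, std::vector<u64>(k));
  std::vector<u64> qmod(kt);
  for (int j = 0; j < kt; ++j) {
    u64 acc = 1;
    for (int i = 0; i < k; ++i) { pmod[j][i] = pf[i] % pt[j]; acc = mulmod(acc, pmod[j][i], pt[j]); }
    qmod[j] = acc;
  }
  NumericMatrix out(kt, n);
  std::vector<u64> xs(k), dg(k), scratch;
  for (int c = 0; c < n; ++c) {
    for (int i = 0; i < k; ++i) xs[i] = (u64)llround(x(i, c));
    garner_digits(cx, xs.data(), dg.data());
    bool neg = digits_above_half(cx, dg.data(), scratch);
    for (int j = 0; j < kt; ++j) {
      u64 v = mixed_eval_mod(cx, dg.data(), pt[j], pmod[j].data());
      if (neg) v = submod(v, qmod[j], pt[j]);
      out(j, c) = (double)v;
    }
  }
  return out;
}

// round(t * X / q) in the q basis, where X is carried (centered) in the
// concatenated basis [q_primes, aux_primes].
// [[Rcpp::export]]
NumericMatrix cpp_scale_round(NumericMatrix x, NumericVector qprimes,
                              NumericVector auxprimes, double tt) {
  std::vector<u64> pq = primes_vec(qprimes), pa = primes_vec(auxprimes);
  const MixedCtx& cq = get_mixed(pq);
  const MixedCtx& ca = get_mixed(pa);
  int kq = pq.size(), ka = pa.size(), n = x.ncol();
  if (x.nrow() != kq + ka) stop("row/prime mismatch");
  u64 t = (u64)llround(tt);
  // tables: q primes mod aux primes (and product), inverse of q mod aux,
  // aux primes mod q primes (and product)
  std::vector<std::vector<u64>> pq_mod_a(ka, std::vector<u64>(kq));
  std::vector<u64> q_mod_a(ka), qinv_a(ka);
  for (int j = 0; j < ka; ++j) {
    u64 acc = 1;
    for (int i = 0; i < kq; ++i) { pq_mod_a[j][i] = pq[i] % pa[j]; acc = mulmod(acc, pq_mod_a[j][i], pa[j]); }
    q_mod_a[j] = acc; qinv_a[j] = invmod(acc, pa[j]);
  }
  std::vector<std::vector<u64>> pa_mod_q(kq, std::vector<u64>(ka));
  std::vector<u64> a_mod_q(kq);
  for (int i = 0; i < kq; ++i) {
    u64 acc = 1;
    for (int j = 0; j < ka; ++j) { pa_mod_q[i][j] = pa[j] % pq[i]; acc = mulmod(acc, pa_mod_q[i][j], pq[i]); }
    a_mod_q[i] = acc;
  }
  NumericMatrix out(kq, n);
  std::vector<u64> wq(kq), wa(ka), dq(kq), da(ka), ya(ka), scratch;
  for (int c = 0; c < n; ++c) {
    for (int i = 0; i < kq; ++i) wq[i] = mulmod(t, (u64)llround(x(i, c)), pq[i]);
    for (int j = 0; j < ka; ++j) wa[j] = mulmod(t, (u64)llround(x(kq + j, c)), pa[j]);
    // r = centered remainder of w mod q, extended to the aux basis
    garner_digits(cq, wq.data(), dq.data());
    bool negR = digits_above_half(cq, dq.data(), scratch);
    for (int j = 0; j < ka; ++j) {
      u64 r = mixed_eval_mod(cq, dq.data(), pa[j], pq_mod_a[j].data());
      if (negR) r = submod(r, q_mod_a[j], pa[j]);
      ya[j] = mulmod(submod(wa[j], r, pa[j]), qinv_a[j], pa[j]);
    }
    // y = (w - r)/q is exact in the aux basis; bring it back to the q basis
    garner_digits(ca, ya.data(), da.data());
    bool negY = digits_above_half(ca, da.data(), scratch);
    for (int i = 0; i < kq; ++i) {
      u64 v = mixed_eval_mod(ca, da.data(), pq[i], pa_mod_q[i].data());
      if (negY) v = submod(v, a_mod_q[i], pq[i]);
      out(i, c) = (double)v;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Decryption scaling and noise measurement

static long double limbs_to_ld(const std::vector<u64>& L) {
  int top = L.size() - 1;
  while (top > 0 && L[top] == 0) --top;
  long double v = 0.0L;
  for (int i = top; i >= 0 && i >= top - 2; --i)
    v = v * 18446744073709551616.0L + (long double)L[i];
  int below = top >= 2 ? top - 2 : 0;
  return ldexpl(v, 64 * below);
}

// per-coefficient round(t * centered(X) / q) reduced to [0, t)
// [[Rcpp::export]]
NumericVector cpp_decrypt_scale(NumericMatrix v, NumericVector qprimes, double tt) {
  std::vector<u64> pq = primes_vec(qprimes);
  const MixedCtx& cq = get_mixed(pq);
  int k = pq.size(), n = v.ncol();
  long long t = (long long)llround(tt);
  long double q_ld = limbs_to_ld(cq.prod);
  NumericVector out(n);
  std::vector<u64> xs(k), dg(k), L, mag;
  for (int c = 0; c < n; ++c) {
    for (int i = 0; i < k; ++i) xs[i] = (u64)llround(v(i, c));
    garner_digits(cq, xs.data(), dg.data());
    limbs_from_digits(cq, dg.data(), L);
    long long m;
    if (limbs_cmp(L, cq.half) > 0) {
      mag = cq.prod; limbs_sub(mag, L);
      m = -llroundl((long double)t * limbs_to_ld(mag) / q_ld);
    } else {
      m = llroundl((long double)t * limbs_to_ld(L) / q_ld);
    }
    m %= t; if (m < 0) m += t;
    out[c] = (double)m;
  }
  return out;
}

// per-coefficient log2 |centered(X)| (exact limb magnitude); -Inf for zero
// [[Rcpp::export]]
NumericVector cpp_noise_bits(NumericMatrix v, NumericVector primes) {
  std::vector<u64> pq = primes_vec(primes);
  const MixedCtx& cq = get_mixed(pq);
  int k = pq.size(), n = v.ncol();
  NumericVector out(n);
  std::vector<u64> xs(k), dg(k), L, mag;
  for (int c = 0; c < n; ++c) {
    for (int i = 0; i < k; ++i) xs[i] = (u64)llround(v(i, c));
    garner_digits(cq, xs.data(), dg.data());
    limbs_from_digits(cq, dg.data(), L);
    if (limbs_cmp(L, cq.half) > 0) { mag = cq.prod; limbs_sub(mag, L); }
    else mag = L;
    bool zero = true;
    for (u64 w : mag) if (w) { zero = false; break; }
    out[c] = zero ? R_NegInf : (double)log2l(limbs_to_ld(mag));
  }
  return out;
}

// Delta = floor(q/t) as per-prime residues: q = 0 mod p_i, so
// Delta = -(q mod t) * t^{-1} mod p_i
// [[Rcpp::export]]
NumericVector cpp_delta_mod(NumericVector qprimes, double tt) {
  std::vector<u64> pq = primes_vec(qprimes);
  u64 t = (u64)llround(tt);
  u64 qmt = 1;
  for (u64 p : pq) qmt = mulmod(qmt, p % t, t);
  NumericVector out(pq.size());
  for (size_t i = 0; i < pq.size(); ++i) {
    u64 p = pq[i];
    u64 v = mulmod(submod(0, qmt % p, p), invmod(t % p, p), p);
    out[i] = (double)v;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_q_mod(NumericVector qprimes, double m) {
  std::vector<u64> pq = primes_vec(qprimes);
  u64 mm = (u64)llround(m), acc = 1;
  for (u64 p : pq) acc = mulmod(acc, p % mm, mm);
  return (double)acc;
}

// exact bit length of q = prod(primes)
// [[Rcpp::export]]
double cpp_q_bits(NumericVector qprimes) {
  std::vector<u64> pq = primes_vec(qprimes);
  const MixedCtx& cq = get_mixed(pq);
  int top = cq.prod.size() - 1;
  while (top > 0 && cq.prod[top] == 0) --top;
  u64 h = cq.prod[top];
  int b = 0; while (h) { h >>= 1; ++b; }
  return 64.0 * top + b;
}

// ---------------------------------------------------------------------------
// Gadget decomposition: base-2^logbase digits of the canonical representative

static inline u64 limb_bits(const std::vector<u64>& L, int lo, int width) {
  int w = lo / 64, off = lo % 64;
  u64 v = (w < (int)L.size()) ? (L[w] >> off) : 0;
  if (off + width > 64 && w + 1 < (int)L.size()) v |= L[w + 1] << (64 - off);
  return v & (((u64)1 << width) - 1);
}

// [[Rcpp::export]]
List cpp_gadget_decompose(NumericMatrix x, NumericVector primes, int logbase, int ndigits) {
  std::vector<u64> pq = primes_vec(primes);
  const MixedCtx& cq = get_mixed(pq);
  int k = pq.size(), n = x.ncol();
  List out(ndigits);
  std::vector<NumericMatrix> mats;
  for (int j = 0; j < ndigits; ++j) mats.push_back(NumericMatrix(k, n));
  std::vector<u64> xs(k), dg(k), L;
  for (int c = 0; c < n; ++c) {
    for (int i = 0; i < k; ++i) xs[i] = (u64)llround(x(i, c));
    garner_digits(cq, xs.data(), dg.data());
    limbs_from_digits(cq, dg.data(), L);
    for (int j = 0; j < ndigits; ++j) {
      u64 d = limb_bits(L, j * logbase, logbase);
      for (int r = 0; r < k; ++r) mats[j](r, c) = (double)d;
    }
  }
  for (int j = 0; j < ndigits; ++j) out[j] = mats[j];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gadget_recompose(List digs, NumericVector primes, int logbase) {
  std::vector<u64> pq = primes_vec(primes);
  int k = pq.size();
  NumericMatrix first = digs[0];
  int n = first.ncol();
  u64 B = (u64)1 << logbase;
  NumericMatrix out(k, n);
  std::vector<u64> pw(k, 1);
  for (int j = 0; j < digs.size(); ++j) {
    NumericMatrix d = digs[j];
    for (int r = 0; r < k; ++r)
      for (int c = 0; c < n; ++c)
        out(r, c) = (double)addmod((u64)llround(out(r, c)),
                                   mulmod((u64)llround(d(r, c)), pw[r], pq[r]), pq[r]);
    for (int r = 0; r < k; ++r) pw[r] = mulmod(pw[r], B % pq[r], pq[r]);
  }
  return out;
}

// Decompose c once, then for each key matrix K (stacked: row j*k + r is
// digit j, prime r, already in the NTT domain) return
// InvNTT( sum_j NTT(digit_j) o K[j] ).
// [[Rcpp::export]]
List cpp_gadget_inner(NumericMatrix cmat, List keymats, NumericVector primes,
                      int logbase, int ndigits) {
  std::vector<u64> pq = primes_vec(primes);
  const MixedCtx& cq = get_mixed(pq);
  int k = pq.size(), n = cmat.ncol();
  int L = keymats.size();
  // digits of every coefficient
  std::vector<std::vector<u64>> dig(ndigits, std::vector<u64>(n));
  std::vector<u64> xs(k), dg(k), lim;
  for (int c = 0; c < n; ++c) {
    for (int i = 0; i < k; ++i) xs[i] = (u64)llround(cmat(i, c));
    garner_digits(cq, xs.data(), dg.data());
    limbs_from_digits(cq, dg.data(), lim);
    for (int j = 0; j < ndigits; ++j) dig[j][c] = limb_bits(lim, j * logbase, logbase);
  }
  std::vector<std::vector<std::vector<u64>>> acc(
      L, std::vector<std::vector<u64>>(k, std::vector<u64>(n, 0)));
  std::vector<const double*> kptr(L);
  std::vector<int> knrow(L);
  std::vector<NumericMatrix> kms;
  for (int l = 0; l < L; ++l) {
    NumericMatrix km = keymats[l];
    if (km.nrow() != ndigits * k || km.ncol() != n) stop("key matrix dimension mismatch");
    kms.push_back(km);
  }
  std::vector<u64> buf(n);
  for (int j = 0; j < ndigits; ++j) {
    for (int r = 0; r < k; ++r) {
      const NttTables& tb = get_tables(pq[r], n);
      for (int c = 0; c < n; ++c) buf[c] = dig[j][c] % pq[r];
      ntt_fwd(buf.data(), n, tb, pq[r]);
      for (int l = 0; l < L; ++l) {
        NumericMatrix& km = kms[l];
        int row = j * k + r;
        for (int c = 0; c < n; ++c)
          acc[l][r][c] = addmod(acc[l][r][c],
                                mulmod(buf[c], (u64)llround(km(row, c)), pq[r]), pq[r]);
      }
    }
  }
  List out(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix m(k, n);
    for (int r = 0; r < k; ++r) {
      const NttTables& tb = get_tables(pq[r], n);
      ntt_inv(acc[l][r].data(), n, tb, pq[r]);
      for (int c = 0; c < n; ++c) m(r, c) = (double)acc[l][r][c];
    }
    out[l] = m;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Deterministic samplers (splitmix64)

struct Sm64 { u64 s; };
static inline u64 sm_next(Sm64& g) {
  u64 z = (g.s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// uniform element of R_q: independent uniform residue per prime row
// [[Rcpp::export]]
NumericMatrix cpp_sample_uniform(double seed, NumericVector primes, int n) {
  std::vector<u64> pq = primes_vec(primes);
  Sm64 g{(u64)llround(seed)};
  int k = pq.size();
  NumericMatrix out(k, n);
  for (int r = 0; r < k; ++r) {
    u64 p = pq[r];
    int bits = 0; u64 h = p - 1; while (h) { h >>= 1; ++bits; }
    u64 mask = (bits >= 64) ? ~0ULL : (((u64)1 << bits) - 1);
    for (int c = 0; c < n; ++c) {
      u64 v;
      do { v = sm_next(g) & mask; } while (v >= p);
      out(r, c) = (double)v;
    }
  }
  return out;
}

// ternary {-1, 0, 1} polynomial, residues per prime row
// [[Rcpp::export]]
NumericMatrix cpp_sample_ternary(double seed, int n, NumericVector primes) {
  std::vector<u64> pq = primes_vec(primes);
  Sm64 g{(u64)llround(seed)};
  int k = pq.size();
  NumericMatrix out(k, n);
  for (int c = 0; c < n; ++c) {
    u64 v;
    do { v = sm_next(g) & 3; } while (v == 3);
    long long coef = (long long)v - 1;
    for (int r = 0; r < k; ++r)
      out(r, c) = (double)(coef < 0 ? pq[r] - 1 : (u64)coef);
  }
  return out;
}

// rounded continuous Gaussian with rejection beyond 6*sigma
// [[Rcpp::export]]
NumericMatrix cpp_sample_gauss(double seed, double sigma, int n, NumericVector primes) {
  std::vector<u64> pq = primes_vec(primes);
  Sm64 g{(u64)llround(seed)};
  int k = pq.size();
  NumericMatrix out(k, n);
  if (sigma <= 0) return out;
  long long tail = (long long)std::floor(6.0 * sigma);
  for (int c = 0; c < n; ++c) {
    long long x;
    do {
      double u1 = ((double)(sm_next(g) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
      double u2 = ((double)(sm_next(g) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
      double z = std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
      x = (long long)llround(z * sigma);
    } while (x > tail || x < -tail);
    for (int r = 0; r < k; ++r) {
      long long m = x % (long long)pq[r]; if (m < 0) m += (long long)pq[r];
      out(r, c) = (double)m;
    }
  }
  return out;
}

// uniform integer coefficients in [-bound, bound] (smudging noise)
// [[Rcpp::export]]
NumericMatrix cpp_sample_smudge(double seed, double bound, int n, NumericVector primes) {
  std::vector<u64> pq = primes_vec(primes);
  Sm64 g{(u64)llround(seed)};
  int k = pq.size();
  NumericMatrix out(k, n);
  u64 B = (u64)llround(bound);
  u64 range = 2 * B + 1;
  int bits = 0; u64 h = range - 1; while (h) { h >>= 1; ++bits; }
  u64 mask = (((u64)1 << bits) - 1);
  for (int c = 0; c < n; ++c) {
    u64 v;
    if (B == 0) v = 0;
    else do { v = sm_next(g) & mask; } while (v >= range);
    long long x = (long long)v - (long long)B;
    for (int r = 0; r < k; ++r) {
      long long m = x % (long long)pq[r]; if (m < 0) m += (long long)pq[r];
      out(r, c) = (double)m;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Small modular helpers used by the plaintext-side circuit code

// [[Rcpp::export]]
NumericVector cpp_mulmod_vec(NumericVector a, NumericVector b, double p) {
  u64 pp = (u64)llround(p);
  int n = a.size();
  if (b.size() != n && b.size() != 1) stop("length mismatch");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    u64 x = (u64)llround(a[i]);
    u64 y = (u64)llround(b.size() == 1 ? b[0] : b[i]);
    out[i] = (double)mulmod(x % pp, y % pp, pp);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_powmod(double a, double e, double p) {
  return (double)powmod((u64)llround(a), (u64)llround(e), (u64)llround(p));
}

// [[Rcpp::export]]
double cpp_invmod(double a, double p) {
  u64 pp = (u64)llround(p);
  u64 aa = ((u64)llround(a)) % pp;
  if (aa == 0) stop("non-invertible element");
  return (double)invmod(aa, pp);
}
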