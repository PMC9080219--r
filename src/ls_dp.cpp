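#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Local similarity dynamic program.
//
// For an alignment offset d (series y shifted d months later than x), the
// aligned products are z_k = x[k] * y[k + d] (and symmetrically for d < 0).
// Best positive segment: P_k = max(0, P_{k-1} + z_k); best negative segment:
// N_k = max(0, N_{k-1} - z_k). The LS score is the larger running maximum
// divided by the FULL series length n (not the interval length), signed.
// Ties: positive sign wins, smaller |d| wins (offsets scanned 0,-1,+1,...),
// earlier start wins (strict improvement required while scanning forward).

struct LsBest {
  double score;     // unsigned best segment sum
  int start, stop;  // 0-based inclusive, along the aligned vector
};

static void scan_segments(const double* x, const double* y, int len,
                          LsBest& pos, LsBest& neg) {
  double pp = 0.0, nn = 0.0;
  int ps = 0, ns = 0;
  pos.score = neg.score = 0.0;
  pos.start = pos.stop = neg.start = neg.stop = 0;
  for (int k = 0; k < len; ++k) {
    double z = x[k] * y[k];
    if (pp + z > 0) { pp += z; } else { pp = 0.0; ps = k + 1; }
    if (pp > pos.score) { pos.score = pp; pos.start = ps; pos.stop = k; }
    if (nn - z > 0) { nn -= z; } else { nn = 0.0; ns = k + 1; }
    if (nn > neg.score) { neg.score = nn; neg.start = ns; neg.stop = k; }
  }
}

// Core scorer over all offsets |d| <= max_delay. Returns signed score and,
// optionally, the alignment of the best segment.
static double ls_core(const double* x, const double* y, int n, int max_delay,
                      int* out_delay, int* out_sa, int* out_ea,
                      int* out_sb, int* out_eb) {
  double best = -1.0;  // unsigned
  double best_signed = 0.0;
  int b_delay = 0, b_sa = 0, b_ea = -1, b_sb = 0, b_eb = -1;
  for (int ad = 0; ad <= max_delay; ++ad) {
    for (int s = 0; s < (ad == 0 ? 1 : 2); ++s) {
      int d = (s == 0) ? -ad : ad;  // scan order 0,-1,+1,-2,+2,...
      int len = n - ad;
      if (len < 1) continue;
      // d >= 0: pair x[k] with y[k+d]; d < 0: pair x[k+|d|] with y[k]
      const double* xx = (d >= 0) ? x : x + ad;
      const double* yy = (d >= 0) ? y + d : y;
      LsBest pos, neg;
      scan_segments(xx, yy, len, pos, neg);
      // positive preferred on exact tie
      double sc; int sgn, st, en;
      if (pos.score >= neg.score) { sc = pos.score; sgn = 1; st = pos.start; en = pos.stop; }
      else                        { sc = neg.score; sgn = -1; st = neg.start; en = neg.stop; }
      if (sc > best + 1e-12) {
        best = sc;
        best_signed = sgn * sc;
        b_delay = d;
        b_sa = (d >= 0) ? st : st + ad;
        b_ea = (d >= 0) ? en : en + ad;
        b_sb = (d >= 0) ? st + d : st;
        b_eb = (d >= 0) ? en + d : en;
      }
    }
  }
  if (out_delay) {
    *out_delay = b_delay;
    *out_sa = b_sa; *out_ea = b_ea; *out_sb = b_sb; *out_eb = b_eb;
  }
  return best_signed / n;
}

// [[Rcpp::export]]
List ls_score_cpp(NumericVector x, NumericVector y, int max_delay) {
  int n = x.size();
  if (y.size() != n) stop("series lengths differ");
  int d = 0, sa = 0, ea = -1, sb = 0, eb = -1;
  double ls = ls_core(x.begin(), y.begin(), n, max_delay, &d, &sa, &ea, &sb, &eb);
  return List::create(_["ls"] = ls, _["delay"] = d,
                      _["start_a"] = sa + 1, _["stop_a"] = ea + 1,
                      _["start_b"] = sb + 1, _["stop_b"] = eb + 1);
}

// Fisher-Yates with an explicit 64-bit generator so results are
// reproducible across platforms and independent of R's RNG state.
static inline uint32_t bounded(std::mt19937_64& rng, uint32_t bound) {
  uint64_t threshold = (~uint64_t(0) - bound + 1) % bound;
  for (;;) {
    uint64_t r = rng();
    if (r >= threshold) return (uint32_t)(r % bound);
  }
}

static void shuffle_idx(std::vector<int>& idx, std::mt19937_64& rng) {
  for (int i = (int)idx.size() - 1; i > 0; --i) {
    int j = (int)bounded(rng, (uint32_t)(i + 1));
    std::swap(idx[i], idx[j]);
  }
}

// [[Rcpp::export]]
double ls_perm_pvalue_cpp(NumericVector x, NumericVector y, int max_delay,
                          int n_perm, double seed) {
  int n = x.size();
  if (y.size() != n) stop("series lengths differ");
  double obs = std::fabs(ls_core(x.begin(), y.begin(), n, max_delay,
                                 nullptr, nullptr, nullptr, nullptr, nullptr));
  std::mt19937_64 rng((uint64_t)seed);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> yp(n);
  int count = 0;
  for (int b = 0; b < n_perm; ++b) {
    shuffle_idx(idx, rng);
    for (int i = 0; i < n; ++i) yp[i] = y[idx[i]];
    double s = std::fabs(ls_core(x.begin(), yp.data(), n, max_delay,
                                 nullptr, nullptr, nullptr, nullptr, nullptr));
    if (s >= obs - 1e-12) ++count;
  }
  return (count + 1.0) / (n_perm + 1.0);
}

// All-pairs LS over the rows of `mat` (rows = series), returning parallel
// vectors for the pair list given by 1-based row indices ia, ib.
// [[Rcpp::export]]
List ls_pairs_cpp(NumericMatrix mat, IntegerVector ia, IntegerVector ib,
                  int max_delay) {
  int K = ia.size(), n = mat.ncol();
  NumericVector ls(K);
  IntegerVector delay(K), sa(K), ea(K), sb(K), eb(K);
  std::vector<double> xi(n), yi(n);
  for (int k = 0; k < K; ++k) {
    int a = ia[k] - 1, b = ib[k] - 1;
    for (int j = 0; j < n; ++j) { xi[j] = mat(a, j); yi[j] = mat(b, j); }
    int d = 0, s1 = 0, e1 = -1, s2 = 0, e2 = -1;
    ls[k] = ls_core(xi.data(), yi.data(), n, max_delay, &d, &s1, &e1, &s2, &e2);
    delay[k] = d; sa[k] = s1 + 1; ea[k] = e1 + 1; sb[k] = s2 + 1; eb[k] = e2 + 1;
  }
  return List::create(_["ls"] = ls, _["delay"] = delay,
                      _["start_a"] = sa, _["stop_a"] = ea,
                      _["start_b"] = sb, _["stop_b"] = eb);
}

// Batch permutation p-values for selected pairs; per-pair substream so the
// result does not depend on which other pairs were screened in.
// [[Rcpp::export]]
NumericVector ls_perm_batch_cpp(NumericMatrix mat, IntegerVector ia,
                                IntegerVector ib, int max_delay, int n_perm,
                                double seed) {
  int K = ia.size(), n = mat.ncol();
  NumericVector p(K);
  std::vector<double> xi(n), yi(n), yp(n);
  std::vector<int> idx(n);
  for (int k = 0; k < K; ++k) {
    int a = ia[k] - 1, b = ib[k] - 1;
    for (int j = 0; j < n; ++j) { xi[j] = mat(a, j); yi[j] = mat(b, j); }
    double obs = std::fabs(ls_core(xi.data(), yi.data(), n, max_delay,
                                   nullptr, nullptr, nullptr, nullptr, nullptr));
    uint64_t sd = (uint64_t)seed * 1000003ULL + (uint64_t)(a + 1) * 7919ULL +
                  (uint64_t)(b + 1);
    std::mt19937_64 rng(sd);
    for (int i = 0; i < n; ++i) idx[i] = i;
    int count = 0;
    for (int bb = 0; bb < n_perm; ++bb) {
      shuffle_idx(idx, rng);
      for (int i = 0; i < n; ++i) yp[i] = yi[idx[i]];
      double s = std::fabs(ls_core(xi.data(), yp.data(), n, max_delay,
                                   nullptr, nullptr, nullptr, nullptr, nullptr));
      if (s >= obs - 1e-12) ++count;
    }
    p[k] = (count + 1.0) / (n_perm + 1.0);
  }
  return p;
}

// Null LS sample for Monte Carlo calibration of the theoretical tail:
// products of independent standard Gaussian pairs, z-scored to unit
// population variance, scored at delay 0..max_delay.
// [[Rcpp::export]]
NumericVector ls_null_sample_cpp(int n, int n_sim, int max_delay, double seed) {
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  NumericVector out(n_sim);
  std::vector<double> x(n), y(n);
  for (int s = 0; s < n_sim; ++s) {
    double mx = 0, my = 0;
    for (int i = 0; i < n; ++i) { x[i] = gauss(rng); y[i] = gauss(rng); mx += x[i]; my += y[i]; }
    mx /= n; my /= n;
    double vx = 0, vy = 0;
    for (int i = 0; i < n; ++i) {
      x[i] -= mx; y[i] -= my; vx += x[i] * x[i]; vy += y[i] * y[i];
    }
    vx = std::sqrt(vx / n); vy = std::sqrt(vy / n);
    for (int i = 0; i < n; ++i) { x[i] /= vx; y[i] /= vy; }
    double v = ls_core(x.data(), y.data(), n, max_delay,
                       nullptr, nullptr, nullptr, nullptr, nullptr);
    out[s] = std::fabs(v);
  }
  return out;
}

// ---- interaction information permutation test on discretized series ----

static double mi_counts(const std::vector<int>& joint,
                        const std::vector<int>& ma,
                        const std::vector<int>& mb, int nb, int n) {
  double mi = 0.0, dn = (double)n;
  for (int i = 0; i < nb; ++i) {
    for (int j = 0; j < nb; ++j) {
      int c = joint[i + nb * j];
      if (c > 0) {
        double pj = c / dn;
        mi += pj * std::log2(pj * dn * dn / ((double)ma[i] * (double)mb[j]));
      }
    }
  }
  return mi;
}

static double cmi_of(const int* a, const int* b, const int* e, int n,
                     int nb, std::vector<int>& j3, std::vector<int>& jae,
                     std::vector<int>& jbe, std::vector<int>& me) {
  std::fill(j3.begin(), j3.end(), 0);
  std::fill(jae.begin(), jae.end(), 0);
  std::fill(jbe.begin(), jbe.end(), 0);
  std::fill(me.begin(), me.end(), 0);
  for (int t = 0; t < n; ++t) {
    int ai = a[t] - 1, bi = b[t] - 1, ei = e[t] - 1;
    ++j3[ai + nb * bi + nb * nb * ei];
    ++jae[ai + nb * ei];
    ++jbe[bi + nb * ei];
    ++me[ei];
  }
  double dn = (double)n, cmi = 0.0;
  for (int ei = 0; ei < nb; ++ei) {
    if (me[ei] == 0) continue;
    for (int ai = 0; ai < nb; ++ai) {
      int cae = jae[ai + nb * ei];
      if (cae == 0) continue;
      for (int bi = 0; bi < nb; ++bi) {
        int c = j3[ai + nb * bi + nb * nb * ei];
        if (c > 0) {
          double p = c / dn;
          cmi += p * std::log2((double)c * (double)me[ei] /
                               ((double)cae * (double)jbe[bi + nb * ei]));
        }
      }
    }
  }
  return cmi;
}

// II = MI(A;B|E) - MI(A;B) with a permutation test of negative II
// (permuting E); p = (1 + #{II* <= II}) / (n_perm + 1).
// [[Rcpp::export]]
List ii_perm_cpp(IntegerVector a, IntegerVector b, IntegerVector e,
                 int n_bins, int n_perm, double seed) {
  int n = a.size(), nb = n_bins;
  std::vector<int> jab(nb * nb, 0), ma(nb, 0), mb(nb, 0);
  for (int t = 0; t < n; ++t) {
    ++jab[(a[t] - 1) + nb * (b[t] - 1)];
    ++ma[a[t] - 1];
    ++mb[b[t] - 1];
  }
  double mi_ab = mi_counts(jab, ma, mb, nb, n);
  std::vector<int> j3(nb * nb * nb), jae(nb * nb), jbe(nb * nb), me(nb);
  std::vector<int> ev(n);
  for (int t = 0; t < n; ++t) ev[t] = e[t];
  double cmi = cmi_of(a.begin(), b.begin(), ev.data(), n, nb, j3, jae, jbe,
                      me);
  double ii = cmi - mi_ab;
  std::mt19937_64 rng((uint64_t)seed);
  std::vector<int> idx(n);
  for (int t = 0; t < n; ++t) idx[t] = t;
  std::vector<int> ep(n);
  int count = 0;
  for (int bb = 0; bb < n_perm; ++bb) {
    shuffle_idx(idx, rng);
    for (int t = 0; t < n; ++t) ep[t] = ev[idx[t]];
    double ii_star = cmi_of(a.begin(), b.begin(), ep.data(), n, nb, j3, jae,
                            jbe, me) - mi_ab;
    if (ii_star <= ii + 1e-12) ++count;
  }
  return List::create(_["ii"] = ii, _["mi_ab"] = mi_ab,
                      _["cmi"] = cmi,
                      _["p"] = (count + 1.0) / (n_perm + 1.0));
}
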