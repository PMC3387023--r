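#include <Rcpp.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Fast numerics for the Monte-Carlo engine.
//
// log I0: Abramowitz & Stegun 9.8.1 / 9.8.2 polynomial approximations
// (relative error ~1e-7, adequate for Monte-Carlo decision variables and
// verified against base besselI in the test suite).  The large-x branch is
// valid for all x >= 3.75 and never overflows because it works in log space.
// ---------------------------------------------------------------------------

// log I0 via a lazily built lookup table on [0, 16] (linear interpolation of
// exact scaled besselI values, error ~2e-7) and the 5-term asymptotic
// expansion beyond (error < 3e-7 at the switch point).
static std::vector<double> l0tab;
static const int L0N = 8192;
static const double L0MAX = 16.0;

static void init_l0tab() {
  if (!l0tab.empty()) return;
  l0tab.resize(L0N + 2);
  for (int i = 0; i <= L0N + 1; ++i) {
    double x = i * (L0MAX / L0N);
    l0tab[i] = std::log(R::bessel_i(x, 0.0, 2.0)) + x;
  }
}

static inline double fast_log_i0(double x) {
  if (x < L0MAX) {
    double p = x * (L0N / L0MAX);
    int i = (int)p;
    double w = p - i;
    return l0tab[i] * (1.0 - w) + l0tab[i + 1] * w;
  }
  double u = 1.0 / (8.0 * x);
  return x - 0.5 * std::log(x) - 0.91893853320467274 +
         std::log1p(u * (1.0 + u * (4.5 + u * (37.5 + u * 459.375))));
}

// wrap to [-pi, pi)
static inline double wrap_pi(double a) {
  a = a + M_PI;
  a -= 2.0 * M_PI * std::floor(a / (2.0 * M_PI));
  return a - M_PI;
}

// ---------------------------------------------------------------------------
// von Mises sampling, Best & Fisher (1979) rejection algorithm.
// kappa == 0 gives the uniform limit; very large kappa uses the wrapped
// normal limit (sd = 1/sqrt(kappa)).  Uses R's RNG stream throughout.
// ---------------------------------------------------------------------------

static double rvm1(double mu, double kappa) {
  // below ~1e-5 the distribution is uniform to ~1e-5 in density and the
  // Best-Fisher constants suffer catastrophic cancellation (rho ~ kappa^2/2
  // underflows against 2), so sample uniformly
  if (kappa <= 1e-5) return unif_rand() * 2.0 * M_PI - M_PI;
  if (kappa > 5e6) return wrap_pi(mu + norm_rand() / std::sqrt(kappa));
  double tau = 1.0 + std::sqrt(1.0 + 4.0 * kappa * kappa);
  double rho = (tau - std::sqrt(2.0 * tau)) / (2.0 * kappa);
  double r = (1.0 + rho * rho) / (2.0 * rho);
  double f = 0.0;
  for (;;) {
    double z = std::cos(M_PI * unif_rand());
    f = (1.0 + r * z) / (r + z);
    double c = kappa * (r - f);
    double u = unif_rand();
    if (c * (2.0 - c) - u > 0.0) break;
    if (std::log(c / u) + 1.0 - c >= 0.0) break;
  }
  double th = (unif_rand() > 0.5 ? 1.0 : -1.0) * std::acos(f);
  return wrap_pi(mu + th);
}

// [[Rcpp::export]]
NumericVector rvm_cpp(int n, double mu, double kappa) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rvm1(mu, kappa);
  return out;
}

// [[Rcpp::export]]
NumericVector rvm_vec_cpp(NumericVector mu, NumericVector kappa) {
  int n = mu.size();
  NumericVector out(n);
  bool sk = (kappa.size() == 1);
  for (int i = 0; i < n; ++i) out[i] = rvm1(mu[i], sk ? kappa[0] : kappa[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector log_i0_fast_cpp(NumericVector x) {
  init_l0tab();
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fast_log_i0(x[i]);
  return out;
}

// ---------------------------------------------------------------------------
// kappa(J) by table lookup: lk holds log(kappa) on an equally spaced log(J)
// grid (ljmin + i * dlj).  Outside the table, the exact asymptotic limits
// kappa ~ sqrt(2 J) (J -> 0) and kappa ~ J + 1/2 + 1/(8J) (J -> Inf) apply.
// ---------------------------------------------------------------------------

static inline double kappa_interp1(double J, const double* lk, int n,
                                   double ljmin, double dlj) {
  if (J <= 0.0) return 0.0;
  double l = std::log(J);
  if (l <= ljmin) return std::sqrt(2.0 * J);
  double pos = (l - ljmin) / dlj;
  int i = (int)pos;
  if (i >= n - 1) return J + 0.5 + 1.0 / (8.0 * J);
  double w = pos - i;
  return std::exp(lk[i] * (1.0 - w) + lk[i + 1] * w);
}

// [[Rcpp::export]]
NumericVector kappa_interp_cpp(NumericVector J, NumericVector lk,
                               double ljmin, double dlj) {
  int n = J.size(), m = lk.size();
  NumericVector out(n);
  const double* p = lk.begin();
  for (int i = 0; i < n; ++i) out[i] = kappa_interp1(J[i], p, m, ljmin, dlj);
  return out;
}

// ---------------------------------------------------------------------------
// Quantile-transform percept simulation (common random numbers).
//
// Measurement noise enters through pre-drawn standard normal scores z: a
// draw from VM(0, kappa) is T(z; kappa) = F^{-1}_VM(Phi(z); kappa),
// evaluated by bilinear interpolation of a table of standardized quantiles
// y = x * sqrt(kappa + 1) on a (z, log kappa) grid.  Because the same z
// array drives every parameter combination and both encoding regimes, the
// Monte-Carlo noise of model predictions is common across models and
// largely cancels in likelihood comparisons.  kappa below the table range
// is effectively uniform; above it the normal limit y ~ z applies, and the
// final division by sqrt(kappa + 1) gives the right scale.
// ---------------------------------------------------------------------------

static inline double vm_from_z(double z, double kappa, const double* tab,
                               int nz, int nk, double zmax, double dz,
                               double lkmin, double dlk) {
  if (z > zmax) z = zmax;
  if (z < -zmax) z = -zmax;
  double lk = std::log(kappa > 1e-8 ? kappa : 1e-8);
  double lkmax = lkmin + dlk * (nk - 1);
  if (lk < lkmin) lk = lkmin;
  if (lk > lkmax) lk = lkmax;
  double pz = (z + zmax) / dz;
  int iz = (int)pz;
  if (iz > nz - 2) iz = nz - 2;
  double wz = pz - iz;
  double pk = (lk - lkmin) / dlk;
  int ik = (int)pk;
  if (ik > nk - 2) ik = nk - 2;
  double wk = pk - ik;
  const double* c0 = tab + (std::size_t)ik * nz;
  const double* c1 = c0 + nz;
  double y0 = c0[iz] * (1.0 - wz) + c0[iz + 1] * wz;
  double y1 = c1[iz] * (1.0 - wz) + c1[iz + 1] * wz;
  double y = y0 * (1.0 - wk) + y1 * wk;
  return y / std::sqrt(kappa + 1.0);
}

// Percept simulation driven by shared noise quantiles.  zx, zy: standard
// normal scores per item (length n_types * n_samples * 4); ucfg: uniforms
// for the nuisance configuration (5 per sample: 3 shuffle steps, 1 spare,
// 1 change location).  Gamma precision draws (VP only) come from R's RNG
// stream, seeded by the caller.
// [[Rcpp::export]]
List sim_percepts_q_cpp(IntegerVector type_nh, NumericVector type_delta,
                        IntegerVector type_crel, int n_samples, bool vp,
                        double j_low, double j_high, double tau,
                        NumericVector zx, NumericVector zy, NumericVector ucfg,
                        NumericVector qtab, int nz, double zmax, double dz,
                        double lkmin, double dlk, int nk,
                        NumericVector lk, double ljmin, double dlj) {
  const int n_items = 4;
  int T = type_nh.size();
  int S = T * n_samples, M = S * n_items;
  NumericVector delta(M), jx(M), jy(M), kxv(M), kyv(M), cosd(M), mjx(S), mjy(S);
  IntegerVector rel(M);
  const double* lkp = lk.begin();
  int nlk = lk.size();
  const double* qt = qtab.begin();

  double k_low = 0.0, k_high = 0.0;
  if (!vp) {
    k_low = kappa_interp1(j_low, lkp, nlk, ljmin, dlj);
    k_high = kappa_interp1(j_high, lkp, nlk, ljmin, dlj);
  }

  int idx[4];
  for (int t = 0; t < T; ++t) {
    int nh = type_nh[t];
    double d = type_delta[t];
    int crel = type_crel[t];
    for (int s = 0; s < n_samples; ++s) {
      int si = t * n_samples + s;
      int base = si * n_items;
      const double* uc = ucfg.begin() + (std::size_t)si * 5;
      idx[0] = 0; idx[1] = 1; idx[2] = 2; idx[3] = 3;
      for (int i = n_items - 1; i > 0; --i) {
        int j = (int)(uc[n_items - 1 - i] * (i + 1));
        if (j > i) j = i;
        int tmp = idx[i]; idx[i] = idx[j]; idx[j] = tmp;
      }
      bool hi[4] = {false, false, false, false};
      for (int i = 0; i < nh; ++i) hi[idx[i]] = true;
      int cl = -1;
      if (d != 0.0) {
        int el[4], ne = 0;
        for (int i = 0; i < n_items; ++i)
          if (hi[i] == (crel == 1)) el[ne++] = i;
        if (ne > 0) {
          int j = (int)(uc[4] * ne);
          if (j >= ne) j = ne - 1;
          cl = el[j];
        }
      }
      double sx = 0.0, sy = 0.0;
      for (int i = 0; i < n_items; ++i) {
        double jbar = hi[i] ? j_high : j_low;
        double Jx, Jy, kx, ky;
        if (vp) {
          double sh = jbar / tau;
          Jx = R::rgamma(sh, tau);
          Jy = R::rgamma(sh, tau);
          kx = kappa_interp1(Jx, lkp, nlk, ljmin, dlj);
          ky = kappa_interp1(Jy, lkp, nlk, ljmin, dlj);
        } else {
          Jx = Jy = jbar;
          kx = ky = hi[i] ? k_high : k_low;
        }
        int m = base + i;
        double ex = vm_from_z(zx[m], kx, qt, nz, nk, zmax, dz, lkmin, dlk);
        double ey = vm_from_z(zy[m], ky, qt, nz, nk, zmax, dz, lkmin, dlk);
        double dd = wrap_pi(ex - ey + (i == cl ? d : 0.0));
        delta[m] = dd;
        cosd[m] = std::cos(dd);
        jx[m] = Jx;
        jy[m] = Jy;
        kxv[m] = kx;
        kyv[m] = ky;
        rel[m] = hi[i] ? 1 : 0;
        sx += Jx;
        sy += Jy;
      }
      mjx[si] = sx / n_items;
      mjy[si] = sy / n_items;
    }
  }
  return List::create(_["delta"] = delta, _["cosd"] = cosd,
                      _["jx"] = jx, _["jy"] = jy,
                      _["kx"] = kxv, _["ky"] = kyv, _["rel"] = rel,
                      _["mjx"] = mjx, _["mjy"] = mjy,
                      _["n_samples"] = n_samples, _["n_types"] = T);
}

// ---------------------------------------------------------------------------
// Local log decision variables: log d_i = log I0(kx) + log I0(ky) - log I0(kc)
// with kc = sqrt(kx^2 + ky^2 + 2 kx ky cos(x - y)).  kx/ky may be scalar
// (single assumed precision) or per-item vectors.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector logd_cpp(NumericVector cosd, NumericVector kx, NumericVector ky) {
  init_l0tab();
  int n = cosd.size();
  NumericVector out(n);
  bool sx = (kx.size() == 1), sy = (ky.size() == 1);
  double cx = sx ? fast_log_i0(kx[0]) : 0.0;
  double cy = sy ? fast_log_i0(ky[0]) : 0.0;
  for (int i = 0; i < n; ++i) {
    double a = sx ? kx[0] : kx[i];
    double b = sy ? ky[0] : ky[i];
    double kc = std::sqrt(a * a + b * b + 2.0 * a * b * cosd[i]);
    double la = sx ? cx : fast_log_i0(a);
    double lb = sy ? cy : fast_log_i0(b);
    out[i] = la + lb - fast_log_i0(kc);
  }
  return out;
}

// Fused per-sample decision statistics: computes per-item log d (without
// materializing it) and reduces to the optimal-rule and Max-rule statistics
// in one pass.  kx/ky may be scalar or per-item vectors.
// [[Rcpp::export]]
NumericMatrix stats_cpp(NumericVector cosd, NumericVector kx, NumericVector ky,
                        int n_items) {
  init_l0tab();
  int M = cosd.size(), S = M / n_items;
  NumericMatrix out(S, 2);
  bool sx = (kx.size() == 1), sy = (ky.size() == 1);
  double cx = sx ? fast_log_i0(kx[0]) : 0.0;
  double cy = sy ? fast_log_i0(ky[0]) : 0.0;
  double lg = std::log((double)n_items);
  double ld[8];
  for (int s = 0; s < S; ++s) {
    int base = s * n_items;
    double mx = R_NegInf;
    for (int i = 0; i < n_items; ++i) {
      double a = sx ? kx[0] : kx[base + i];
      double b = sy ? ky[0] : ky[base + i];
      double kc = std::sqrt(a * a + b * b + 2.0 * a * b * cosd[base + i]);
      double v = (sx ? cx : fast_log_i0(a)) + (sy ? cy : fast_log_i0(b)) -
                 fast_log_i0(kc);
      ld[i] = v;
      if (v > mx) mx = v;
    }
    double acc = 0.0;
    for (int i = 0; i < n_items; ++i) acc += std::exp(ld[i] - mx);
    out(s, 0) = mx + std::log(acc) - lg;
    out(s, 1) = mx;
  }
  return out;
}

// Statistics for the single-assumed-precision observer for a whole sweep of
// assumed concentrations, reusing c0 = sqrt(2 + 2 cos(x - y)) so that
// kc = kappa * c0.  Returns an S x (2 * n_kappa) matrix: columns (2j-1, 2j)
// are the optimal/Max statistics for kappa[j].
// [[Rcpp::export]]
NumericMatrix stats_s_cpp(NumericVector c0, NumericVector kappa, int n_items) {
  init_l0tab();
  int M = c0.size(), S = M / n_items, K = kappa.size();
  NumericMatrix out(S, 2 * K);
  double lg = std::log((double)n_items);
  double ld[8];
  for (int j = 0; j < K; ++j) {
    double ka = kappa[j];
    double l2 = 2.0 * fast_log_i0(ka);
    for (int s = 0; s < S; ++s) {
      int base = s * n_items;
      double mx = R_NegInf;
      for (int i = 0; i < n_items; ++i) {
        double v = l2 - fast_log_i0(ka * c0[base + i]);
        ld[i] = v;
        if (v > mx) mx = v;
      }
      double acc = 0.0;
      for (int i = 0; i < n_items; ++i) acc += std::exp(ld[i] - mx);
      out(s, 2 * j) = mx + std::log(acc) - lg;
      out(s, 2 * j + 1) = mx;
    }
  }
  return out;
}

// Fraction of samples per type whose statistic exceeds each threshold.
// stat is laid out type-major (n_samples consecutive entries per type).
// [[Rcpp::export]]
NumericMatrix sweep_cpp(NumericVector stat, int n_samples, NumericVector thr) {
  int S = stat.size(), T = S / n_samples, nt = thr.size();
  NumericMatrix out(T, nt);
  for (int t = 0; t < T; ++t) {
    const double* p = stat.begin() + (std::size_t)t * n_samples;
    for (int j = 0; j < nt; ++j) {
      double th = thr[j];
      int c = 0;
      for (int s = 0; s < n_samples; ++s) c += (p[s] > th);
      out(t, j) = (double)c / n_samples;
    }
  }
  return out;
}

// Per-sample decision statistics from per-item log d:
//   column 1: log( (1/n_items) * sum_i d_i )  (optimal-rule statistic)
//   column 2: max_i log d_i                   (Max-rule statistic)
// [[Rcpp::export]]
NumericMatrix pair_stats_cpp(NumericVector logd, int n_items) {
  int S = logd.size() / n_items;
  NumericMatrix out(S, 2);
  double lg = std::log((double)n_items);
  for (int s = 0; s < S; ++s) {
    const double* p = logd.begin() + (std::size_t)s * n_items;
    double mx = p[0];
    for (int i = 1; i < n_items; ++i) if (p[i] > mx) mx = p[i];
    double acc = 0.0;
    for (int i = 0; i < n_items; ++i) acc += std::exp(p[i] - mx);
    out(s, 0) = mx + std::log(acc) - lg;
    out(s, 1) = mx;
  }
  return out;
}
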