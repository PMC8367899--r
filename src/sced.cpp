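// Core numerics: conditional AR(1) log-likelihood for the two-phase models,
// hierarchical log-prior, adaptive Metropolis-within-Gibbs sampler, and the
// deterministic seed hash used to schedule simulation fits.
//
// Parameter vector layout (length 16, shared by all four models; components a
// model does not estimate are pinned at 0 or at their configured value):
//   0 intercept_p1  1 slope_p1  2 intercept_p2  3 slope_p2
//   4 rho           5 sigma_eps
//   6 mu_int_p1     7 mu_int_p2 8 mu_slope_p1   9 mu_slope_p2
//  10 var_int      11 var_slope
//  12 gmode_int    13 gsd_int   14 gmode_slope  15 gsd_slope
#include <Rcpp.h>
using namespace Rcpp;

static const int NPAR = 16;

// [[Rcpp::export]]
int cpp_seed_hash(int root, int a, int b) {
  // splitmix64-style scramble, folded to a strictly positive 31-bit integer
  uint64_t x = (uint64_t)(uint32_t)root * 0x9E3779B97F4A7C15ULL;
  x += (uint64_t)(uint32_t)a;
  x ^= x >> 30; x *= 0xBF58476D1CE4E5B9ULL;
  x += (uint64_t)(uint32_t)b;
  x ^= x >> 27; x *= 0x94D049BB133111EBULL;
  x ^= x >> 31;
  return (int)(x % 2147483646ULL) + 1;
}

// Conditional log-likelihood. First point of each phase (or of the whole
// series in carry-over mode) is Gaussian around the regression mean with SD
// sigma_eps; later points are Gaussian around regression mean + rho * previous
// raw residual, innovation SD sigma_eps.
static double ll_core(const NumericVector& y, int tb, const double* th,
                      bool carry) {
  const int n = y.size();
  const double b11 = th[0], b21 = th[1], b12 = th[2], b22 = th[3];
  const double rho = th[4], sig = th[5];
  if (!(sig > 0.0) || !(std::fabs(rho) < 1.0)) return R_NegInf;
  double ll = 0.0, eprev = 0.0;
  for (int t = 1; t <= n; ++t) {
    double mu = (t <= tb) ? (b11 + b21 * t) : (b12 + b22 * (t - tb));
    bool first = carry ? (t == 1) : (t == 1 || t == tb + 1);
    double m = first ? mu : (mu + rho * eprev);
    ll += R::dnorm(y[t - 1], m, sig, 1);
    eprev = y[t - 1] - mu;
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_loglik(NumericVector y, int tb, NumericVector theta, bool carry) {
  if (theta.size() != NPAR) stop("theta must have length 16");
  return ll_core(y, tb, REAL(theta), carry);
}

static void gamma_ab(double mode, double sd, double* shape, double* rate) {
  *rate = (mode + std::sqrt(mode * mode + 4.0 * sd * sd)) / (2.0 * sd * sd);
  *shape = 1.0 + mode * (*rate);
}

// prior config vector layout:
//   0 mu_int_lo 1 mu_int_hi 2 mu_slope_mean 3 mu_slope_sd
//   4 sig_lo 5 sig_hi 6 rho_lo 7 rho_hi 8 hyper_lo 9 hyper_hi
//  10 hyper_scale (0 = gamma on the variance, 1 = gamma on the SD)
static double lp_core(const double* th, const int* fr, const double* cfg) {
  double lp = 0.0;
  if (fr[0] || fr[2]) {
    if (!(th[10] > 0.0)) return R_NegInf;
    double s_int = std::sqrt(th[10]);
    if (fr[0]) lp += R::dnorm(th[0], th[6], s_int, 1);
    if (fr[2]) lp += R::dnorm(th[2], th[7], s_int, 1);
  }
  if (fr[1] || fr[3]) {
    if (!(th[11] > 0.0)) return R_NegInf;
    double s_slope = std::sqrt(th[11]);
    if (fr[1]) lp += R::dnorm(th[1], th[8], s_slope, 1);
    if (fr[3]) lp += R::dnorm(th[3], th[9], s_slope, 1);
  }
  if (fr[4]) lp += R::dunif(th[4], cfg[6], cfg[7], 1);
  if (fr[5]) lp += R::dunif(th[5], cfg[4], cfg[5], 1);
  if (fr[6]) lp += R::dunif(th[6], cfg[0], cfg[1], 1);
  if (fr[7]) lp += R::dunif(th[7], cfg[0], cfg[1], 1);
  if (fr[8]) lp += R::dnorm(th[8], cfg[2], cfg[3], 1);
  if (fr[9]) lp += R::dnorm(th[9], cfg[2], cfg[3], 1);
  for (int k = 0; k < 2; ++k) {
    int vi = 10 + k, gm = 12 + 2 * k, gs = 13 + 2 * k;
    if (fr[vi]) {
      double v = th[vi];
      if (!(v > 0.0) || !(th[gm] > 0.0) || !(th[gs] > 0.0)) return R_NegInf;
      double a, b;
      gamma_ab(th[gm], th[gs], &a, &b);
      if (cfg[10] < 0.5) {
        lp += R::dgamma(v, a, 1.0 / b, 1);
      } else {
        double s = std::sqrt(v);
        lp += R::dgamma(s, a, 1.0 / b, 1) - std::log(2.0 * s);
      }
    }
    if (fr[gm]) lp += R::dunif(th[gm], cfg[8], cfg[9], 1);
    if (fr[gs]) lp += R::dunif(th[gs], cfg[8], cfg[9], 1);
  }
  return lp;
}

// [[Rcpp::export]]
double cpp_logprior(NumericVector theta, IntegerVector free_flag,
                    NumericVector cfg) {
  if (theta.size() != NPAR || free_flag.size() != NPAR)
    stop("theta/free_flag must have length 16");
  return lp_core(REAL(theta), INTEGER(free_flag), REAL(cfg));
}

// transforms: 0 identity, 1 logit on (lo, hi), 2 log
static double t_inv(double z, int type, double lo, double hi) {
  if (type == 1) {
    double s = (z > 0.0) ? 1.0 / (1.0 + std::exp(-z))
                         : std::exp(z) / (1.0 + std::exp(z));
    return lo + (hi - lo) * s;
  }
  if (type == 2) return std::exp(z);
  return z;
}

static double t_fwd(double x, int type, double lo, double hi) {
  if (type == 1) return std::log((x - lo) / (hi - x));
  if (type == 2) return std::log(x);
  return x;
}

static double t_ljac(double z, int type, double lo, double hi) {
  if (type == 1) {
    double ls, l1ms;
    if (z > 0.0) { ls = -std::log1p(std::exp(-z)); l1ms = -z + ls; }
    else         { l1ms = -std::log1p(std::exp(z)); ls = z + l1ms; }
    return std::log(hi - lo) + ls + l1ms;
  }
  if (type == 2) return z;
  return 0.0;
}

// Adaptive random-walk Metropolis-within-Gibbs on transformed coordinates.
// Uses R's RNG so set.seed()/.Random.seed give full determinism and resumable
// chains. Step sizes adapt toward 0.44 acceptance in batches of 50 during
// burn-in only.
// [[Rcpp::export]]
List cpp_mwg(NumericVector y, int tb, bool carry, NumericVector theta0,
             IntegerVector free_idx, IntegerVector trans, NumericVector tlo,
             NumericVector thi, NumericVector cfg, int n_burn, int n_keep,
             int thin, NumericVector lstep0, bool adapt) {
  const int nf = free_idx.size();
  if (theta0.size() != NPAR) stop("theta0 must have length 16");
  double th[NPAR];
  int fr[NPAR];
  for (int i = 0; i < NPAR; ++i) { th[i] = theta0[i]; fr[i] = 0; }
  for (int j = 0; j < nf; ++j) fr[free_idx[j]] = 1;

  std::vector<double> z(nf), jac(nf), lstep(nf);
  for (int j = 0; j < nf; ++j) {
    z[j] = t_fwd(th[free_idx[j]], trans[j], tlo[j], thi[j]);
    jac[j] = t_ljac(z[j], trans[j], tlo[j], thi[j]);
    lstep[j] = lstep0[j];
  }
  const double* pcfg = REAL(cfg);
  double ll = ll_core(y, tb, th, carry);
  double lp = lp_core(th, fr, pcfg);
  if (!R_finite(ll + lp)) stop("posterior unevaluable at initial values");

  NumericMatrix draws(n_keep, nf);
  std::vector<int> acc(nf, 0), tries(nf, 0), bacc(nf, 0), btry(nf, 0);
  int batch = 0, kept = 0;
  const int n_total = n_burn + n_keep * thin;

  GetRNGstate();
  for (int it = 0; it < n_total; ++it) {
    for (int j = 0; j < nf; ++j) {
      int idx = free_idx[j];
      double zj = z[j];
      double zp = zj + std::exp(lstep[j]) * norm_rand();
      double xp = t_inv(zp, trans[j], tlo[j], thi[j]);
      double old_x = th[idx];
      th[idx] = xp;
      double llp = ll_core(y, tb, th, carry);
      double lpp = lp_core(th, fr, pcfg);
      double jacp = t_ljac(zp, trans[j], tlo[j], thi[j]);
      double lr = (llp + lpp + jacp) - (ll + lp + jac[j]);
      bool ok = R_finite(llp + lpp) &&
                (lr >= 0.0 || std::log(unif_rand()) < lr);
      if (ok) {
        z[j] = zp; jac[j] = jacp; ll = llp; lp = lpp;
        if (it >= n_burn) acc[j]++; else bacc[j]++;
      } else {
        th[idx] = old_x;
      }
      if (it >= n_burn) tries[j]++; else btry[j]++;
    }
    if (adapt && it < n_burn && ((it + 1) % 50 == 0)) {
      batch++;
      double delta = std::min(0.25, 1.0 / std::sqrt((double)batch));
      for (int j = 0; j < nf; ++j) {
        double rate = btry[j] > 0 ? (double)bacc[j] / btry[j] : 0.0;
        lstep[j] += (rate > 0.44) ? delta : -delta;
        bacc[j] = 0; btry[j] = 0;
      }
    }
    if (it >= n_burn && ((it - n_burn + 1) % thin == 0)) {
      for (int j = 0; j < nf; ++j) draws(kept, j) = th[free_idx[j]];
      kept++;
    }
  }
  PutRNGstate();

  NumericVector th_out(NPAR), ls_out(nf), acc_out(nf);
  for (int i = 0; i < NPAR; ++i) th_out[i] = th[i];
  for (int j = 0; j < nf; ++j) {
    ls_out[j] = lstep[j];
    acc_out[j] = tries[j] > 0 ? (double)acc[j] / tries[j] : NA_REAL;
  }
  return List::create(_["draws"] = draws, _["theta"] = th_out,
                      _["lstep"] = ls_out, _["accept"] = acc_out);
}
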