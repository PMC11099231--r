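#include <Rcpp.h>
using namespace Rcpp;

// Wiener first-passage-time density at the LOWER boundary for a diffusion
// with unit diffusion coefficient, drift v, boundary separation a and
// relative start w in (0,1). Dual series expansion with automatic
// small-time / large-time selection; err is the truncation tolerance on
// the standardized density f(tt, w).
static double wfpt_f_lower(double t, double v, double a, double w,
                           double t0, double err) {
  const double tt = t - t0;
  if (tt <= 0.0 || a <= 0.0 || w <= 0.0 || w >= 1.0) return 0.0;
  const double ttn = tt / (a * a); // time in units of a^2

  // number of terms needed by each expansion
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * ttn) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * ttn *
                         std::log(2.0 * err * std::sqrt(2.0 * M_PI * ttn)));
    ks = std::max(ks, std::sqrt(ttn) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * ttn * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * ttn * err) / (M_PI * M_PI * ttn));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(ttn)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(ttn));
  }

  double f;
  if (ks < kl) { // small-time expansion
    const int K = (int)std::ceil(ks);
    const int lo = -((K - 1) / 2);
    const int hi = ((K - 1) / 2) + ((K - 1) % 2);
    double s = 0.0;
    for (int k = lo; k <= hi; ++k) {
      const double u = w + 2.0 * k;
      s += u * std::exp(-u * u / (2.0 * ttn));
    }
    f = s / std::sqrt(2.0 * M_PI * ttn * ttn * ttn);
  } else {       // large-time expansion
    const int K = (int)std::ceil(kl);
    double s = 0.0;
    for (int k = 1; k <= K; ++k) {
      s += k * std::exp(-k * k * M_PI * M_PI * ttn / 2.0) *
           std::sin(k * M_PI * w);
    }
    f = M_PI * s;
  }
  if (f < 0.0) f = 0.0; // truncation can produce tiny negatives

  const double dens =
      f / (a * a) * std::exp(-v * a * w - v * v * tt / 2.0);
  return dens > 0.0 ? dens : 0.0;
}

static inline double wfpt_one(double t, bool upper, double v, double a,
                              double z, double t0, double err) {
  // upper-boundary density is the lower-boundary density of the mirrored
  // process (v -> -v, w -> 1 - w)
  return upper ? wfpt_f_lower(t, -v, a, 1.0 - z, t0, err)
               : wfpt_f_lower(t, v, a, z, t0, err);
}

// [[Rcpp::export]]
NumericVector wfpt_density_cpp(NumericVector rt, LogicalVector upper,
                               double v, double a, double z, double t0,
                               double err) {
  const int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = wfpt_one(rt[i], upper[i], v, a, z, t0, err);
  return out;
}

// Summed log-likelihood over trials. `upper` codes the chosen boundary,
// `drift_sign` (+1/-1) flips the drift for trials whose target category
// sits at the lower boundary (stimulus coding). Returns -Inf as soon as
// any trial has zero density.
// [[Rcpp::export]]
double wfpt_loglik_cpp(NumericVector rt, IntegerVector upper,
                       IntegerVector drift_sign, double v, double a,
                       double z, double t0, double err) {
  if (a <= 0.0 || z <= 0.0 || z >= 1.0 || t0 < 0.0 ||
      !std::isfinite(v) || !std::isfinite(a))
    return R_NegInf;
  const int n = rt.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    const double veff = drift_sign[i] >= 0 ? v : -v;
    const double d = wfpt_one(rt[i], upper[i] != 0, veff, a, z, t0, err);
    if (d <= 0.0) return R_NegInf;
    ll += std::log(d);
  }
  return ll;
}

// Euler-Maruyama first-passage simulator; uses R's RNG so set.seed()
// governs reproducibility. Returns (rt_seconds incl. t0, hit_upper).
// [[Rcpp::export]]
NumericMatrix ddm_sim_cpp(int n, double v, double a, double z, double t0,
                          double dt) {
  NumericMatrix out(n, 2);
  const double sdt = std::sqrt(dt);
  const long max_steps = (long)(60.0 / dt); // hard cap at 60 s
  for (int i = 0; i < n; ++i) {
    double x = z * a;
    long step = 0;
    while (x > 0.0 && x < a && step < max_steps) {
      x += v * dt + sdt * norm_rand();
      ++step;
    }
    out(i, 0) = t0 + step * dt;
    out(i, 1) = (x >= a) ? 1.0 : 0.0;
  }
  return out;
}
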