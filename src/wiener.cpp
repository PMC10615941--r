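#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time density of a Wiener process between absorbing bounds.
// Everything below works on the unit scale (diffusion coefficient 1, bounds
// at 0 and 1, relative start w, scaled time u = t / a^2); the drift and
// boundary enter through the exponential tilt in dwiener_lower().
//
// Dual-series evaluation: the small-time (image/reflection) expansion and the
// large-time (spectral) expansion are both exact; for each u the series
// needing fewer terms for absolute error `eps` is used.

static double fpt_unit_lower(double u, double w, double eps) {
  // number of terms required (truncation bounds from the standard analysis)
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * u * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * eps) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }

  double f = 0.0;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; ++k) {
      double q = w + 2.0 * k;
      f += q * std::exp(-q * q / (2.0 * u));
    }
    f /= std::sqrt(2.0 * M_PI * u * u * u);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f > 0.0 ? f : 0.0;
}

// defective density of absorption at the LOWER bound at decision time t,
// drift v, separation a, relative start w, diffusion coefficient 1
static double dwiener_lower(double t, double v, double a, double w, double eps) {
  if (t <= 0.0 || !R_finite(t)) return 0.0;
  double u = t / (a * a);
  double f = fpt_unit_lower(u, w, eps);
  if (f <= 0.0) return 0.0;
  double lg = -v * a * w - v * v * t / 2.0 - 2.0 * std::log(a) + std::log(f);
  return std::exp(lg);
}

// upper-bound absorption is the lower-bound problem after the reflection
// v -> -v, w -> 1 - w
static double dwiener(double t, double v, double a, double w, bool upper, double eps) {
  if (upper) return dwiener_lower(t, -v, a, 1.0 - w, eps);
  return dwiener_lower(t, v, a, w, eps);
}

// [[Rcpp::export]]
NumericVector wiener_density_cpp(NumericVector t, double v, double a, double w,
                                 bool upper, double eps) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = dwiener(t[i], v, a, w, upper, eps);
  return out;
}

// summed log defective density over trials; response 1 = upper bound.
// densities floored at `dens_floor` so the objective stays finite (trials
// with rt <= t0 contribute the floor, not an error)
// [[Rcpp::export]]
double ddm_loglik_cpp(NumericVector rt, IntegerVector response,
                      double v, double a, double t0, double w,
                      double eps, double dens_floor) {
  int n = rt.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double dt = rt[i] - t0;
    double dens = (dt > 0.0) ? dwiener(dt, v, a, w, response[i] == 1, eps) : 0.0;
    if (dens < dens_floor) dens = dens_floor;
    ll += std::log(dens);
  }
  return ll;
}

// Euler-Maruyama path simulation (uses R's RNG so set.seed() governs it).
// Returns a matrix with columns (decision time, hit upper bound).
// Between grid points the path is a Brownian bridge, which can cross a
// bound and come back; ignoring that gives an O(sqrt(dt)) bias in both the
// passage times and the absorption probabilities. The standard correction
// absorbs, at each interior step, with the bridge crossing probability
// exp(-2 d0 d1 / (s^2 dt)), where d0 and d1 are the distances to the bound
// before and after the step.
// [[Rcpp::export]]
NumericMatrix ddm_euler_cpp(int n, double v, double a, double w,
                            double dt, double s) {
  NumericMatrix out(n, 2);
  double sdt = s * std::sqrt(dt);
  double s2dt = s * s * dt;
  double tmax = 300.0;
  for (int i = 0; i < n; ++i) {
    double x = w * a;
    double t = 0.0;
    while (t < tmax) {
      double x0 = x;
      x += v * dt + sdt * norm_rand();
      t += dt;
      if (x >= a) { out(i, 0) = t; out(i, 1) = 1.0; break; }
      if (x <= 0.0) { out(i, 0) = t; out(i, 1) = 0.0; break; }
      double p_up = std::exp(-2.0 * (a - x0) * (a - x) / s2dt);
      double p_lo = std::exp(-2.0 * x0 * x / s2dt);
      double u = unif_rand();
      if (u < p_up) { out(i, 0) = t; out(i, 1) = 1.0; break; }
      if (u > 1.0 - p_lo) { out(i, 0) = t; out(i, 1) = 0.0; break; }
    }
    if (t >= tmax) { // essentially unreachable for the drifts used here
      out(i, 0) = tmax;
      out(i, 1) = (x >= a * w) ? 1.0 : 0.0;
    }
  }
  return out;
}
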