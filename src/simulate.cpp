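#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// rate transfer phi(x) = a * x / (1 - exp(-x/b)), overflow-safe, with the
// removable singularity at x = 0 filled by its series expansion
static inline double phi(double x, double a, double b) {
  double u = x / b;
  if (u > 1e-5) {
    // -expm1(-u) = 1 - exp(-u), accurate for small u, saturates at 1
    return a * x / (-std::expm1(-u));
  } else if (u < -1e-5) {
    if (u < -700.0) return 0.0;           // exp(-u) would overflow
    return a * x / (-std::expm1(-u));
  }
  // |u| small: u / (1 - e^-u) = 1 + u/2 + u^2/12 + O(u^4)
  return a * b * (1.0 + u / 2.0 + u * u / 12.0);
}

// Forward-Euler integration of the stochastic Wilson-Cowan system
//   tau dr/dt = -r + phi(W r + I_ext) + eta,  eta ~ N(0, sigma) iid
// Noise enters inside the dt/tau Euler increment without sqrt(dt)
// rescaling unless sqrt_dt_noise is set (Euler-Maruyama convention).
// External drive is piecewise constant: column s of iext applies up to
// step seg_end[s] (1-based, inclusive).
// The trace records the mean rate over each block of record_every steps
// (an anti-alias boxcar); r_final is the exact terminal state.
// [[Rcpp::export]]
List sim_euler(NumericMatrix W, NumericVector tau, double a, double b,
               double sigma, double dt, int n_steps, int record_every,
               NumericVector r0, NumericMatrix iext, IntegerVector seg_end,
               bool sqrt_dt_noise) {
  const int n = W.nrow();
  std::vector<double> r(n), acc(n, 0.0), inp(n), dr(n);
  for (int i = 0; i < n; ++i) r[i] = r0[i];

  const int n_rec = n_steps / record_every;
  NumericMatrix rec(n_rec, n);
  const bool noisy = sigma > 0.0;
  const double noise_scale = sqrt_dt_noise ? std::sqrt(dt) : dt;

  int seg = 0, rec_row = 0, diverged_step = -1;
  for (int step = 0; step < n_steps; ++step) {
    while (seg < seg_end.size() - 1 && step + 1 > seg_end[seg]) ++seg;
    // net input W r + I_ext
    for (int i = 0; i < n; ++i) {
      double s = iext(i, seg);
      for (int j = 0; j < n; ++j) s += W(i, j) * r[j];
      inp[i] = s;
    }
    for (int i = 0; i < n; ++i) {
      double d = -r[i] + phi(inp[i], a, b);
      double upd = (dt / tau[i]) * d;
      if (noisy) upd += (noise_scale / tau[i]) * R::rnorm(0.0, sigma);
      r[i] += upd;
    }
    bool bad = false;
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(r[i]) || std::fabs(r[i]) > 1e8) { bad = true; break; }
      acc[i] += r[i];
    }
    if (bad) { diverged_step = step + 1; break; }
    if ((step + 1) % record_every == 0) {
      for (int i = 0; i < n; ++i) {
        rec(rec_row, i) = acc[i] / record_every;
        acc[i] = 0.0;
      }
      ++rec_row;
    }
  }

  // terminal drift -r + phi(...), for convergence diagnostics
  for (int i = 0; i < n; ++i) {
    double s = iext(i, iext.ncol() - 1);
    for (int j = 0; j < n; ++j) s += W(i, j) * r[j];
    dr[i] = (-r[i] + phi(s, a, b)) / tau[i];
  }

  return List::create(
    _["rates"] = rec,
    _["r_final"] = NumericVector(r.begin(), r.end()),
    _["drift_final"] = NumericVector(dr.begin(), dr.end()),
    _["n_recorded"] = rec_row,
    _["diverged_step"] = diverged_step);
}

// vectorised transfer function (shared with the R-level wrapper)
// [[Rcpp::export]]
NumericVector transfer_cpp(NumericVector x, double a, double b) {
  const int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = phi(x[i], a, b);
  return out;
}
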