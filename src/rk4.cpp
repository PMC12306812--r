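#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step classical RK4 integration of the reduced closed-loop system
//
//   p' = u
//   u' = famp*cos(wb*tau) + gamma*w - u/webar - k*p
//   w' = -a1*p - chi*u - wm*w
//
// with k = 1 - gamma*ua*Kbar_e and w = (beta*q/4)*v the reduced voltage.
// Deterministic: a fixed number of equal steps from tau = 0. Only the tail
// of the trajectory (steps keep_from..n_steps, including the state after
// each step) is returned, so long transients cost no memory.
// [[Rcpp::export]]
NumericMatrix rk4_forced_cpp(double k, double inv_webar, double gamma,
                             double a1, double chi, double wm,
                             double famp, double wb,
                             double h, int n_steps, int keep_from,
                             NumericVector y0) {
  if (n_steps < 1 || keep_from < 0 || keep_from > n_steps)
    stop("invalid step counts");
  const int n_keep = n_steps - keep_from + 1;
  NumericMatrix out(n_keep, 4);
  double p = y0[0], u = y0[1], w = y0[2];

  auto deriv = [&](double tau, double p_, double u_, double w_,
                   double& dp, double& du, double& dw) {
    dp = u_;
    du = famp * std::cos(wb * tau) + gamma * w_ - inv_webar * u_ - k * p_;
    dw = -a1 * p_ - chi * u_ - wm * w_;
  };

  int row = 0;
  if (keep_from == 0) {
    out(0, 0) = 0.0; out(0, 1) = p; out(0, 2) = u; out(0, 3) = w;
    row = 1;
  }
  double k1p, k1u, k1w, k2p, k2u, k2w, k3p, k3u, k3w, k4p, k4u, k4w;
  for (int i = 0; i < n_steps; ++i) {
    const double tau = h * i;
    deriv(tau, p, u, w, k1p, k1u, k1w);
    deriv(tau + 0.5 * h, p + 0.5 * h * k1p, u + 0.5 * h * k1u,
          w + 0.5 * h * k1w, k2p, k2u, k2w);
    deriv(tau + 0.5 * h, p + 0.5 * h * k2p, u + 0.5 * h * k2u,
          w + 0.5 * h * k2w, k3p, k3u, k3w);
    deriv(tau + h, p + h * k3p, u + h * k3u, w + h * k3w, k4p, k4u, k4w);
    p += h / 6.0 * (k1p + 2.0 * k2p + 2.0 * k3p + k4p);
    u += h / 6.0 * (k1u + 2.0 * k2u + 2.0 * k3u + k4u);
    w += h / 6.0 * (k1w + 2.0 * k2w + 2.0 * k3w + k4w);
    if (!std::isfinite(p))
      stop("trajectory diverged (unstable system or step too large)");
    if (i + 1 >= keep_from) {
      out(row, 0) = h * (i + 1);
      out(row, 1) = p; out(row, 2) = u; out(row, 3) = w;
      ++row;
    }
  }
  colnames(out) = CharacterVector::create("tau", "p", "dp", "w");
  return out;
}
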