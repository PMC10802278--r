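#include <Rcpp.h>
using namespace Rcpp;

// Rotation-sweep scoring kernel.
//
// Each candidate bond's four pairwise distances follow
// d(theta)^2 = C + R * cos(theta + delta) and its plane distance
// |K + G * cos(theta + H)|; the composite probability is
// P = exp(-q / 2) with q the sum of squared standardized deviations of
// the five distances. The kernel tracks q (cheaper than P) and only
// exponentiates for grid points reaching the binding threshold tau.
// On a uniform angle grid the cosines advance by a rotation
// recurrence instead of per-point calls.
//
// C4, R4, D4: 4 x n_cand sinusoid constants; K, G, H: length n_cand;
// mu, msig: length 5 (msig = m * sigma); theta in radians. Ties keep
// the earlier candidate, so callers order candidates canonically.
// Returns per-angle best P and candidate (1-based; 0 = none) plus all
// (candidate, angle, P) hits with P >= tau.
// [[Rcpp::export(name = ".sweep_kernel")]]
List sweep_kernel(NumericMatrix C4, NumericMatrix R4, NumericMatrix D4,
                  NumericVector K, NumericVector G, NumericVector H,
                  NumericVector mu, NumericVector msig,
                  NumericVector theta, double tau) {
  const int nc = C4.ncol(), nt = theta.size();
  const double q_tau = (tau > 0.0 && tau <= 1.0)
    ? -2.0 * std::log(tau) : -1.0;        // q <= q_tau  <=>  P >= tau
  std::vector<double> best_q(nt, R_PosInf);
  IntegerVector best_cand(nt);
  std::vector<int> hit_c, hit_t;
  std::vector<double> hit_p;
  double inv_msig[5];
  for (int n = 0; n < 5; ++n) inv_msig[n] = 1.0 / msig[n];

  // uniform grid? then cos(theta[t] + d) advances by a fixed rotation
  bool uniform = nt > 1;
  double step = uniform ? theta[1] - theta[0] : 0.0;
  for (int t = 2; t < nt && uniform; ++t)
    if (std::fabs(theta[t] - theta[t - 1] - step) > 1e-12) uniform = false;
  const double cd = std::cos(step), sd = std::sin(step);

  for (int c = 0; c < nc; ++c) {
    double cs[5], sn[5], A[5], B[5];
    for (int n = 0; n < 4; ++n) {
      A[n] = C4(n, c); B[n] = R4(n, c);
      cs[n] = std::cos(theta[0] + D4(n, c));
      sn[n] = std::sin(theta[0] + D4(n, c));
    }
    A[4] = K[c]; B[4] = G[c];
    cs[4] = std::cos(theta[0] + H[c]);
    sn[4] = std::sin(theta[0] + H[c]);
    for (int t = 0; t < nt; ++t) {
      if (t > 0) {
        if (uniform) {
          for (int n = 0; n < 5; ++n) {
            const double cn = cs[n] * cd - sn[n] * sd;
            sn[n] = sn[n] * cd + cs[n] * sd;
            cs[n] = cn;
          }
        } else {
          for (int n = 0; n < 4; ++n) cs[n] = std::cos(theta[t] + D4(n, c));
          cs[4] = std::cos(theta[t] + H[c]);
        }
      }
      double q = 0.0;
      for (int n = 0; n < 4; ++n) {
        double d2 = A[n] + B[n] * cs[n];
        if (d2 < 0.0) d2 = 0.0;
        const double z = (std::sqrt(d2) - mu[n]) * inv_msig[n];
        q += z * z;
      }
      const double z5 = (std::fabs(A[4] + B[4] * cs[4]) - mu[4]) *
        inv_msig[4];
      q += z5 * z5;
      if (q < best_q[t]) {
        best_q[t] = q;
        best_cand[t] = c + 1;
      }
      if (q_tau >= 0.0 && q <= q_tau) {
        hit_c.push_back(c + 1);
        hit_t.push_back(t + 1);
        hit_p.push_back(std::exp(-0.5 * q));
      }
    }
  }
  NumericVector best_P(nt);
  for (int t = 0; t < nt; ++t)
    best_P[t] = best_cand[t] > 0 ? std::exp(-0.5 * best_q[t]) : 0.0;
  return List::create(_["best_P"] = best_P, _["best_cand"] = best_cand,
                      _["hit_cand"] = wrap(hit_c),
                      _["hit_theta"] = wrap(hit_t),
                      _["hit_P"] = wrap(hit_p));
}
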