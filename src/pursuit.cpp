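#include <Rcpp.h>
using namespace Rcpp;

// Per-sample pursuit integrator. Two angular axes are simulated
// independently: an intent state follows a rate-limited first-order
// exponential approach toward the active target angle, and an
// Ornstein-Uhlenbeck motor-noise state (stationary sd = noise_sd, time
// constant noise_tau) is added on output. Target angles of NA mean "no
// pursuit" (hold the current intent). Uses R's RNG so results are
// reproducible under set.seed().
//
// tgt_a, tgt_b: per-sample target angles (degrees), NA = hold
// dt: sample interval (s); tau: pursuit time constant (s)
// vmax: angular speed cap (deg/s, Inf allowed); noise_sd: motor noise sd (deg)
// [[Rcpp::export]]
NumericMatrix pursuit_core(NumericVector tgt_a, NumericVector tgt_b,
                           double dt, double tau, double vmax,
                           double noise_sd, double noise_tau) {
  int n = tgt_a.size();
  NumericMatrix out(n, 2);
  double intent[2] = {0.0, 0.0};
  double noise[2] = {0.0, 0.0};
  // exact first-order discretizations
  double k_pursuit = 1.0 - std::exp(-dt / tau);
  double rho = (noise_tau > 0) ? std::exp(-dt / noise_tau) : 0.0;
  double sigma_step = noise_sd * std::sqrt(1.0 - rho * rho);
  double max_step = vmax * dt;

  for (int i = 0; i < n; ++i) {
    double tgt[2] = {tgt_a[i], tgt_b[i]};
    for (int ax = 0; ax < 2; ++ax) {
      if (!NumericVector::is_na(tgt[ax])) {
        double step = (tgt[ax] - intent[ax]) * k_pursuit;
        if (step > max_step) step = max_step;
        if (step < -max_step) step = -max_step;
        intent[ax] += step;
      }
      if (noise_sd > 0) {
        noise[ax] = rho * noise[ax] + sigma_step * R::rnorm(0.0, 1.0);
      }
      out(i, ax) = intent[ax] + noise[ax];
    }
  }
  return out;
}
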