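#include <Rcpp.h>
using namespace Rcpp;

// Paused/spurting correlated random walk with wall attraction, used by
// simulate_track().  The recursion is inherently sequential (heading and
// position feed back through the wall-attraction term), hence C++.
//
// Per frame:
//  - two-state pause/move Markov chain; transition probabilities are
//    per-frame and already scaled by the caller (rate * dt), and are
//    modulated by the startle gain so stimulus epochs raise motility;
//  - at bout (movement run) start a peak velocity V is drawn lognormal;
//    frame speed follows a burst profile v_base + (V - v_base) *
//    exp(-(t_in_bout - t_peak)^2 / (2 sd^2)) so the bout maximum ~ V;
//  - heading gets Gaussian noise (sd turn_sd deg/frame) plus a drift of
//    wall_bias * sin(outward - heading) degrees/frame pulling the fish
//    toward the nearest wall (thigmotaxis);
//  - reflective well boundaries; step_dist is speed * dt.
// All randomness comes from R's RNG, so set.seed() governs everything.

// [[Rcpp::export(name = ".walk_sim")]]
List walk_sim(int n, double dt,
              NumericVector gain,
              double p_enter, double p_exit,
              double v_base, double v_peak_meanlog, double v_peak_sdlog,
              double turn_sd, double wall_bias,
              double burst_t_peak, double burst_sd,
              double x_min, double x_max, double y_min, double y_max,
              double x0, double y0, double h0) {
  NumericVector x(n), y(n), h(n), d(n);
  const double DEG = 180.0 / M_PI;
  double cx = 0.5 * (x_min + x_max), cy = 0.5 * (y_min + y_max);
  double xi = x0, yi = y0, hi = h0;
  bool moving = false;
  double V = v_base;
  double t_bout = 0.0;

  for (int i = 0; i < n; ++i) {
    double g = gain[i];
    if (moving) {
      if (R::unif_rand() < std::min(1.0, p_enter / g)) moving = false;
    } else {
      if (R::unif_rand() < std::min(1.0, p_exit * g)) {
        moving = true;
        V = std::exp(R::rnorm(v_peak_meanlog, v_peak_sdlog));
        t_bout = 0.0;
      }
    }
    double speed = 0.0;
    if (moving) {
      double prof = std::exp(-std::pow(t_bout - burst_t_peak, 2.0) /
                             (2.0 * burst_sd * burst_sd));
      speed = g * (v_base + (V - v_base) * prof);
      if (speed < 0.0) speed = 0.0;
      // heading update only while moving; frozen during pauses
      double outward = std::atan2(yi - cy, xi - cx) * DEG;
      double delta = std::sin((outward - hi) / DEG);
      double drift = wall_bias * delta;
      if (drift > 90.0) drift = 90.0;          // keep the pull stable at
      if (drift < -90.0) drift = -90.0;        // coarse frame rates
      hi += R::rnorm(0.0, turn_sd) + drift;
      hi -= 360.0 * std::floor(hi / 360.0);
      xi += speed * dt * std::cos(hi / DEG);
      yi += speed * dt * std::sin(hi / DEG);
      // reflective boundaries (single reflection suffices for sane speeds)
      if (xi > x_max) { xi = 2.0 * x_max - xi; hi = 540.0 - hi; }
      if (xi < x_min) { xi = 2.0 * x_min - xi; hi = 540.0 - hi; }
      if (yi > y_max) { yi = 2.0 * y_max - yi; hi = 360.0 - hi; }
      if (yi < y_min) { yi = 2.0 * y_min - yi; hi = 360.0 - hi; }
      hi -= 360.0 * std::floor(hi / 360.0);
      if (xi > x_max) xi = x_max;
      if (xi < x_min) xi = x_min;
      if (yi > y_max) yi = y_max;
      if (yi < y_min) yi = y_min;
      t_bout += dt;
    }
    x[i] = xi; y[i] = yi; h[i] = hi;
    d[i] = (i == 0) ? 0.0 : speed * dt;
  }
  return List::create(_["x"] = x, _["y"] = y, _["heading"] = h,
                      _["step_dist"] = d);
}
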