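#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Reflect z into [-h, h] (triangular fold, period 4h).
static inline double reflect(double z, double h) {
  double p = 4.0 * h;
  double u = z + h;
  double w = u - std::floor(u / p) * p; // u mod p, in [0, p)
  if (w > 2.0 * h) w = p - w;
  return w - h;
}

// Two-state (bound/free) Brownian switching simulator with an axial
// detection slice, localization noise, photobleaching and blinking-aware
// trajectory ids. State switching is exact in continuous time: within each
// frame interval the displacement variance is integrated piecewise over the
// visited states (2 * sum_i D_i * t_i per axis). Uses R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export]]
DataFrame sim_two_state_cpp(int n_particles, int n_frames, double dt,
                            double d_free, double d_bound,
                            double k_on, double k_off,
                            double sigma, double k_bleach,
                            double half_depth, double slice_half,
                            int blink_max_gap, double fov) {
  RNGScope scope;
  std::vector<int> traj, frame, pid;
  std::vector<double> xs, ys;
  std::vector<int> states; // 1 = bound, 0 = free

  double tot = k_on + k_off;
  double fb = (tot > 0) ? k_on / tot : 0.0;
  double p_bleach = 1.0 - std::exp(-k_bleach * dt);
  int next_traj = 0;

  for (int p = 0; p < n_particles; ++p) {
    int state = (unif_rand() < fb) ? 1 : 0;
    double x = unif_rand() * fov, y = unif_rand() * fov;
    double z = (2.0 * unif_rand() - 1.0) * half_depth;
    double rate = state ? k_off : k_on;
    double t_next = (rate > 0) ? exp_rand() / rate : R_PosInf;
    int last_emit = -1000000, cur_traj = -1;

    for (int f = 0; f < n_frames; ++f) {
      if (f > 0) {
        // advance one frame interval, integrating over state segments
        double remaining = dt, var = 0.0;
        while (t_next < remaining) {
          var += 2.0 * (state ? d_bound : d_free) * t_next;
          remaining -= t_next;
          state = 1 - state;
          rate = state ? k_off : k_on;
          t_next = (rate > 0) ? exp_rand() / rate : R_PosInf;
        }
        if (std::isfinite(t_next)) t_next -= remaining;
        var += 2.0 * (state ? d_bound : d_free) * remaining;
        double sd = std::sqrt(var);
        x += norm_rand() * sd;
        y += norm_rand() * sd;
        z = reflect(z + norm_rand() * sd, half_depth);
        if (p_bleach > 0 && unif_rand() < p_bleach) break; // bleached
      }
      if (std::fabs(z) <= slice_half) {
        if (last_emit < 0 || f - last_emit > blink_max_gap + 1) {
          cur_traj = next_traj++;
        }
        traj.push_back(cur_traj);
        frame.push_back(f);
        pid.push_back(p);
        xs.push_back(x + norm_rand() * sigma);
        ys.push_back(y + norm_rand() * sigma);
        states.push_back(state);
        last_emit = f;
      }
    }
  }

  return DataFrame::create(
    _["trajectory_id"] = wrap(traj),
    _["frame"] = wrap(frame),
    _["x_um"] = wrap(xs),
    _["y_um"] = wrap(ys),
    _["true_state"] = wrap(states),
    _["particle"] = wrap(pid));
}
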