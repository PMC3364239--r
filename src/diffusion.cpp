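#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Marsaglia polar method on top of R's uniform stream: ~2x faster than the
// inversion-based R::norm_rand and still fully reproducible from set.seed().
static double spare_normal;
static bool have_spare = false;

static inline double fast_normal() {
  if (have_spare) { have_spare = false; return spare_normal; }
  double u, v, s;
  do {
    u = 2.0 * R::unif_rand() - 1.0;
    v = 2.0 * R::unif_rand() - 1.0;
    s = u * u + v * v;
  } while (s >= 1.0 || s == 0.0);
  double f = std::sqrt(-2.0 * std::log(s) / s);
  spare_normal = v * f;
  have_spare = true;
  return u * f;
}

// Brownian-dynamics photon emission times for one diffusing species.
//
// n_mol molecules start uniformly distributed in a periodic box with half
// widths (half_x, half_y, half_z) centred on the two-photon observation
// volume. Each step of length dt adds an independent Gaussian displacement of
// SD step_sd per axis (step_sd = sqrt(2 D dt)) and wraps periodically. The
// detected count in a step is Poisson with mean
//   rate_peak * exp(-4 (x^2+y^2)/omega^2 - 4 z^2 / z0^2) * dt,
// the squared-Gaussian two-photon detection weight; photon times are placed
// uniformly within the step. Uses R's RNG so results are reproducible from
// set.seed(). Returns unsorted emission times in seconds.
// [[Rcpp::export(name = ".bd_photon_times")]]
NumericVector bd_photon_times(int n_mol, double n_steps_d, double dt,
                              double step_sd,
                              double half_x, double half_y, double half_z,
                              double omega_um, double z0_um,
                              double rate_peak_cps) {
  const double inv_w2 = 4.0 / (omega_um * omega_um);
  const double inv_z2 = 4.0 / (z0_um * z0_um);
  const double span_x = 2.0 * half_x, span_y = 2.0 * half_y,
               span_z = 2.0 * half_z;
  const double rate_dt = rate_peak_cps * dt;
  const long long n_steps = (long long)n_steps_d;
  // exp(-34) * rate_dt is < 1e-10 photons/step for any sane configuration
  const double arg_cut = 34.0;
  std::vector<double> times;
  times.reserve(1024);
  RNGScope scope;
  have_spare = false;   // never carry RNG state across calls
  for (int m = 0; m < n_mol; ++m) {
    double x = R::runif(-half_x, half_x);
    double y = R::runif(-half_y, half_y);
    double z = R::runif(-half_z, half_z);
    for (long long s = 0; s < n_steps; ++s) {
      x += fast_normal() * step_sd;
      y += fast_normal() * step_sd;
      z += fast_normal() * step_sd;
      // periodic wrap (steps are always << box, one fold suffices)
      if (x > half_x) x -= span_x; else if (x < -half_x) x += span_x;
      if (y > half_y) y -= span_y; else if (y < -half_y) y += span_y;
      if (z > half_z) z -= span_z; else if (z < -half_z) z += span_z;
      double arg = inv_w2 * (x * x + y * y) + inv_z2 * z * z;
      if (arg < arg_cut) {
        double lam = rate_dt * std::exp(-arg);
        int k = (int)R::rpois(lam);
        for (int i = 0; i < k; ++i)
          times.push_back(((double)s + R::unif_rand()) * dt);
      }
    }
    if (m % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return wrap(times);
}
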