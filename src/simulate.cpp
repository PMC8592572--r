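#include <Rcpp.h>
using namespace Rcpp;

// Euler accumulation of the attentional diffusion in 1-ms steps.
// drift: per-dwell drift (evidence units per ms), dur: dwell lengths (ms).
// The first step at or beyond +/- boundary ends the trial (no sub-ms
// interpolation). Uses R's RNG so results are reproducible via set.seed().
// [[Rcpp::export(name = ".addm_accumulate_cpp")]]
List addm_accumulate_cpp(NumericVector drift, IntegerVector dur, double sigma,
                         double boundary, double v0, int max_ms) {
  double V = v0;
  int t = 0;
  int n = drift.size();
  for (int i = 0; i < n; ++i) {
    double mu = drift[i];
    int d = dur[i];
    for (int s = 0; s < d; ++s) {
      if (t >= max_ms)
        return List::create(_["crossed"] = false, _["t"] = t,
                            _["choice"] = 0, _["n_dwell"] = i);
      V += mu + sigma * norm_rand();
      ++t;
      if (V >= boundary)
        return List::create(_["crossed"] = true, _["t"] = t,
                            _["choice"] = 1, _["n_dwell"] = i + 1);
      if (V <= -boundary)
        return List::create(_["crossed"] = true, _["t"] = t,
                            _["choice"] = -1, _["n_dwell"] = i + 1);
    }
  }
  return List::create(_["crossed"] = false, _["t"] = t, _["choice"] = 0,
                      _["n_dwell"] = n);
}

// Constant-drift diffusion (diffusion coefficient 1) simulated by
// Euler-Maruyama between boundaries 0 and a, start z*a, step dt seconds.
// With correct_boundary the boundaries are pulled inward by
// 0.5826*sqrt(dt) (Broadie-Glasserman continuity correction), removing the
// O(sqrt(dt)) overshoot bias of the discrete scheme.
// v may be length 1 (n iid paths) or length n (one path per drift).
// [[Rcpp::export(name = ".euler_ddm_cpp")]]
List euler_ddm_cpp(int n, NumericVector v, double a, double z, double dt,
                   double max_t, bool correct_boundary) {
  NumericVector rt(n);
  IntegerVector up(n);
  double sdt = std::sqrt(dt);
  double shift = correct_boundary ? 0.5826 * sdt : 0.0;
  double lo = shift, hi = a - shift;
  double x0 = z * a;
  if (x0 <= lo || x0 >= hi) stop("start point inside corrected boundaries required");
  int max_steps = (int)std::ceil(max_t / dt);
  for (int i = 0; i < n; ++i) {
    double vi = v.size() == 1 ? v[0] : v[i];
    double x = x0;
    int s = 0;
    int hit = NA_INTEGER;
    while (s < max_steps) {
      x += vi * dt + sdt * norm_rand();
      ++s;
      if (x >= hi) { hit = 1; break; }
      if (x <= lo) { hit = 0; break; }
    }
    rt[i] = s * dt;
    up[i] = hit;
  }
  return List::create(_["rt"] = rt, _["upper"] = up);
}
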