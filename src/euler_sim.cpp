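#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama simulation of an unbiased Wiener diffusion between two
// absorbing boundaries at 0 and alpha, starting from alpha/2, diffusion
// coefficient fixed at 1.  One (drift, boundary, ndt) triple per trial, so
// hierarchical datasets can be simulated in a single call.  Uses R's RNG
// (norm_rand), so results are reproducible under set.seed().
//
// Trials still unabsorbed after max_time are resolved by the sign of the
// current position and reported in the `censored` column; callers warn.
// [[Rcpp::export]]
List euler_sim_cpp(NumericVector drift, NumericVector boundary,
                   NumericVector ndt, double dt, double max_time) {
  const int n = drift.size();
  NumericVector rt(n);
  IntegerVector acc(n);
  IntegerVector censored(n);
  const double sdt = std::sqrt(dt);
  const long max_steps = (long)std::ceil(max_time / dt);

  for (int i = 0; i < n; ++i) {
    const double a = boundary[i];
    const double mu = drift[i] * dt;
    double x = a / 2.0;
    long s = 0;
    while (x > 0.0 && x < a && s < max_steps) {
      x += mu + sdt * norm_rand();
      ++s;
    }
    if (x >= a) {
      acc[i] = 1;
    } else if (x <= 0.0) {
      acc[i] = 0;
    } else {
      acc[i] = (x > a / 2.0) ? 1 : 0;
      censored[i] = 1;
    }
    rt[i] = ndt[i] + (double)s * dt;
  }
  return List::create(_["accuracy"] = acc, _["rt"] = rt,
                      _["censored"] = censored);
}
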