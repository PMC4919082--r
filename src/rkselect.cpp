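#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama first-passage simulation for log-linear (GBM-type) scalar
// life histories.  Integration is carried out in log-size, which preserves
// positivity exactly and makes the scheme exact in distribution per step
// (the log-increment is Gaussian).  Uses R's RNG so set.seed() governs the
// ensemble; paths are simulated sequentially, so enlarging n_paths leaves
// the earlier paths unchanged.
//
// Returns grid-crossing ages (smallest grid age with X >= x*), bridge ages
// (linear interpolation in log-state at overshoot, plus Brownian-bridge
// sampling of within-step crossings that the grid misses), and a censoring
// flag for paths that never reach the mature size before the horizon.
// [[Rcpp::export]]
List fp_gbm_cpp(int n_paths, double u0, double ustar, double nu,
                double sig, double dt, double horizon,
                bool keep_paths = false) {
  RNGScope scope;
  int n_steps = (int)std::ceil(horizon / dt);
  NumericVector age_grid(n_paths), age_bridge(n_paths);
  LogicalVector censored(n_paths);
  NumericMatrix paths;
  if (keep_paths) paths = NumericMatrix(n_paths, n_steps + 1);
  double sqdt = std::sqrt(dt);
  double denom = sig > 0 ? sig * sig * dt : 1.0;
  for (int i = 0; i < n_paths; ++i) {
    double u = u0;
    bool hit = false;
    if (keep_paths) paths(i, 0) = u;
    for (int k = 0; k < n_steps; ++k) {
      double unew = u + nu * dt;
      if (sig > 0) unew += sig * sqdt * norm_rand();
      if (keep_paths) paths(i, k + 1) = unew;
      if (unew >= ustar) {
        age_grid[i] = (k + 1) * dt;
        // exact in the deterministic case, O(dt) correction otherwise
        double frac = (unew > u) ? (ustar - u) / (unew - u) : 1.0;
        age_bridge[i] = (k + frac) * dt;
        hit = true;
      } else if (sig > 0 && u < ustar) {
        // Brownian-bridge probability of an excursion above ustar within
        // the step even though both endpoints lie below it
        double p = std::exp(-2.0 * (ustar - u) * (ustar - unew) / denom);
        if (unif_rand() < p) {
          age_grid[i] = (k + 1) * dt;
          age_bridge[i] = (k + 0.5) * dt;
          hit = true;
        }
      }
      if (hit) {
        if (keep_paths) {
          for (int kk = k + 1; kk <= n_steps; ++kk) paths(i, kk) = ustar;
        }
        break;
      }
      u = unew;
    }
    if (!hit) {
      age_grid[i] = NA_REAL;
      age_bridge[i] = NA_REAL;
      censored[i] = true;
    }
  }
  List out = List::create(_["age_grid"] = age_grid,
                          _["age_bridge"] = age_bridge,
                          _["censored"] = censored,
                          _["dt"] = dt, _["horizon"] = horizon);
  if (keep_paths) out["log_paths"] = paths;
  return out;
}

// Thomas algorithm for tridiagonal systems: lower/upper have length n-1.
// [[Rcpp::export]]
NumericVector thomas_cpp(NumericVector lower, NumericVector diag,
                         NumericVector upper, NumericVector rhs) {
  int n = diag.size();
  NumericVector cp(n), dp(n), x(n);
  cp[0] = upper.size() > 0 ? upper[0] / diag[0] : 0.0;
  dp[0] = rhs[0] / diag[0];
  for (int i = 1; i < n; ++i) {
    double m = diag[i] - lower[i - 1] * cp[i - 1];
    cp[i] = (i < n - 1) ? upper[i] / m : 0.0;
    dp[i] = (rhs[i] - lower[i - 1] * dp[i - 1]) / m;
  }
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dp[i] - cp[i] * x[i + 1];
  return x;
}

// Thomas solve with multiple right-hand sides (columns of rhs).
// [[Rcpp::export]]
NumericMatrix thomas_multi_cpp(NumericVector lower, NumericVector diag,
                               NumericVector upper, NumericMatrix rhs) {
  int n = diag.size(), m = rhs.ncol();
  NumericVector cp(n);
  NumericMatrix x(n, m);
  std::vector<double> mfac(n);
  cp[0] = upper.size() > 0 ? upper[0] / diag[0] : 0.0;
  mfac[0] = diag[0];
  for (int i = 1; i < n; ++i) {
    mfac[i] = diag[i] - lower[i - 1] * cp[i - 1];
    cp[i] = (i < n - 1) ? upper[i] / mfac[i] : 0.0;
  }
  for (int j = 0; j < m; ++j) {
    std::vector<double> dp(n);
    dp[0] = rhs(0, j) / mfac[0];
    for (int i = 1; i < n; ++i)
      dp[i] = (rhs(i, j) - lower[i - 1] * dp[i - 1]) / mfac[i];
    x(n - 1, j) = dp[n - 1];
    for (int i = n - 2; i >= 0; --i) x(i, j) = dp[i] - cp[i] * x(i + 1, j);
  }
  return x;
}
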