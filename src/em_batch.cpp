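#include <Rcpp.h>
#include <cmath>

// Batched EM for the three-component Normal/Binomial/zero mixture.
// One row of V = the neighbor values of one gene; every row is fitted
// independently with exactly the same update rules as the pure-R
// reference (em_init / em_estep / em_mstep / fit_mixture). R's own
// dnorm/dbinom/fround are used so both paths agree to machine precision.

namespace {

struct Params {
  double l1, l2, l3, mu, sigma, p;
  int N;
};

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

inline double comp_density(double x, int j, const Params& par,
                           double zero_tol) {
  if (j == 0) return R::dnorm(x, par.mu, par.sigma, 0);
  if (j == 1) {
    double k = R::fround(x, 0.0);
    if (k < 0.0 || k > par.N) return 0.0;
    return R::dbinom(k, (double)par.N, par.p, 0);
  }
  return std::fabs(x) <= zero_tol ? 1.0 : 0.0;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericMatrix em_fit_batch_cpp(Rcpp::NumericMatrix V, Rcpp::List cfg) {
  const int G = V.nrow();
  const int n = V.ncol();
  if (n < 2) Rcpp::stop("EM needs at least 2 values per gene");

  const int max_iter = Rcpp::as<int>(cfg["max_iter"]);
  const double tol = Rcpp::as<double>(cfg["tol"]);
  const double sigma_floor = Rcpp::as<double>(cfg["sigma_floor"]);
  const double p_floor = Rcpp::as<double>(cfg["p_floor"]);
  const double zero_tol = Rcpp::as<double>(cfg["zero_tol"]);
  const double component_eps = Rcpp::as<double>(cfg["component_eps"]);
  const double weight_eps = Rcpp::as<double>(cfg["weight_eps"]);

  Rcpp::NumericMatrix out(G, 9);
  Rcpp::colnames(out) = Rcpp::CharacterVector::create(
      "lambda1", "lambda2", "lambda3", "mu", "sigma", "N", "p",
      "iterations", "converged");

  std::vector<double> x(n);
  std::vector<double> resp(3 * n);

  for (int g = 0; g < G; ++g) {
    double sum = 0.0;
    for (int i = 0; i < n; ++i) { x[i] = V(g, i); sum += x[i]; }

    // init: mean/sd of values, p0 = 0.1, N0 from the nonzero mean
    Params par;
    par.mu = sum / n;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) ss += (x[i] - par.mu) * (x[i] - par.mu);
    par.sigma = std::sqrt(ss / (n - 1));
    if (par.sigma < sigma_floor) par.sigma = sigma_floor;
    par.p = 0.1;
    double nz_sum = 0.0; int nz_n = 0;
    for (int i = 0; i < n; ++i) if (x[i] > 0) { nz_sum += x[i]; ++nz_n; }
    if (nz_n == 0) par.N = 1;
    else {
      double N0 = R::fround(nz_sum / nz_n / par.p, 0.0);
      par.N = (int)clampd(N0, 1.0, 9.0);
    }
    par.l1 = par.l2 = par.l3 = 1.0 / 3.0;

    bool converged = false;
    int it = 0;
    for (it = 1; it <= max_iter; ++it) {
      // E step: responsibilities with component_eps guard, row-normalized
      for (int i = 0; i < n; ++i) {
        double u0 = par.l1 * comp_density(x[i], 0, par, zero_tol) + component_eps;
        double u1 = par.l2 * comp_density(x[i], 1, par, zero_tol) + component_eps;
        double u2 = par.l3 * comp_density(x[i], 2, par, zero_tol) + component_eps;
        double rs = u0 + u1 + u2;
        resp[3 * i] = u0 / rs;
        resp[3 * i + 1] = u1 / rs;
        resp[3 * i + 2] = u2 / rs;
      }

      // M step
      double P1[3] = {0.0, 0.0, 0.0};
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < 3; ++j) P1[j] += resp[3 * i + j];

      Params nw = par;
      nw.l1 = P1[0] / n; nw.l2 = P1[1] / n; nw.l3 = P1[2] / n;

      if (P1[0] >= weight_eps) {
        double P2 = 0.0;
        for (int i = 0; i < n; ++i) P2 += resp[3 * i] * x[i];
        double mean1 = P2 / P1[0];
        double P3 = 0.0;
        for (int i = 0; i < n; ++i)
          P3 += resp[3 * i] * (x[i] - mean1) * (x[i] - mean1);
        nw.mu = mean1;
        nw.sigma = std::sqrt(P3 / P1[0]);
        if (nw.sigma < sigma_floor) nw.sigma = sigma_floor;
      }

      if (P1[1] >= weight_eps) {
        double P2 = 0.0;
        for (int i = 0; i < n; ++i) P2 += resp[3 * i + 1] * x[i];
        double mean2 = P2 / P1[1];
        double P3 = 0.0;
        for (int i = 0; i < n; ++i)
          P3 += resp[3 * i + 1] * (x[i] - mean2) * (x[i] - mean2);
        double var2 = P3 / P1[1];
        if (mean2 > 0)
          nw.p = clampd(1.0 - var2 / mean2, p_floor, 1.0 - p_floor);
        nw.N = (int)clampd(R::fround(mean2 / nw.p, 0.0), 1.0, 9.0);
        nw.p = clampd(mean2 / nw.N, p_floor, 1.0 - p_floor);
      }

      double delta = std::fabs(nw.l1 - par.l1);
      delta = std::max(delta, std::fabs(nw.l2 - par.l2));
      delta = std::max(delta, std::fabs(nw.l3 - par.l3));
      delta = std::max(delta, std::fabs(nw.mu - par.mu));
      delta = std::max(delta, std::fabs(nw.sigma - par.sigma));
      delta = std::max(delta, std::fabs(nw.p - par.p));
      par = nw;
      if (delta < tol) { converged = true; break; }
    }
    if (it > max_iter) it = max_iter;

    out(g, 0) = par.l1; out(g, 1) = par.l2; out(g, 2) = par.l3;
    out(g, 3) = par.mu; out(g, 4) = par.sigma;
    out(g, 5) = (double)par.N; out(g, 6) = par.p;
    out(g, 7) = (double)it; out(g, 8) = converged ? 1.0 : 0.0;
  }
  return out;
}
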