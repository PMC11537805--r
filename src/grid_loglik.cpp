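#include <Rcpp.h>
using namespace Rcpp;

// Binomial log-likelihood kernel (no binomial coefficient) with the
// boundary convention: a predicted frequency of exactly 0 or 1 contributes
// 0 when the observed count sits on the same boundary and -Inf otherwise.
static inline double binom_term(double k, double total, double p) {
  if (p <= 0.0) return (k > 0.0) ? R_NegInf : 0.0;
  if (p >= 1.0) return (k < total) ? R_NegInf : 0.0;
  return k * std::log(p) + (total - k) * std::log(1.0 - p);
}

// Composite binomial log-likelihood of pooled adult counts, evaluated on a
// full (alpha x beta x gamma) grid with the viability ratios fixed.
// The X-linked frequency recursion is iterated per grid point from each
// setup's founding state (p1_init 0 or 1, all females heterozygous).
//
// Observations arrive pooled per setup: parallel vectors of generation,
// white-male count m, male total M, white-female count n, female total N.
// Result is a vector of length na*nb*ng in column-major order
// (alpha index fastest, then beta, then gamma).
// [[Rcpp::export]]
NumericVector grid_loglik_cpp(NumericVector alpha_grid,
                              NumericVector beta_grid,
                              NumericVector gamma_grid,
                              double mu, double nu, double epsilon,
                              NumericVector p1_init,
                              List gens, List m, List M, List n, List N) {
  const int na = alpha_grid.size(), nb = beta_grid.size(),
            ng = gamma_grid.size();
  const int nsetup = p1_init.size();
  NumericVector out((R_xlen_t)na * nb * ng);

  // per-setup observation arrays and the last generation needed
  std::vector<IntegerVector> gv(nsetup);
  std::vector<NumericVector> mv(nsetup), Mv(nsetup), nv(nsetup), Nv(nsetup);
  std::vector<int> tmax(nsetup);
  for (int s = 0; s < nsetup; ++s) {
    gv[s] = gens[s]; mv[s] = m[s]; Mv[s] = M[s]; nv[s] = n[s]; Nv[s] = N[s];
    int tm = 1;
    for (int i = 0; i < gv[s].size(); ++i) tm = std::max(tm, gv[s][i]);
    tmax[s] = tm;
  }

  R_xlen_t idx = 0;
  for (int ig = 0; ig < ng; ++ig) {
    const double g = gamma_grid[ig];
    for (int ib = 0; ib < nb; ++ib) {
      const double b = beta_grid[ib];
      for (int ia = 0; ia < na; ++ia, ++idx) {
        const double a = alpha_grid[ia];
        double lnL = 0.0;
        for (int s = 0; s < nsetup && lnL > R_NegInf; ++s) {
          double p1 = p1_init[s], Q11 = 0.0, Q12 = 1.0, Q22 = 0.0;
          int nobs = gv[s].size(), iobs = 0;
          // observations sorted by generation on the R side
          for (int t = 1; t <= tmax[s]; ++t) {
            if (t > 1) {
              const double m1 = 2.0 * Q11 * b + Q12;
              const double m2 = 2.0 * Q22 * g + Q12;
              const double p1n = m1 * mu / (m1 * mu + m2);
              const double W11 = p1 * a * m1 * nu;
              const double W12 = p1 * a * m2 + (1.0 - p1) * m1;
              const double W22 = (1.0 - p1) * m2 * epsilon;
              const double W = W11 + W12 + W22;
              p1 = p1n; Q11 = W11 / W; Q12 = W12 / W; Q22 = W22 / W;
            }
            while (iobs < nobs && gv[s][iobs] == t) {
              lnL += binom_term(mv[s][iobs], Mv[s][iobs], p1);
              lnL += binom_term(nv[s][iobs], Nv[s][iobs], Q11);
              ++iobs;
            }
          }
        }
        out[idx] = lnL;
      }
    }
  }
  return out;
}
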