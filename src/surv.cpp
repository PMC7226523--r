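#include <Rcpp.h>
using namespace Rcpp;

// Single-covariate Cox proportional-hazards fit by Newton-Raphson on the
// Efron-approximated partial likelihood. Used for the univariate screening
// step, where hundreds of thousands of one-dimensional fits are needed.

// [[Rcpp::export]]
List cpp_coxph1(NumericVector x, NumericVector time, IntegerVector status,
                int max_iter = 25, double tol = 1e-9) {
  int n = x.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return time[a] < time[b]; });

  double beta = 0.0, loglik = 0.0, imat = 0.0;
  bool converged = false;

  auto pass = [&](double b, double &ll, double &U, double &I) {
    ll = 0; U = 0; I = 0;
    double S0 = 0, S1 = 0, S2 = 0;
    int i = n - 1;
    while (i >= 0) {
      double t = time[ord[i]];
      // add everyone with this time to the risk set
      int j = i;
      double s0d = 0, s1d = 0, s2d = 0, sumx = 0;
      int d = 0;
      while (j >= 0 && time[ord[j]] == t) {
        double xi = x[ord[j]];
        double w = std::exp(b * xi);
        S0 += w; S1 += w * xi; S2 += w * xi * xi;
        if (status[ord[j]]) { ++d; s0d += w; s1d += w * xi; s2d += w * xi * xi; sumx += xi; }
        --j;
      }
      if (d > 0) {
        ll += b * sumx;
        U += sumx;
        for (int l = 0; l < d; ++l) {
          double f = (double)l / d;
          double p0 = S0 - f * s0d, p1 = S1 - f * s1d, p2 = S2 - f * s2d;
          ll -= std::log(p0);
          U -= p1 / p0;
          I += p2 / p0 - (p1 / p0) * (p1 / p0);
        }
      }
      i = j;
    }
  };

  double ll, U, I;
  pass(beta, ll, U, I);
  double ll0 = ll;
  for (int it = 0; it < max_iter; ++it) {
    if (I <= 0) break;
    double step = U / I;
    double nb = beta + step;
    if (nb > 22) nb = 22; if (nb < -22) nb = -22;
    double ll2, U2, I2;
    pass(nb, ll2, U2, I2);
    int halving = 0;
    while (ll2 < ll && halving < 20) {  // step halving
      nb = (beta + nb) / 2;
      pass(nb, ll2, U2, I2);
      ++halving;
    }
    bool done = std::fabs(ll2 - ll) < tol;
    beta = nb; ll = ll2; U = U2; I = I2;
    if (done) { converged = true; break; }
  }
  loglik = ll; imat = I;
  double se = imat > 0 ? 1.0 / std::sqrt(imat) : NA_REAL;
  return List::create(_["beta"] = beta, _["se"] = se,
                      _["loglik"] = loglik, _["loglik0"] = ll0,
                      _["converged"] = converged);
}

// Harrell concordance counting over comparable pairs: pairs with distinct
// survival times whose earlier time is an observed event. Tied-time pairs are
// not comparable (in particular two events at the same time). Tied risk
// scores in a comparable pair contribute 0.5.

// [[Rcpp::export]]
List cpp_concordance(NumericVector risk, NumericVector time, IntegerVector status) {
  int n = risk.size();
  double conc = 0, disc = 0, tied = 0;
  long comparable = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (time[i] == time[j]) continue;
      int s = time[i] < time[j] ? i : j;   // shorter time
      int l = s == i ? j : i;
      if (!status[s]) continue;
      ++comparable;
      if (risk[s] > risk[l]) conc += 1;
      else if (risk[s] == risk[l]) tied += 1;
      else disc += 1;
    }
  double ci = comparable > 0 ? (conc + 0.5 * tied) / comparable : NA_REAL;
  return List::create(_["ci"] = ci, _["concordant"] = conc, _["discordant"] = disc,
                      _["tied_risk"] = tied, _["comparable"] = (double)comparable);
}
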