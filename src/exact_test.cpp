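#include <Rcpp.h>
using namespace Rcpp;

// Two-sided p-value of the conditional NB exact test for one gene.
// Conditional on the total t = z1 + z2 of two group sums with sizes
// n1/phi and n2/phi (library sizes equalized upstream), every split
// y + (t - y) is scored by its conditional probability and the p-value is
// the total mass of outcomes no more probable than the observed split
// ("small p" convention, ties included), capped at 1.
//
// With equalized libraries the per-sample mean cancels out of the
// conditional distribution, so only the gamma terms and the split remain.
static double exact_pval_one(int z1, int z2, double n1, double n2,
                             double phi) {
  const int t = z1 + z2;
  if (t == 0) return 1.0;
  const double r1 = n1 / phi, r2 = n2 / phi;
  std::vector<double> lp(t + 1);
  double m = R_NegInf;
  for (int y = 0; y <= t; ++y) {
    lp[y] = R::lgammafn(y + r1) - R::lgammafn(y + 1.0) +
            R::lgammafn(t - y + r2) - R::lgammafn(t - y + 1.0);
    if (lp[y] > m) m = lp[y];
  }
  double tot = 0.0, tail = 0.0;
  const double obs = lp[z1];
  const double cut = obs + 1e-10 * std::fabs(obs);  // relative tie tolerance
  for (int y = 0; y <= t; ++y) {
    const double w = std::exp(lp[y] - m);
    tot += w;
    if (lp[y] <= cut) tail += w;
  }
  double p = tail / tot;
  return p > 1.0 ? 1.0 : p;
}

// [[Rcpp::export]]
NumericVector exact_nb_pvals(IntegerVector z1, IntegerVector z2,
                             double n1, double n2, NumericVector phi) {
  const int G = z1.size();
  if (z2.size() != G || phi.size() != G)
    stop("z1, z2 and phi must have equal length");
  NumericVector p(G);
  for (int g = 0; g < G; ++g) {
    if (z1[g] < 0 || z2[g] < 0) stop("negative group sum");
    double ph = phi[g];
    if (!(ph > 0)) ph = 1e-8;   // Poisson limit approached from above
    p[g] = exact_pval_one(z1[g], z2[g], n1, n2, ph);
  }
  return p;
}
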