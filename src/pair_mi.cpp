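#include <Rcpp.h>
using namespace Rcpp;

// Mutual information (nats) between all column pairs of an integer-coded
// alignment. X is N x C with values in 1..nsym. The pseudocount is a total
// prior mass spread uniformly over the joint alphabet: each joint cell gets
// pseudocount/nsym^2 and each marginal cell pseudocount/nsym, so joint and
// marginal smoothed frequencies stay consistent and MI of an independent
// pair is not inflated by the prior.
// [[Rcpp::export(name = ".pair_mi")]]
NumericMatrix pair_mi(IntegerMatrix X, int nsym, double pseudocount) {
  const int N = X.nrow(), C = X.ncol();
  NumericMatrix MI(C, C);
  const double lam_joint = pseudocount / (double)(nsym * nsym);
  const double lam_marg = pseudocount / (double)nsym;
  const double tot = (double)N + pseudocount;

  NumericMatrix marg(nsym, C);
  for (int c = 0; c < C; ++c) {
    for (int r = 0; r < N; ++r) {
      int v = X(r, c);
      if (v < 1 || v > nsym) stop("symbol code out of range");
      marg(v - 1, c) += 1.0;
    }
  }

  std::vector<double> joint((size_t)nsym * nsym);
  std::vector<double> lfa(nsym), lfb(nsym);
  for (int a = 0; a < C; ++a) {
    for (int x = 0; x < nsym; ++x) lfa[x] = (marg(x, a) + lam_marg) / tot;
    for (int b = a + 1; b < C; ++b) {
      std::fill(joint.begin(), joint.end(), 0.0);
      for (int r = 0; r < N; ++r)
        joint[(size_t)(X(r, a) - 1) * nsym + (X(r, b) - 1)] += 1.0;
      for (int y = 0; y < nsym; ++y) lfb[y] = (marg(y, b) + lam_marg) / tot;
      double mi = 0.0;
      for (int x = 0; x < nsym; ++x) {
        const double fa = lfa[x];
        const double *jrow = &joint[(size_t)x * nsym];
        for (int y = 0; y < nsym; ++y) {
          const double fab = (jrow[y] + lam_joint) / tot;
          if (fab > 0.0) mi += fab * std::log(fab / (fa * lfb[y]));
        }
      }
      MI(a, b) = mi;
      MI(b, a) = mi;
    }
  }
  return MI;
}
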