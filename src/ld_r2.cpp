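#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Mean squared Burrows composite correlation over all locus pairs of a
// complete (NA-free) dose matrix, with an optional delete-one-individual
// jackknife.  For a pair (a, b):
//   Delta = (S/(S-1)) * (mean(x_a x_b)/2 - 2 p_a p_b)
//   r2    = Delta^2 / (p_a(1-p_a) p_b(1-p_b))
// which is the estimator the random-mating small-sample bias corrections
// of the LD-Ne literature are calibrated for.  Loci monomorphic in the
// (sub)sample are skipped.  Crossproducts are computed once and downdated
// per individual, so each jackknife replicate costs O(L^2).
// [[Rcpp::export]]
List mean_r2_complete(const arma::mat& X, bool jackknife) {
  const int n = X.n_rows, L = X.n_cols;
  arma::rowvec s = arma::sum(X, 0);
  arma::mat C = X.t() * X;

  auto accumulate = [&](const arma::vec& sv, const arma::mat& Cm,
                        const arma::rowvec* xk, int S,
                        double& total, long long& npairs) {
    arma::vec p(L), den(L);
    for (int a = 0; a < L; ++a) {
      p(a) = sv(a) / (2.0 * S);
      den(a) = p(a) * (1.0 - p(a));
    }
    const double fac = (double)S / (S - 1);
    for (int a = 0; a < L - 1; ++a) {
      if (den(a) <= 0) continue;
      for (int b = a + 1; b < L; ++b) {
        if (den(b) <= 0) continue;
        double cab = Cm(a, b);
        if (xk) cab -= (*xk)(a) * (*xk)(b);
        double P = cab / (2.0 * S);
        double D = fac * (P - 2.0 * p(a) * p(b));
        total += D * D / (den(a) * den(b));
        ++npairs;
      }
    }
  };

  double total = 0.0;
  long long npairs = 0;
  accumulate(s.t(), C, nullptr, n, total, npairs);
  double mean_full = npairs > 0 ? total / npairs : NA_REAL;

  NumericVector jack(jackknife ? n : 0);
  if (jackknife) {
    for (int k = 0; k < n; ++k) {
      arma::rowvec xk = X.row(k);
      arma::vec sk = (s - xk).t();
      double tot = 0.0;
      long long cnt = 0;
      accumulate(sk, C, &xk, n - 1, tot, cnt);
      jack[k] = cnt > 0 ? tot / cnt : NA_REAL;
    }
  }
  return List::create(_["mean_r2"] = mean_full,
                      _["n_pairs"] = (double)npairs,
                      _["jack"] = jack);
}
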