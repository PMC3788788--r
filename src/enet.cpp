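#include <Rcpp.h>
using namespace Rcpp;

// Elastic-net coordinate descent on the Gram ("covariance") form.
//
// Objective, with X the n x p design and y the response:
//   f(beta) = 1/(2n) * ||y - X beta||^2
//           + lambda * ( alpha * ||beta||_1 + (1 - alpha)/2 * ||beta||_2^2 )
// No intercept, no column standardization: callers pass G = X'X and b = X'y.
//
// Coordinate update for j:
//   z_j    = ( b_j - sum_{k != j} G_jk beta_k ) / n
//   beta_j = S(z_j, lambda * alpha) / ( G_jj / n + lambda * (1 - alpha) )
// where S is the soft-threshold operator. G_jj == 0 (empty predictor column)
// pins beta_j at 0.

static inline double soft_threshold(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// [[Rcpp::export(name = ".enet_path_gram")]]
NumericMatrix enet_path_gram(NumericMatrix G, NumericVector b, double n,
                             NumericVector lambda, double alpha,
                             double tol, int max_iter) {
  const int p = G.ncol();
  const int nlam = lambda.size();
  if (G.nrow() != p) stop("G must be square");
  if (b.size() != p) stop("length(b) must equal ncol(G)");
  if (n <= 0) stop("n must be positive");

  NumericMatrix beta_path(p, nlam);
  std::vector<double> beta(p, 0.0);
  std::vector<double> gdiag(p);
  for (int j = 0; j < p; ++j) gdiag[j] = G(j, j);

  // warm starts down the (assumed decreasing) lambda sequence
  for (int l = 0; l < nlam; ++l) {
    const double lam = lambda[l];
    const double l1 = lam * alpha;
    const double l2 = lam * (1.0 - alpha);
    for (int it = 0; it < max_iter; ++it) {
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        if (gdiag[j] <= 0.0) { beta[j] = 0.0; continue; }
        double dot = 0.0;
        const double *gj = &G(0, j);
        for (int k = 0; k < p; ++k) dot += gj[k] * beta[k];
        dot -= gdiag[j] * beta[j];
        const double z = (b[j] - dot) / n;
        const double bj = soft_threshold(z, l1) / (gdiag[j] / n + l2);
        const double d = std::fabs(bj - beta[j]);
        if (d > max_delta) max_delta = d;
        beta[j] = bj;
      }
      if (max_delta < tol) break;
    }
    for (int j = 0; j < p; ++j) beta_path(j, l) = beta[j];
  }
  return beta_path;
}
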