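#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// k nearest neighbours (self included, at position 1) under Euclidean
// distance, computed blockwise via the expansion |x-y|^2 = |x|^2 - 2x.y + |y|^2.
// Ties are broken by cell index so results are deterministic.
// [[Rcpp::export]]
Rcpp::IntegerMatrix knn_euclidean(const arma::mat& X, const int k) {
  const int n = X.n_rows;
  if (k > n) Rcpp::stop("k must not exceed the number of rows");
  arma::vec sq = arma::sum(arma::square(X), 1);
  Rcpp::IntegerMatrix out(n, k);

  const int block = 1024;
  std::vector<std::pair<double, int>> cand(n);
  for (int start = 0; start < n; start += block) {
    const int end = std::min(start + block, n);
    arma::mat D = X.rows(start, end - 1) * X.t();  // (end-start) x n
    for (int i = start; i < end; ++i) {
      const int r = i - start;
      for (int j = 0; j < n; ++j) {
        cand[j] = {sq(i) - 2.0 * D(r, j) + sq(j), j};
      }
      std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
      for (int j = 0; j < k; ++j) out(i, j) = cand[j].second + 1;
    }
  }
  return out;
}
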