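#include <Rcpp.h>
using namespace Rcpp;

// L1 (Manhattan) distances from every row of `points` to every row of
// `centroids`; the assignment-step kernel of the state clustering.
// [[Rcpp::export(name = ".l1_cross_dist_cpp")]]
NumericMatrix l1_cross_dist_cpp(NumericMatrix points, NumericMatrix centroids) {
  const int m = points.nrow(), d = points.ncol(), k = centroids.nrow();
  NumericMatrix out(m, k);
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < d; ++c) {
      const double mu = centroids(j, c);
      for (int i = 0; i < m; ++i) {
        out(i, j) += std::fabs(points(i, c) - mu);
      }
    }
  }
  return out;
}
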