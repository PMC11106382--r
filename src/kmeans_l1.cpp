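#include <Rcpp.h>
using namespace Rcpp;

// One full run of the hybrid L1-assignment / mean-update k-means from given
// initial centroids. Returns assignments (1-based), centroids, the
// squared-error objective trace, and a convergence flag.
// [[Rcpp::export(name = ".kmeans_l1_run_cpp")]]
List kmeans_l1_run_cpp(NumericMatrix points, NumericMatrix init,
                       int max_iter) {
  const int m = points.nrow(), d = points.ncol(), k = init.nrow();
  NumericMatrix centroids(clone(init));
  IntegerVector assign_cur(m), assign_prev(m, -1);
  std::vector<double> trace;
  bool converged = false;

  for (int it = 0; it < max_iter; ++it) {
    // assignment step: nearest centroid under L1
    std::vector<double> dist_own(m);
    for (int i = 0; i < m; ++i) {
      double best = R_PosInf;
      int besti = 0;
      for (int j = 0; j < k; ++j) {
        double s = 0.0;
        for (int c = 0; c < d; ++c) s += std::fabs(points(i, c) - centroids(j, c));
        if (s < best) { best = s; besti = j; }
      }
      assign_cur[i] = besti;
      dist_own[i] = best;
    }
    // re-seed any empty cluster at the point farthest from its centroid
    std::vector<int> counts(k, 0);
    for (int i = 0; i < m; ++i) counts[assign_cur[i]]++;
    for (int j = 0; j < k; ++j) {
      if (counts[j] == 0) {
        int far = 0;
        double fd = -1.0;
        for (int i = 0; i < m; ++i)
          if (dist_own[i] > fd) { fd = dist_own[i]; far = i; }
        counts[assign_cur[far]]--;
        assign_cur[far] = j;
        counts[j] = 1;
        dist_own[far] = -1.0; // exclude from further re-seeding
      }
    }
    // update step: cluster means
    std::fill(centroids.begin(), centroids.end(), 0.0);
    for (int i = 0; i < m; ++i)
      for (int c = 0; c < d; ++c) centroids(assign_cur[i], c) += points(i, c);
    for (int j = 0; j < k; ++j)
      for (int c = 0; c < d; ++c) centroids(j, c) /= counts[j];
    // squared-error objective (Eq. style: within-cluster sum of squares)
    double obj = 0.0;
    for (int i = 0; i < m; ++i)
      for (int c = 0; c < d; ++c) {
        const double r = points(i, c) - centroids(assign_cur[i], c);
        obj += r * r;
      }
    trace.push_back(obj);
    bool same = true;
    for (int i = 0; i < m; ++i)
      if (assign_cur[i] != assign_prev[i]) { same = false; break; }
    if (same) { converged = true; break; }
    assign_prev = clone(assign_cur);
  }
  return List::create(_["assignments"] = assign_cur + 1,
                      _["centroids"] = centroids,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["converged"] = converged);
}
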