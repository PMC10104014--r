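#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Exact Euclidean k-nearest neighbors, brute force with a per-query
// bounded selection. `query` and `ref` are d x n matrices (points in
// columns, cache-friendly). Ties are broken by ascending reference index.
// When `self` is true the i-th query is assumed to be the i-th reference
// point and is excluded from its own neighbor list.
// [[Rcpp::export]]
List knn_cpp(NumericMatrix query, NumericMatrix ref, int k, bool self) {
  const int d = query.nrow();
  const int nq = query.ncol();
  const int nr = ref.ncol();
  if (ref.nrow() != d) stop("dimension mismatch");
  if (k < 1 || k > nr - (self ? 1 : 0)) stop("invalid k");

  IntegerMatrix idx(nq, k);
  NumericMatrix dist(nq, k);
  typedef std::pair<double, int> DI;  // (squared distance, ref index)

  std::vector<DI> heap;
  heap.reserve(k + 1);
  const double* rp = REAL(ref);
  const double* qp = REAL(query);

  for (int i = 0; i < nq; ++i) {
    heap.clear();
    const double* q = qp + (size_t)i * d;
    for (int j = 0; j < nr; ++j) {
      if (self && j == i) continue;
      const double* r = rp + (size_t)j * d;
      // four partial accumulators let the compiler pipeline the FP adds
      double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
      int t = 0;
      for (; t + 4 <= d; t += 4) {
        double d0 = q[t] - r[t];
        double d1 = q[t + 1] - r[t + 1];
        double d2 = q[t + 2] - r[t + 2];
        double d3 = q[t + 3] - r[t + 3];
        s0 += d0 * d0; s1 += d1 * d1; s2 += d2 * d2; s3 += d3 * d3;
      }
      for (; t < d; ++t) {
        double diff = q[t] - r[t];
        s0 += diff * diff;
      }
      double s = (s0 + s1) + (s2 + s3);
      DI cand(s, j);
      if ((int)heap.size() < k) {
        heap.push_back(cand);
        std::push_heap(heap.begin(), heap.end());
      } else if (cand < heap.front()) {
        std::pop_heap(heap.begin(), heap.end());
        heap.back() = cand;
        std::push_heap(heap.begin(), heap.end());
      }
    }
    std::sort_heap(heap.begin(), heap.end());
    for (int t = 0; t < k; ++t) {
      idx(i, t) = heap[t].second + 1;  // 1-based for R
      dist(i, t) = std::sqrt(heap[t].first);
    }
  }
  return List::create(Named("idx") = idx, Named("dist") = dist);
}
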