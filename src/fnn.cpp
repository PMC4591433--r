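#include <Rcpp.h>
using namespace Rcpp;

// Nearest-neighbour statistics for the false-nearest-neighbour test.
//
// Base points are the delay vectors of dimension `d` (0-based start index
// i, coordinates x[i + m*lag], m = 0..d-1) that can also be extended to
// dimension d+1, i.e. i + d*lag < N. For each base point the nearest
// neighbour under the Euclidean metric is searched among all base points j
// with |i - j| > theiler (j == i is always excluded). Ties are broken by
// the smallest index. Returns the d-dimensional neighbour distance R_d and
// the extra-coordinate increment |x[i + d*lag] - x[j + d*lag]|.
// [[Rcpp::export]]
List fnn_neighbor_stats(NumericVector x, int lag, int d, int theiler) {
  int N = x.size();
  if (lag < 1) stop("lag must be >= 1");
  if (d < 1) stop("dimension must be >= 1");
  int M = N - d * lag;
  if (M < 2) stop("series too short for this embedding dimension and lag");
  NumericVector dist(M), delta(M);
  LogicalVector found(M);
  for (int i = 0; i < M; ++i) {
    double best = R_PosInf;
    int bj = -1;
    for (int j = 0; j < M; ++j) {
      int sep = i - j; if (sep < 0) sep = -sep;
      if (sep <= theiler) continue;
      double s = 0.0;
      for (int m = 0; m < d; ++m) {
        double diff = x[i + m * lag] - x[j + m * lag];
        s += diff * diff;
        if (s >= best) break;
      }
      if (s < best) { best = s; bj = j; }
    }
    if (bj < 0) {
      found[i] = false; dist[i] = NA_REAL; delta[i] = NA_REAL;
    } else {
      found[i] = true;
      dist[i] = std::sqrt(best);
      delta[i] = std::fabs(x[i + d * lag] - x[bj + d * lag]);
    }
  }
  return List::create(_["dist"] = dist, _["delta"] = delta,
                      _["found"] = found);
}
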