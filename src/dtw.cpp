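#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Dependent (multivariate) DTW: dynamic program over the K x K' grid with
// squared per-frame Euclidean local cost and steps {(-1,-1),(-1,0),(0,-1)},
// boundary (1,1) -> (K,K'). Returns the minimal cumulative squared cost;
// the R wrapper takes the square root by default.
// [[Rcpp::export]]
double dtw_dependent_cost(NumericMatrix a, NumericMatrix b) {
  const int ka = a.nrow(), kb = b.nrow(), m = a.ncol();
  if (b.ncol() != m) stop("trajectories must share the same number of contacts");
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(kb), curr(kb);
  for (int i = 0; i < ka; ++i) {
    for (int j = 0; j < kb; ++j) {
      double c = 0.0;
      for (int d = 0; d < m; ++d) {
        double diff = a(i, d) - b(j, d);
        c += diff * diff;
      }
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else {
        best = inf;
        if (i > 0 && j > 0 && prev[j - 1] < best) best = prev[j - 1];
        if (i > 0 && prev[j] < best) best = prev[j];
        if (j > 0 && curr[j - 1] < best) best = curr[j - 1];
      }
      curr[j] = c + best;
    }
    std::swap(prev, curr);
  }
  return prev[kb - 1];
}
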