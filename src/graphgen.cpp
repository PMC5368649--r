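#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// G(n, p) edge sampling by geometric skipping over the n*(n-1)/2 node pairs
// in lexicographic order; O(expected edges) time, driven by R's RNG so that
// set.seed() in the caller makes it reproducible. Returns a 2-column
// (0-based) edge matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_er_edges(int n, double p) {
  std::vector<int> ei, ej;
  if (p >= 1.0) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) { ei.push_back(i); ej.push_back(j); }
  } else if (p > 0.0) {
    const double total = 0.5 * (double)n * (double)(n - 1);
    const double log1mp = std::log1p(-p);
    double idx = -1.0;
    // row_start(i) = linear index of pair (i, i+1)
    int i = 0;
    double row_start = 0.0, row_len = n - 1;
    for (;;) {
      double u = unif_rand();
      if (u <= 0.0) u = 1e-300;
      idx += 1.0 + std::floor(std::log(u) / log1mp);
      if (idx >= total) break;
      while (idx >= row_start + row_len) {
        row_start += row_len;
        row_len -= 1.0;
        ++i;
      }
      int j = i + 1 + (int)(idx - row_start);
      ei.push_back(i);
      ej.push_back(j);
    }
  }
  IntegerMatrix out(ei.size(), 2);
  for (size_t k = 0; k < ei.size(); ++k) {
    out(k, 0) = ei[k];
    out(k, 1) = ej[k];
  }
  return out;
}
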