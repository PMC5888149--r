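// Spatiotemporal flood fill over burned pixel-observations.
// Two observations are linked when their pixels are identical or adjacent
// under the requested connectivity AND their burn dates differ by at most
// date_gap days; fires are the connected components of that relation.
#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector floodfill_cpp(IntegerVector row, IntegerVector col,
                            IntegerVector date, int n_rows, int n_cols,
                            int connectivity, int date_gap) {
  int n = row.size();
  IntegerVector label(n, 0);
  if (n == 0) return label;

  // per-pixel observation lists
  std::vector<std::vector<int> > at_pixel((size_t)n_rows * n_cols);
  for (int i = 0; i < n; ++i)
    at_pixel[(size_t)(row[i] - 1) + (size_t)(col[i] - 1) * n_rows].push_back(i);

  int ndir;
  static const int dr8[] = {0, -1, 1, 0, 0, -1, -1, 1, 1};
  static const int dc8[] = {0, 0, 0, -1, 1, -1, 1, -1, 1};
  ndir = (connectivity == 8) ? 9 : 5;  // first entry is the same pixel

  std::vector<int> stack;
  int comp = 0;
  for (int s = 0; s < n; ++s) {
    if (label[s] != 0) continue;
    ++comp;
    label[s] = comp;
    stack.push_back(s);
    while (!stack.empty()) {
      int j = stack.back();
      stack.pop_back();
      int r = row[j], c = col[j];
      for (int d = 0; d < ndir; ++d) {
        int rr = r + dr8[d], cc = c + dc8[d];
        if (rr < 1 || rr > n_rows || cc < 1 || cc > n_cols) continue;
        const std::vector<int>& obs = at_pixel[(size_t)(rr - 1) + (size_t)(cc - 1) * n_rows];
        for (size_t q = 0; q < obs.size(); ++q) {
          int k = obs[q];
          if (label[k] != 0) continue;
          if (std::abs(date[j] - date[k]) <= date_gap) {
            label[k] = comp;
            stack.push_back(k);
          }
        }
      }
    }
  }
  return label;
}
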