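#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary mask.
// Scan order is row-major (row 0 at top), so components are labeled 1..K in
// raster order of their first (top-left-most) pixel. Connectivity 4 or 8.
// [[Rcpp::export(name = ".label_cc")]]
IntegerMatrix label_cc(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  int dr4[] = {-1, 1, 0, 0};
  int dc4[] = {0, 0, -1, 1};
  int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  int nn = connectivity == 8 ? 8 : 4;
  int label = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) == 0 || out(r, c) != 0) continue;
      ++label;
      stack.push_back(r + c * nr);
      out(r, c) = label;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = cr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) != 0 && out(r2, c2) == 0) {
            out(r2, c2) = label;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return out;
}
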