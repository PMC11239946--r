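#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling by stack-based region growing.
// Components are numbered 1..N in raster-scan order (row by row, left to
// right) of their first-encountered pixel, which makes labels deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask,
                                   const int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  static const int dr4[] = {-1, 1, 0, 0};
  static const int dc4[] = {0, 0, -1, 1};
  static const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int nn = (connectivity == 4) ? 4 : 8;
  const int* dr = (connectivity == 4) ? dr4 : dr8;
  const int* dc = (connectivity == 4) ? dc4 : dc8;
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      while (!stack.empty()) {
        const std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < nn; ++k) {
          const int r = p.first + dr[k], c = p.second + dc[k];
          if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
          if (mask(r, c) && lab(r, c) == 0) {
            lab(r, c) = next;
            stack.push_back(std::make_pair(r, c));
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
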