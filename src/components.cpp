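#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Connected-component labelling of a logical matrix by iterative flood fill.
// connectivity: 4 (edge neighbours) or 8 (edge + diagonal). Labels are
// 1..n_components in scan order (column-major, matching R's indexing), 0 is
// background. Scan order makes the lowest-index tie-break downstream trivial.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity = 8) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(c * nr + r);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = cr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(c2 * nr + r2);
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
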