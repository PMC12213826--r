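// 8-connected component labeling of a binary mask (BFS flood fill).

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      stack.clear();
      stack.push_back(r0 + c0 * nr);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int r = idx % nr, c = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            const int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(rr + cc * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
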