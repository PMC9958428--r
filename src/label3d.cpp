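// 3-D connected-component labelling (6-connectivity) for binary volumes.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Labels TRUE voxels with positive component ids (0 = background).
// [[Rcpp::export(name = ".label3dCore")]]
IntegerVector label3dCore(LogicalVector vol, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const int *v = LOGICAL(vol);
  IntegerVector labels(n, 0);
  int *lab = INTEGER(labels);
  std::vector<R_xlen_t> stack;
  int nextLabel = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!v[start] || lab[start]) continue;
    ++nextLabel;
    lab[start] = nextLabel;
    stack.push_back(start);
    while (!stack.empty()) {
      const R_xlen_t p = stack.back();
      stack.pop_back();
      const int i = (int)(p % n1);
      const int j = (int)((p / n1) % n2);
      const int k = (int)(p / ((R_xlen_t)n1 * n2));
      const R_xlen_t nb[6] = {p - 1, p + 1, p - n1, p + n1,
                              p - (R_xlen_t)n1 * n2, p + (R_xlen_t)n1 * n2};
      const bool ok[6] = {i > 0, i < n1 - 1, j > 0, j < n2 - 1,
                          k > 0, k < n3 - 1};
      for (int d = 0; d < 6; ++d) {
        if (!ok[d]) continue;
        const R_xlen_t q = nb[d];
        if (v[q] && !lab[q]) {
          lab[q] = nextLabel;
          stack.push_back(q);
        }
      }
    }
  }
  return labels;
}
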