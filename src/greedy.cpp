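#include <Rcpp.h>
using namespace Rcpp;

// Greedy match assignment over candidates pre-sorted by ascending match
// score (ties already broken): accept a candidate iff its exposed member
// still has capacity and (unless reuse is allowed) its control is unused.
// [[Rcpp::export]]
LogicalVector greedy_assign_cpp(IntegerVector exposed, IntegerVector control,
                                int n_exposed, int n_control, int max_controls,
                                bool allow_control_reuse) {
  int n = exposed.size();
  LogicalVector accept(n);
  std::vector<int> taken(n_exposed + 1, 0);
  std::vector<char> used(n_control + 1, 0);
  for (int i = 0; i < n; ++i) {
    int e = exposed[i], c = control[i];
    if (taken[e] >= max_controls) continue;
    if (!allow_control_reuse && used[c]) continue;
    taken[e] += 1;
    used[c] = 1;
    accept[i] = true;
  }
  return accept;
}
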