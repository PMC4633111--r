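#include <Rcpp.h>
using namespace Rcpp;

// Double-edge-swap loop for degree-preserving rewiring. The candidate
// edge indices and orientation flips are drawn in R beforehand, so the
// procedure is a deterministic function of them (and hence of the seed).
// adj is modified in place (the caller passes a copy); edges is 1-based.
// [[Rcpp::export(name = ".maslov_swaps_cpp")]]
int maslov_swaps_cpp(NumericMatrix adj, IntegerMatrix edges,
                     IntegerVector e1s, IntegerVector e2s,
                     LogicalVector flips) {
  int done = 0;
  int attempts = e1s.size();
  for (int t = 0; t < attempts; ++t) {
    int e1 = e1s[t] - 1, e2 = e2s[t] - 1;
    if (e1 == e2) continue;
    int a = edges(e1, 0), b = edges(e1, 1);
    int c = edges(e2, 0), d = edges(e2, 1);
    if (flips[t]) { int tmp = c; c = d; d = tmp; }
    if (a == d || c == b) continue;
    if (adj(a - 1, d - 1) != 0 || adj(c - 1, b - 1) != 0) continue;
    adj(a - 1, b - 1) = adj(b - 1, a - 1) = 0;
    adj(c - 1, d - 1) = adj(d - 1, c - 1) = 0;
    adj(a - 1, d - 1) = adj(d - 1, a - 1) = 1;
    adj(c - 1, b - 1) = adj(b - 1, c - 1) = 1;
    edges(e1, 0) = std::min(a, d); edges(e1, 1) = std::max(a, d);
    edges(e2, 0) = std::min(c, b); edges(e2, 1) = std::max(c, b);
    ++done;
  }
  return done;
}
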