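#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Maslov-Sneppen double-edge swap preserving the degree sequence.
// edges: E x 2 matrix of 0-based endpoints, i < j. Uses R's RNG so results
// are reproducible under set.seed(). Returns the rewired edge list plus the
// accepted/attempted counts; the R wrapper turns a shortfall into an error.
// [[Rcpp::export(name = ".double_edge_swap_cpp")]]
List double_edge_swap_cpp(IntegerMatrix edges, int n_nodes, int target_swaps,
                          int max_tries) {
  int E = edges.nrow();
  std::vector<int> a(E), b(E);
  std::unordered_set<long long> present;
  present.reserve(E * 2);
  auto key = [n_nodes](int u, int v) {
    if (u > v) std::swap(u, v);
    return (long long)u * n_nodes + v;
  };
  for (int e = 0; e < E; ++e) {
    a[e] = edges(e, 0); b[e] = edges(e, 1);
    present.insert(key(a[e], b[e]));
  }
  int accepted = 0, tries = 0;
  while (accepted < target_swaps && tries < max_tries) {
    ++tries;
    int e1 = (int)(unif_rand() * E), e2 = (int)(unif_rand() * E);
    if (e1 == e2) continue;
    int u = a[e1], v = b[e1], x = a[e2], y = b[e2];
    if (unif_rand() < 0.5) std::swap(x, y); // random orientation
    // propose (u,x) and (v,y)
    if (u == x || v == y) continue;
    if (present.count(key(u, x)) || present.count(key(v, y))) continue;
    present.erase(key(u, v));
    present.erase(key(x, y));
    present.insert(key(u, x));
    present.insert(key(v, y));
    a[e1] = u; b[e1] = x;
    a[e2] = v; b[e2] = y;
    ++accepted;
  }
  IntegerMatrix out(E, 2);
  for (int e = 0; e < E; ++e) {
    out(e, 0) = a[e] < b[e] ? a[e] : b[e];
    out(e, 1) = a[e] < b[e] ? b[e] : a[e];
  }
  return List::create(_["edges"] = out, _["accepted"] = accepted,
                      _["tries"] = tries);
}
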