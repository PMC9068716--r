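#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving randomization of a simple undirected graph by repeated
// double-edge swaps: pick two edges (a,b), (c,d) and rewire to (a,d), (c,b)
// unless that would create a self-loop or a multi-edge.  Every accepted swap
// leaves all node degrees unchanged.
//
// edges: m x 2 one-based node indices; n_nodes: node count;
// n_swaps: attempted swaps.  Returns the rewired m x 2 edge list.
// [[Rcpp::export]]
IntegerMatrix double_edge_swap_cpp(IntegerMatrix edges, int n_nodes,
                                   int n_swaps) {
  const int m = edges.nrow();
  if (m < 2) return edges;
  std::vector<int> a(m), b(m);
  std::vector<char> adj((size_t)n_nodes * n_nodes, 0);
  for (int e = 0; e < m; ++e) {
    a[e] = edges(e, 0) - 1;
    b[e] = edges(e, 1) - 1;
    adj[(size_t)a[e] * n_nodes + b[e]] = 1;
    adj[(size_t)b[e] * n_nodes + a[e]] = 1;
  }
  for (int s = 0; s < n_swaps; ++s) {
    int e1 = (int)(R::unif_rand() * m);
    int e2 = (int)(R::unif_rand() * m);
    if (e1 == e2) continue;
    int u1 = a[e1], v1 = b[e1], u2 = a[e2], v2 = b[e2];
    // randomly orient the second edge so both pairings are reachable
    if (R::unif_rand() < 0.5) std::swap(u2, v2);
    if (u1 == u2 || u1 == v2 || v1 == u2 || v1 == v2) continue;
    if (adj[(size_t)u1 * n_nodes + v2] || adj[(size_t)u2 * n_nodes + v1])
      continue;
    adj[(size_t)u1 * n_nodes + v1] = adj[(size_t)v1 * n_nodes + u1] = 0;
    adj[(size_t)u2 * n_nodes + v2] = adj[(size_t)v2 * n_nodes + u2] = 0;
    b[e1] = v2;
    a[e2] = u2;
    b[e2] = v1;
    adj[(size_t)u1 * n_nodes + v2] = adj[(size_t)v2 * n_nodes + u1] = 1;
    adj[(size_t)u2 * n_nodes + v1] = adj[(size_t)v1 * n_nodes + u2] = 1;
  }
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = a[e] + 1;
    out(e, 1) = b[e] + 1;
  }
  return out;
}
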