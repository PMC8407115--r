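#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Random node-removal collapse simulation.
// edges: 0-based E x 2 matrix; P: node count; n_repeats: removal orders.
// Per repeat, nodes are removed in a uniformly random order and after each
// removal the ratio of the largest remaining connected component to the
// original P is recorded (simulated backwards by node addition with a
// union-find, O(P + E) per repeat). Returns the P-column curve per repeat
// (column i = fraction after removing i nodes) and the per-repeat mean R.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List robustness_sim_cpp(IntegerMatrix edges, int P, int n_repeats) {
  int E = edges.nrow();
  std::vector<std::vector<int>> adj(P);
  for (int e = 0; e < E; ++e) {
    adj[edges(e, 0)].push_back(edges(e, 1));
    adj[edges(e, 1)].push_back(edges(e, 0));
  }
  NumericMatrix curves(n_repeats, P);
  NumericVector Rvals(n_repeats);
  std::vector<int> parent(P), size(P), order(P);
  std::vector<char> active(P);
  for (int rep = 0; rep < n_repeats; ++rep) {
    // Fisher-Yates via R RNG: removal order
    for (int i = 0; i < P; ++i) order[i] = i;
    for (int i = P - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    std::fill(active.begin(), active.end(), 0);
    int maxc = 0;
    curves(rep, P - 1) = 0.0;  // all nodes removed
    // add nodes back in reverse removal order
    for (int k = P - 1; k >= 1; --k) {
      int v = order[k];
      parent[v] = v; size[v] = 1; active[v] = 1;
      int rv = v;
      for (size_t a = 0; a < adj[v].size(); ++a) {
        int u = adj[v][a];
        if (!active[u]) continue;
        int ru = uf_find(parent, u);
        rv = uf_find(parent, rv);
        if (ru != rv) {
          if (size[ru] < size[rv]) std::swap(ru, rv);
          parent[rv] = ru;
          size[ru] += size[rv];
          rv = ru;
        }
      }
      rv = uf_find(parent, v);
      if (size[rv] > maxc) maxc = size[rv];
      // active set = order[k..P-1], i.e. k nodes have been removed
      curves(rep, k - 1) = (double)maxc / (double)P;
    }
    double s = 0.0;
    for (int i = 0; i < P; ++i) s += curves(rep, i);
    Rvals[rep] = s / P;
  }
  return List::create(_["curves"] = curves, _["R"] = Rvals);
}
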