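#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Union-find with path halving; sizes tracked for giant-component queries.
namespace {

struct UnionFind {
  std::vector<int> parent;
  std::vector<int> size;
  int max_size;
  explicit UnionFind(int n) : parent(n), size(n, 1), max_size(n > 0 ? 1 : 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
    if (size[a] > max_size) max_size = size[a];
  }
};

} // namespace

// Synchronous LTM cascade. A node activates in round r+1 once >= m_i of its
// neighbors are active at rounds <= r. Returns final states, activation
// times (0 for seeds, -1 for never active) and the number of rounds.
// [[Rcpp::export]]
List cpp_spread(IntegerVector xadj, IntegerVector adj, IntegerVector m,
                IntegerVector seeds) {
  const int n = xadj.size() - 1;
  IntegerVector state(n, 0), atime(n, -1);
  std::vector<int> cnt(n, 0);
  std::vector<int> frontier, nxt, candidates;
  for (int s = 0; s < seeds.size(); ++s) {
    int v = seeds[s];
    if (state[v]) continue;
    state[v] = 1;
    atime[v] = 0;
    frontier.push_back(v);
  }
  int rounds = 0;
  while (!frontier.empty()) {
    candidates.clear();
    for (size_t f = 0; f < frontier.size(); ++f) {
      int u = frontier[f];
      for (int e = xadj[u]; e < xadj[u + 1]; ++e) {
        int v = adj[e];
        if (state[v]) continue;
        if (cnt[v]++ == 0) candidates.push_back(v);
        // duplicates in candidates are harmless: filtered by state below
        if (cnt[v] >= m[v]) candidates.push_back(v);
      }
    }
    nxt.clear();
    for (size_t c = 0; c < candidates.size(); ++c) {
      int v = candidates[c];
      if (!state[v] && cnt[v] >= m[v]) {
        state[v] = 1;
        atime[v] = rounds + 1;
        nxt.push_back(v);
      }
    }
    if (!nxt.empty()) ++rounds;
    frontier.swap(nxt);
  }
  return List::create(_["state"] = state, _["time"] = atime,
                      _["rounds"] = rounds);
}

// Size of the largest connected component of the subgraph induced by the
// active nodes.
// [[Rcpp::export]]
int cpp_giant_active(IntegerVector xadj, IntegerVector adj,
                     IntegerVector active) {
  const int n = xadj.size() - 1;
  if (n == 0) return 0;
  UnionFind uf(n);
  bool any = false;
  for (int u = 0; u < n; ++u) {
    if (!active[u]) continue;
    any = true;
    for (int e = xadj[u]; e < xadj[u + 1]; ++e) {
      int v = adj[e];
      if (v > u && active[v]) uf.unite(u, v);
    }
  }
  if (!any) return 0;
  int best = 0;
  for (int u = 0; u < n; ++u)
    if (active[u]) {
      int r = uf.find(u);
      if (uf.size[r] > best) best = uf.size[r];
    }
  return best;
}

// Q(q) along a seeding order: seeds are added one at a time, the monotone
// cascade is continued incrementally, and the giant active component is
// tracked with a union-find as nodes activate. Equivalent to restarting the
// cascade for every prefix (monotone dynamics), but costs O(M alpha) total.
// Returns, for prefix sizes 0..length(ranking): number of active nodes and
// the giant active component size.
// [[Rcpp::export]]
List cpp_q_curve(IntegerVector xadj, IntegerVector adj, IntegerVector m,
                 IntegerVector ranking) {
  const int n = xadj.size() - 1;
  const int len = ranking.size();
  std::vector<char> active(n, 0);
  std::vector<int> cnt(n, 0);
  UnionFind uf(n);
  int n_active = 0, giant = 0;
  IntegerVector out_active(len + 1), out_giant(len + 1);
  std::queue<int> q;

  auto activate = [&](int v) {
    active[v] = 1;
    ++n_active;
    for (int e = xadj[v]; e < xadj[v + 1]; ++e) {
      int u = adj[e];
      if (active[u]) {
        uf.unite(v, u);
      } else {
        if (++cnt[u] >= m[u]) q.push(u);
      }
    }
    int r = uf.find(v);
    if (uf.size[r] > giant) giant = uf.size[r];
    if (n_active == 1 && giant == 0) giant = 1;
  };

  out_active[0] = 0;
  out_giant[0] = 0;
  for (int s = 0; s < len; ++s) {
    int v = ranking[s];
    if (!active[v]) activate(v);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      if (!active[u] && cnt[u] >= m[u]) activate(u);
    }
    out_active[s + 1] = n_active;
    out_giant[s + 1] = giant;
  }
  return List::create(_["n_active"] = out_active, _["giant"] = out_giant);
}
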