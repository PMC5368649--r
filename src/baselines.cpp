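#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

// k-shell index by bucket peeling, O(N + M).
// [[Rcpp::export]]
IntegerVector cpp_coreness(IntegerVector xadj, IntegerVector adj) {
  const int n = xadj.size() - 1;
  IntegerVector core(n);
  if (n == 0) return core;
  std::vector<int> deg(n), pos(n), vert(n), bin;
  int md = 0;
  for (int i = 0; i < n; ++i) {
    deg[i] = xadj[i + 1] - xadj[i];
    md = std::max(md, deg[i]);
  }
  bin.assign(md + 2, 0);
  for (int i = 0; i < n; ++i) ++bin[deg[i]];
  int start = 0;
  for (int d = 0; d <= md; ++d) { int c = bin[d]; bin[d] = start; start += c; }
  for (int i = 0; i < n; ++i) { pos[i] = bin[deg[i]]++; vert[pos[i]] = i; }
  for (int d = md; d > 0; --d) bin[d] = bin[d - 1];
  bin[0] = 0;
  for (int k = 0; k < n; ++k) {
    int v = vert[k];
    core[v] = deg[v];
    for (int e = xadj[v]; e < xadj[v + 1]; ++e) {
      int u = adj[e];
      if (deg[u] > deg[v]) {
        int du = deg[u], pu = pos[u], pw = bin[du], w = vert[pw];
        if (u != w) {
          std::swap(vert[pu], vert[pw]);
          pos[u] = pw;
          pos[w] = pu;
        }
        ++bin[du];
        --deg[u];
      }
    }
  }
  return core;
}

// Adaptive high-degree ranking: repeatedly take the live node of maximal
// residual degree (ties: smallest id), then delete it and its edges.
// [[Rcpp::export]]
List cpp_rank_hda(IntegerVector xadj, IntegerVector adj, int budget) {
  const int n = xadj.size() - 1;
  std::vector<int> deg(n);
  std::vector<char> alive(n, 1);
  std::priority_queue<std::pair<int, int>> heap;
  for (int i = 0; i < n; ++i) {
    deg[i] = xadj[i + 1] - xadj[i];
    heap.push({deg[i], -i});
  }
  std::vector<int> order;
  std::vector<int> score;
  while ((int)order.size() < budget && !heap.empty()) {
    int d = heap.top().first, v = -heap.top().second;
    heap.pop();
    if (!alive[v] || d != deg[v]) continue;
    order.push_back(v);
    score.push_back(d);
    alive[v] = 0;
    for (int e = xadj[v]; e < xadj[v + 1]; ++e) {
      int u = adj[e];
      if (alive[u]) heap.push({--deg[u], -u});
    }
  }
  return List::create(_["order"] = IntegerVector(order.begin(), order.end()),
                      _["score"] = IntegerVector(score.begin(), score.end()));
}

// Adaptive k-shell ranking: recompute the k-shell decomposition of the
// residual graph after each removal; pick the node in the highest shell,
// ties broken by residual degree then smallest id. Quadratic overall.
// [[Rcpp::export]]
List cpp_rank_ksa(IntegerVector xadj, IntegerVector adj, int budget) {
  const int n = xadj.size() - 1;
  std::vector<char> alive(n, 1);
  std::vector<int> deg(n), order, score;
  std::vector<int> idmap(n), sub_xadj, sub_adj;
  for (int i = 0; i < n; ++i) deg[i] = xadj[i + 1] - xadj[i];
  for (int it = 0; it < budget; ++it) {
    // build residual CSR
    sub_xadj.assign(1, 0);
    sub_adj.clear();
    std::vector<int> live;
    int nl = 0;
    for (int i = 0; i < n; ++i)
      if (alive[i]) { idmap[i] = nl++; live.push_back(i); }
    if (nl == 0) break;
    for (int k = 0; k < nl; ++k) {
      int v = live[k];
      for (int e = xadj[v]; e < xadj[v + 1]; ++e)
        if (alive[adj[e]]) sub_adj.push_back(idmap[adj[e]]);
      sub_xadj.push_back((int)sub_adj.size());
    }
    IntegerVector c = cpp_coreness(wrap(sub_xadj), wrap(sub_adj));
    // pick max (shell, degree, -id)
    int bi = -1, bc = -1, bd = -1;
    for (int k = 0; k < nl; ++k) {
      int v = live[k];
      if (c[k] > bc || (c[k] == bc && deg[v] > bd)) {
        bi = v; bc = c[k]; bd = deg[v];
      }
    }
    order.push_back(bi);
    score.push_back(bc);
    alive[bi] = 0;
    for (int e = xadj[bi]; e < xadj[bi + 1]; ++e)
      if (alive[adj[e]]) --deg[adj[e]];
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["order"] = IntegerVector(order.begin(), order.end()),
                      _["score"] = IntegerVector(score.begin(), score.end()));
}

namespace {

// timestamped deterministic LTM cascade size (number of active nodes)
struct CascadeCounter {
  const int* xadj; const int* adj; const int* m;
  int n;
  std::vector<int> st_epoch, cnt_epoch;
  std::vector<int> cnt;
  int epoch;
  CascadeCounter(const int* x, const int* a, const int* mm, int nn)
      : xadj(x), adj(a), m(mm), n(nn), st_epoch(nn, 0), cnt_epoch(nn, 0),
        cnt(nn, 0), epoch(0) {}
  inline bool active(int v) const { return st_epoch[v] == epoch; }
  int run(const std::vector<int>& seeds) {
    ++epoch;
    int nact = 0;
    std::queue<int> q;
    for (size_t s = 0; s < seeds.size(); ++s) {
      int v = seeds[s];
      if (active(v)) continue;
      st_epoch[v] = epoch;
      ++nact;
      q.push(v);
    }
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int e = xadj[u]; e < xadj[u + 1]; ++e) {
        int v = adj[e];
        if (active(v)) continue;
        if (cnt_epoch[v] != epoch) { cnt_epoch[v] = epoch; cnt[v] = 0; }
        if (++cnt[v] >= m[v]) {
          st_epoch[v] = epoch;
          ++nact;
          q.push(v);
        }
      }
    }
    return nact;
  }
};

} // namespace

// Exact greedy (GA): sequentially add the node with the maximal marginal
// gain in total activated count; one deterministic cascade per candidate.
// [[Rcpp::export]]
List cpp_rank_greedy(IntegerVector xadj, IntegerVector adj, IntegerVector m,
                     int budget) {
  const int n = xadj.size() - 1;
  CascadeCounter cc(xadj.begin(), adj.begin(), m.begin(), n);
  std::vector<int> seeds;
  std::vector<char> chosen(n, 0);
  std::vector<double> gains;
  int base = 0;
  for (int it = 0; it < budget && (int)seeds.size() < n; ++it) {
    int best = -1, best_sz = -1;
    for (int v = 0; v < n; ++v) {
      if (chosen[v]) continue;
      seeds.push_back(v);
      int sz = cc.run(seeds);
      seeds.pop_back();
      if (sz > best_sz) { best_sz = sz; best = v; }
    }
    if (best < 0) break;
    seeds.push_back(best);
    chosen[best] = 1;
    gains.push_back(best_sz - base);
    base = best_sz;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["order"] = IntegerVector(seeds.begin(), seeds.end()),
                      _["gain"] = NumericVector(gains.begin(), gains.end()));
}
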