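#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

// Residual picture used throughout this file: collapse of chosen seeds and
// of the subcritical vertices they trigger is encoded by removing nodes
// (alive = 0) and decrementing surviving neighbors' residual degree rdeg
// and residual threshold rm. A live node is subcritical iff rm == 1. A
// subcritical path from i is a simple directed walk i -> v1 -> ... -> vl -> w
// with every v subcritical; the terminal hop w is any live neighbor of vl
// other than v_{l-1} (so each vl contributes rdeg[vl] - 1 paths at depth l).
// The modified (CI-TMm) variant refuses to traverse vulnerable vertices,
// i.e. nodes whose ORIGINAL threshold is 1.

namespace {

// Score for the selector when the path-enumeration budget is exhausted:
// larger than any attainable finite score, ties broken by node id.
const double SAT_SCORE = 1e300;

struct PathCount {
  double score;                 // rdeg[i] + sum_l N_l
  std::vector<double> counts;   // counts[l-1] = N_l
  std::vector<int> reached;     // subcritical nodes ever visited
  bool saturated;
};

struct Frame { int node; int ptr; };

// Iterative DFS over simple subcritical paths starting at i. `visited` and
// `rflag` are caller-provided n-sized scratch arrays (all false on entry,
// restored to all false on exit). `cap` bounds the number of enumeration
// events; on overflow the DFS aborts with saturated = true.
void count_paths_dfs(const int* xadj, const int* adj, const char* alive,
                     const int* rdeg, const int* rm, const int* morig,
                     int i, int L, double cap, bool modified,
                     std::vector<char>& visited, std::vector<char>& rflag,
                     PathCount& out) {
  out.score = rdeg[i];
  out.counts.clear();
  out.reached.clear();
  out.saturated = false;
  if (L == 0) return;
  double events = 0.0;
  std::vector<Frame> st;
  visited[i] = 1;
  st.push_back({i, xadj[i]});
  while (!st.empty()) {
    Frame& f = st.back();
    if (f.ptr < xadj[f.node + 1]) {
      int w = adj[f.ptr++];
      if (!alive[w] || visited[w] || rm[w] != 1) continue;
      if (modified && morig[w] == 1) continue;
      int depth = (int)st.size(); // w sits at this depth (root at depth 0)
      double contrib = rdeg[w] - 1;
      if ((int)out.counts.size() < depth) out.counts.resize(depth, 0.0);
      out.counts[depth - 1] += contrib;
      out.score += contrib;
      if (!rflag[w]) { rflag[w] = 1; out.reached.push_back(w); }
      if (++events > cap) { out.saturated = true; break; }
      if (L < 0 || depth < L) {
        visited[w] = 1;
        st.push_back({w, xadj[w]});
      }
    } else {
      visited[f.node] = 0;
      st.pop_back();
    }
  }
  // clear scratch (also after an aborted DFS)
  for (size_t k = 0; k < st.size(); ++k) visited[st[k].node] = 0;
  for (size_t k = 0; k < out.reached.size(); ++k) rflag[out.reached[k]] = 0;
  if (out.saturated) out.score = SAT_SCORE;
}

// BFS through the live subcritical subgraph from i, depth-limited by L
// (L < 0: unlimited). Returns the reached subcritical vertices, i.e.
// C(i, L) \ {i}. Exact regardless of any DFS saturation.
void subcritical_reach_bfs(const int* xadj, const int* adj, const char* alive,
                           const int* rm, const int* morig, int i, int L,
                           bool modified, std::vector<char>& rflag,
                           std::vector<int>& reached) {
  reached.clear();
  if (L == 0) return;
  std::queue<std::pair<int, int>> q; // (node, depth)
  q.push({i, 0});
  rflag[i] = 1;
  while (!q.empty()) {
    int u = q.front().first, d = q.front().second;
    q.pop();
    if (L >= 0 && d >= L) continue;
    for (int e = xadj[u]; e < xadj[u + 1]; ++e) {
      int w = adj[e];
      if (!alive[w] || rflag[w] || rm[w] != 1) continue;
      if (modified && morig[w] == 1) continue;
      rflag[w] = 1;
      reached.push_back(w);
      q.push({w, d + 1});
    }
  }
  rflag[i] = 0;
  for (size_t k = 0; k < reached.size(); ++k) rflag[reached[k]] = 0;
}

} // namespace

// [[Rcpp::export]]
List cpp_count_paths(IntegerVector xadj, IntegerVector adj,
                     IntegerVector alive_, IntegerVector rdeg,
                     IntegerVector rm, IntegerVector morig, int node,
                     int L, double cap, bool modified) {
  const int n = xadj.size() - 1;
  std::vector<char> alive(n), visited(n, 0), rflag(n, 0);
  for (int i = 0; i < n; ++i) alive[i] = (char)alive_[i];
  PathCount pc;
  count_paths_dfs(xadj.begin(), adj.begin(), alive.data(), rdeg.begin(),
                  rm.begin(), morig.begin(), node, L, cap, modified, visited,
                  rflag, pc);
  std::vector<int> creach;
  subcritical_reach_bfs(xadj.begin(), adj.begin(), alive.data(), rm.begin(),
                        morig.begin(), node, L, modified, rflag, creach);
  return List::create(
      _["score"] = pc.score, _["counts"] = NumericVector(pc.counts.begin(),
                                                         pc.counts.end()),
      _["reached"] = IntegerVector(creach.begin(), creach.end()),
      _["saturated"] = pc.saturated);
}

// Scores for all live nodes in a given residual state.
// [[Rcpp::export]]
NumericVector cpp_score_all(IntegerVector xadj, IntegerVector adj,
                            IntegerVector alive_, IntegerVector rdeg,
                            IntegerVector rm, IntegerVector morig, int L,
                            double cap, bool modified) {
  const int n = xadj.size() - 1;
  std::vector<char> alive(n), visited(n, 0), rflag(n, 0);
  for (int i = 0; i < n; ++i) alive[i] = (char)alive_[i];
  NumericVector out(n, NA_REAL);
  PathCount pc;
  for (int i = 0; i < n; ++i) {
    if (!alive[i]) continue;
    count_paths_dfs(xadj.begin(), adj.begin(), alive.data(), rdeg.begin(),
                    rm.begin(), morig.begin(), i, L, cap, modified, visited,
                    rflag, pc);
    out[i] = pc.score;
    if (i % 2048 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

namespace {

// Shared machinery for the adaptive greedy selector and the activation
// timeline: removal of C(i, L) with per-removed-neighbor decrements and
// closure (a survivor whose residual threshold hits 0 is certainly
// activated, so it is removed recursively with the same decrements).
struct Residual {
  int n;
  const int* xadj; const int* adj;
  std::vector<char> alive;
  std::vector<int> rdeg, rm, morig;
  std::vector<char> visited, rflag; // DFS/BFS scratch
  std::vector<int> changed;         // live nodes decremented last collapse
  std::vector<char> changed_flag;
  int n_alive;

  Residual(IntegerVector xadj_, IntegerVector adj_, IntegerVector m_)
      : n(xadj_.size() - 1), xadj(xadj_.begin()), adj(adj_.begin()),
        alive(n, 1), rdeg(n), rm(n), morig(m_.begin(), m_.begin() + n),
        visited(n, 0), rflag(n, 0), changed_flag(n, 0), n_alive(n) {
    for (int i = 0; i < n; ++i) {
      rdeg[i] = xadj[i + 1] - xadj[i];
      rm[i] = morig[i];
    }
  }

  // Remove {i} + C, decrement surviving neighbors, apply closure.
  // Fills `changed` with surviving decremented nodes and `removed_now`
  // with everything removed (i, C members, closure victims).
  void collapse(int i, const std::vector<int>& creach,
                std::vector<int>& removed_now) {
    changed.clear();
    removed_now.clear();
    std::queue<int> rq;
    if (alive[i]) { alive[i] = 0; --n_alive; rq.push(i); removed_now.push_back(i); }
    for (size_t k = 0; k < creach.size(); ++k) {
      int c = creach[k];
      if (alive[c]) { alive[c] = 0; --n_alive; rq.push(c); removed_now.push_back(c); }
    }
    while (!rq.empty()) {
      int r = rq.front(); rq.pop();
      for (int e = xadj[r]; e < xadj[r + 1]; ++e) {
        int u = adj[e];
        if (!alive[u]) continue;
        --rdeg[u];
        if (rm[u] > 0) --rm[u];
        if (rm[u] == 0) {
          alive[u] = 0; --n_alive;
          rq.push(u);
          removed_now.push_back(u);
          if (changed_flag[u]) changed_flag[u] = 0; // dead: drop from changed
        } else if (!changed_flag[u]) {
          changed_flag[u] = 1;
          changed.push_back(u);
        }
      }
    }
    // compact: keep only still-live changed nodes, reset flags
    size_t w = 0;
    for (size_t k = 0; k < changed.size(); ++k) {
      int u = changed[k];
      if (alive[u] && changed_flag[u]) changed[w++] = u;
      changed_flag[u] = 0;
    }
    changed.resize(w);
  }
};

} // namespace

// Adaptive greedy CI-TM seed selection (Algorithm: score all, repeatedly
// pick the live node with the largest CI-TM_L (ties: smallest id), remove
// C(i, L) with closure, and rescore only the nodes whose score can have
// changed - nodes adjacent to the removed set plus the neighborhoods of
// every subcritical cluster touching a decremented node.
// [[Rcpp::export]]
List cpp_select_seeds(IntegerVector xadj, IntegerVector adj, IntegerVector m,
                      int budget, int L, double cap, bool modified) {
  Residual st(xadj, adj, m);
  const int n = st.n;
  std::vector<double> score(n, 0.0);
  std::vector<char> dirty(n, 0);
  std::vector<int> dirty_list;
  // max-heap on (score, -id); entries are lazily invalidated
  std::priority_queue<std::pair<double, int>> heap;
  PathCount pc;
  std::vector<int> creach, removed_now;

  for (int i = 0; i < n; ++i) {
    count_paths_dfs(st.xadj, st.adj, st.alive.data(), st.rdeg.data(),
                    st.rm.data(), st.morig.data(), i, L, cap, modified,
                    st.visited, st.rflag, pc);
    score[i] = pc.score;
    heap.push({score[i], -i});
    if (i % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  std::vector<int> seeds;
  std::vector<double> sel_score;
  std::vector<char> cluster_done(n, 0);
  std::vector<int> cluster_nodes;

  auto rescore = [&](int i) {
    count_paths_dfs(st.xadj, st.adj, st.alive.data(), st.rdeg.data(),
                    st.rm.data(), st.morig.data(), i, L, cap, modified,
                    st.visited, st.rflag, pc);
    score[i] = pc.score;
    dirty[i] = 0;
    heap.push({score[i], -i});
  };

  while ((int)seeds.size() < budget && st.n_alive > 0) {
    Rcpp::checkUserInterrupt();
    // eager rescore of dirty nodes, ascending id; if a rescore saturates the
    // enumeration cap that node is the global maximum, so stop early and
    // leave the rest dirty (they are rescored on pop or next iteration).
    if (!dirty_list.empty()) {
      std::sort(dirty_list.begin(), dirty_list.end());
      size_t k = 0;
      for (; k < dirty_list.size(); ++k) {
        int u = dirty_list[k];
        if (!st.alive[u] || !dirty[u]) { dirty[u] = 0; continue; }
        rescore(u);
        if (score[u] >= SAT_SCORE) { ++k; break; }
      }
      dirty_list.erase(dirty_list.begin(), dirty_list.begin() + k);
    }
    // pop the current maximum
    int pick = -1;
    while (!heap.empty()) {
      double s = heap.top().first;
      int u = -heap.top().second;
      heap.pop();
      if (!st.alive[u]) continue;
      if (dirty[u]) { rescore(u); continue; }
      if (s != score[u]) continue; // stale entry
      pick = u;
      break;
    }
    if (pick < 0) break;
    seeds.push_back(pick);
    sel_score.push_back(score[pick]);

    subcritical_reach_bfs(st.xadj, st.adj, st.alive.data(), st.rm.data(),
                          st.morig.data(), pick, L, modified, st.rflag,
                          creach);
    st.collapse(pick, creach, removed_now);

    // mark dirty: every decremented survivor, plus the full neighborhoods of
    // the subcritical clusters those survivors belong to (their path trees
    // changed). cluster_done guards repeated BFS within this iteration.
    cluster_nodes.clear();
    for (size_t k = 0; k < st.changed.size(); ++k) {
      int u = st.changed[k];
      if (!dirty[u]) { dirty[u] = 1; dirty_list.push_back(u); }
      if (st.rm[u] == 1 && !(modified && st.morig[u] == 1) &&
          !cluster_done[u]) {
        // BFS this subcritical cluster
        std::queue<int> cq;
        cq.push(u);
        cluster_done[u] = 1;
        cluster_nodes.push_back(u);
        while (!cq.empty()) {
          int c = cq.front(); cq.pop();
          if (!dirty[c]) { dirty[c] = 1; dirty_list.push_back(c); }
          for (int e = st.xadj[c]; e < st.xadj[c + 1]; ++e) {
            int w = st.adj[e];
            if (!st.alive[w]) continue;
            if (st.rm[w] == 1 && !(modified && st.morig[w] == 1)) {
              if (!cluster_done[w]) {
                cluster_done[w] = 1;
                cluster_nodes.push_back(w);
                cq.push(w);
              }
            } else if (!dirty[w]) {
              dirty[w] = 1;
              dirty_list.push_back(w);
            }
          }
        }
      }
    }
    for (size_t k = 0; k < cluster_nodes.size(); ++k)
      cluster_done[cluster_nodes[k]] = 0;
  }

  return List::create(_["seeds"] = IntegerVector(seeds.begin(), seeds.end()),
                      _["score"] = NumericVector(sel_score.begin(),
                                                 sel_score.end()));
}

// Activation timeline: activate nodes in the given order (skipping those
// already activated), record the CI-TM_L score and pure path count at each
// ranked activation, then auto-activate the attached subcritical vertices
// (same collapse + closure as the selector).
// [[Rcpp::export]]
List cpp_path_timeline(IntegerVector xadj, IntegerVector adj, IntegerVector m,
                       IntegerVector ranking, int L, double cap,
                       bool modified) {
  Residual st(xadj, adj, m);
  PathCount pc;
  std::vector<int> creach, removed_now;
  const int len = ranking.size();
  NumericVector out_score(len, NA_REAL), out_paths(len, NA_REAL);
  IntegerVector out_active(len, NA_INTEGER);
  int n_removed = 0;
  for (int k = 0; k < len; ++k) {
    int v = ranking[k];
    if (!st.alive[v]) continue;
    count_paths_dfs(st.xadj, st.adj, st.alive.data(), st.rdeg.data(),
                    st.rm.data(), st.morig.data(), v, L, cap, modified,
                    st.visited, st.rflag, pc);
    out_score[k] = pc.score;
    out_paths[k] = pc.score >= SAT_SCORE ? R_PosInf : pc.score - st.rdeg[v];
    subcritical_reach_bfs(st.xadj, st.adj, st.alive.data(), st.rm.data(),
                          st.morig.data(), v, L, modified, st.rflag, creach);
    st.collapse(v, creach, removed_now);
    n_removed += (int)removed_now.size();
    out_active[k] = n_removed;
    if (k % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["score"] = out_score, _["n_paths"] = out_paths,
                      _["n_activated"] = out_active);
}

// Single collapse step exposed for the R-level SelectionState API.
// [[Rcpp::export]]
List cpp_collapse_step(IntegerVector xadj, IntegerVector adj,
                       IntegerVector alive_, IntegerVector rdeg_,
                       IntegerVector rm_, IntegerVector morig, int node,
                       IntegerVector creach) {
  const int n = xadj.size() - 1;
  Residual st(xadj, adj, morig);
  for (int i = 0; i < n; ++i) {
    st.alive[i] = (char)alive_[i];
    st.rdeg[i] = rdeg_[i];
    st.rm[i] = rm_[i];
  }
  st.n_alive = 0;
  for (int i = 0; i < n; ++i) st.n_alive += st.alive[i] ? 1 : 0;
  std::vector<int> cr(creach.begin(), creach.end()), removed_now;
  st.collapse(node, cr, removed_now);
  return List::create(
      _["alive"] = IntegerVector(st.alive.begin(), st.alive.end()),
      _["rdeg"] = IntegerVector(st.rdeg.begin(), st.rdeg.end()),
      _["rm"] = IntegerVector(st.rm.begin(), st.rm.end()),
      _["removed"] = IntegerVector(removed_now.begin(), removed_now.end()));
}
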