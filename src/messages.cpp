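#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Directed links are indexed by position in the CSR adjacency array: link
// e in [xadj[i], xadj[i+1]) is i -> adj[e]. rev[e] is the index of the
// reverse link adj[e] -> i. Adjacency rows must be sorted ascending.

// [[Rcpp::export]]
IntegerVector cpp_reverse_links(IntegerVector xadj, IntegerVector adj) {
  const int n = xadj.size() - 1;
  IntegerVector rev(adj.size());
  for (int i = 0; i < n; ++i) {
    for (int e = xadj[i]; e < xadj[i + 1]; ++e) {
      int j = adj[e];
      // binary search for i in row j
      int lo = xadj[j], hi = xadj[j + 1] - 1, pos = -1;
      while (lo <= hi) {
        int mid = (lo + hi) / 2;
        if (adj[mid] == i) { pos = mid; break; }
        if (adj[mid] < i) lo = mid + 1; else hi = mid - 1;
      }
      if (pos < 0) stop("adjacency is not symmetric");
      rev[e] = pos;
    }
  }
  return rev;
}

namespace {

// Monotone fixed-point solver for the message-passing equations
//   nu_{i->j} = n_i  OR  ( sum_{k in di\j} nu_{k->i} >= m_i ).
// Queue-driven: in_cnt[i] tracks sum_k nu_{k->i}; a link i->j flips when
// in_cnt[i] - nu_{j->i} reaches m_i. Starting from all-zero (minus seed
// links), messages only ever flip 0 -> 1, so the first fixed point reached
// is the minimal one.
struct MessageSolver {
  const int* xadj; const int* adj; const int* rev; const int* m;
  int n; int nlinks;
  std::vector<int> nu_epoch, in_epoch, seed_epoch;
  std::vector<int> in_cnt;
  int epoch;
  MessageSolver(const int* xadj_, const int* adj_, const int* rev_,
                const int* m_, int n_, int nlinks_)
      : xadj(xadj_), adj(adj_), rev(rev_), m(m_), n(n_), nlinks(nlinks_),
        nu_epoch(nlinks_, 0), in_epoch(n_, 0), seed_epoch(n_, 0),
        in_cnt(n_, 0), epoch(0) {}

  inline bool nu(int e) const { return nu_epoch[e] == epoch; }
  inline bool is_seed(int i) const { return seed_epoch[i] == epoch; }
  inline int incnt(int i) const { return in_epoch[i] == epoch ? in_cnt[i] : 0; }

  // returns number of active messages
  int solve(const int* seeds, int nseeds) {
    ++epoch;
    int nact = 0;
    std::queue<int> q; // flipped links pending neighbor updates
    for (int s = 0; s < nseeds; ++s) {
      int i = seeds[s];
      if (is_seed(i)) continue;
      seed_epoch[i] = epoch;
      for (int e = xadj[i]; e < xadj[i + 1]; ++e) {
        if (!nu(e)) { nu_epoch[e] = epoch; ++nact; q.push(e); }
      }
    }
    while (!q.empty()) {
      int e = q.front(); q.pop();
      int i = adj[e]; // link is k->i
      if (in_epoch[i] != epoch) { in_epoch[i] = epoch; in_cnt[i] = 0; }
      ++in_cnt[i];
      if (is_seed(i)) continue; // out-links already active
      for (int e2 = xadj[i]; e2 < xadj[i + 1]; ++e2) {
        if (nu(e2)) continue;
        int jrev = rev[e2]; // link j->i where j = adj[e2]
        int excl = nu(jrev) ? 1 : 0;
        if (in_cnt[i] - excl >= m[i]) {
          nu_epoch[e2] = epoch;
          ++nact;
          q.push(e2);
        }
      }
    }
    return nact;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_solve_messages(IntegerVector xadj, IntegerVector adj,
                        IntegerVector rev, IntegerVector m,
                        IntegerVector seeds) {
  const int n = xadj.size() - 1;
  const int nlinks = adj.size();
  MessageSolver ms(xadj.begin(), adj.begin(), rev.begin(), m.begin(), n,
                   nlinks);
  ms.solve(seeds.begin(), seeds.size());
  IntegerVector nu(nlinks);
  for (int e = 0; e < nlinks; ++e) nu[e] = ms.nu(e) ? 1 : 0;
  IntegerVector incnt(n);
  for (int i = 0; i < n; ++i) incnt[i] = ms.incnt(i);
  return List::create(_["nu"] = nu, _["in_count"] = incnt);
}

// For every node as the sole seed, the number of active messages at the
// minimal fixed point. Timestamped state makes the whole pass O(sum of
// cascade sizes), not O(N * 2M).
// [[Rcpp::export]]
NumericVector cpp_single_seed_message_counts(IntegerVector xadj,
                                             IntegerVector adj,
                                             IntegerVector rev,
                                             IntegerVector m) {
  const int n = xadj.size() - 1;
  MessageSolver ms(xadj.begin(), adj.begin(), rev.begin(), m.begin(), n,
                   adj.size());
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    out[s] = ms.solve(&s, 1);
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
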