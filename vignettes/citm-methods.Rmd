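---
title: "Collective influence in threshold cascades: model, algorithm and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective influence in threshold cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citm)
```

## The model

The Linear Threshold Model describes complex contagion: node $i$ of an
undirected simple graph ($N$ nodes, $M$ edges, adjacency $A_{ij}$)
activates once $m_i$ of its neighbors are active, and never deactivates.
Seeds ($n_i = 1$, a fraction $q$ of nodes) are active at time 0. Because
the dynamics are monotone, the fixed point is unique and independent of
the update schedule; `spread()` runs synchronous rounds, and the test
suite checks agreement with a brute-force asynchronous oracle. The
observable of interest is $Q(q)$, the fraction of nodes in the largest
connected component of the final active set. Under the *fractional
threshold* rule $m_i = \lceil t\,k_i\rceil$ with $t \approx 0.5$ on
sparse random graphs, $Q(q)$ first rises continuously from 0 and then
jumps discontinuously at a critical seed fraction $q_c$ — a first-order
transition, which is what makes seed selection here qualitatively harder
than in models that map onto ordinary percolation ($m_i = k_i - 1$):
linear-stability machinery built on the non-backtracking matrix does not
apply directly.

## Messages, the linearized operator, and subcritical paths

On the $2M$ directed links the cavity equations read

$$\nu_{i\to j} = n_i \;\vee\; \Big[\textstyle\sum_{k\in\partial i
\setminus j}\nu_{k\to i}\ \ge\ m_i\Big],$$

with $\nu_{i\to j}$ the indicator that $i$ ends active when $j$ is
removed. The textbook form ORs over all $\binom{k_i-1}{m_i}$
combinations of $m_i$ active neighbors; for binary messages that
collapses to the counting condition above (the suite verifies this by
exhaustive enumeration up to $k = 8$). `solve_messages()` iterates
monotonically from the all-zero state, so it returns the *minimal* fixed
point in at most $2M$ flips.

Linearizing the link map around the inactive state gives an operator
$\hat B$ on link pairs: $\hat B_{k\to i,\,i\to j} = 1$ iff the links are
consecutive, non-backtracking ($k \ne j$), and $i$ is *subcritical*
without $k$ and $j$ — it has exactly $m_i - 1$ active neighbors among
the rest. (`bhat()` evaluates entries on demand; a $2M \times 2M$ matrix
is never formed.) Iterating the linearized system shows that a seed's
contribution to the norm $|\nu| = \sum \nu_{i\to j}/2M$ travels along
**subcritical paths** — chains of subcritical nodes, each one activation
away from firing — and motivates the score

$$\mathrm{CI\!-\!TM}_L(i) = k_i + \sum_{\ell=1}^{L} N_\ell(i),$$

where $N_\ell(i)$ counts subcritical paths of length $\ell$ from $i$.
On trees this score (at $L=\infty$, single seed) equals the number of
active directed links exactly; the suite asserts this on 100 random
trees with random thresholds.

### What exactly is a path (a design decision)

The linearization counts non-backtracking *walks*, which on loopy graphs
include infinite cyclic families. We therefore count **simple** paths:
$i \to v_1 \to \dots \to v_\ell \to w$ with all $v$ distinct, live and
subcritical; only the terminal hop is allowed to close onto an earlier
node ($w \ne v_{\ell-1}$ is the only constraint on $w$, preserving the
non-backtracking rule at the last step). Each $v_\ell$ hence contributes
its residual degree minus one. This reproduces the canonical worked
example (scores 3/5/7 at $L = 0/1/2$) and guarantees termination of
unlimited-depth counting. An alternative reading — counting each reached
subcritical *node* once, as a breadth-first visit would — differs only
in degenerate loopy cases; we measured the two to be numerically
indistinguishable on the ensembles used here (correlation with the exact
norm ≥ 0.9999 for both).

## The adaptive selector

`select_seeds()` implements the greedy loop: score all nodes, then
repeatedly (1) pick the live node with maximal score, ties to the
smallest id for bit-reproducibility; (2) remove $C(i, L)$ — the seed
plus every subcritical vertex on its subcritical paths, computed by a
depth-limited BFS through the subcritical subgraph, which equals the
union over simple paths; (3) decrement each surviving neighbor's
residual degree and residual threshold once per removed adjacent node;
(4) rescore only nodes whose score can have changed.

Decisions worth recording:

* **Residual picture.** A live node is subcritical iff its residual
  threshold equals 1; prior activations are encoded as decrements. This
  is equivalent to "has $m_i - 1$ active neighbors" because every
  removed neighbor was activated.
* **Closure.** A survivor whose residual threshold reaches 0 is already
  guaranteed to activate, so it is removed recursively with the same
  decrements. Not closing would leave impossible ($m = 0$) live
  candidates that waste seeds. The reference algorithm is silent here;
  we also tested the literal alternative of decrementing thresholds only
  once per collapse step and found it strictly worse (larger $q_c$), so
  the per-removed-neighbor rule stands.
* **Rescoring set.** A score can change only if the node's own degree
  changed, a neighbor changed subcritical status, or a subcritical
  cluster reachable from it changed. All such triggers are adjacent to
  the removed set, so after each collapse we mark dirty the decremented
  survivors plus the full neighborhoods of every subcritical cluster
  containing one; dirty nodes are rescored eagerly (ascending id) before
  the next pop, with lazily invalidated heap entries. This is the exact
  unlimited-$L$ analogue of "rescore within $L+1$ hops".
* **Enumeration cap.** Near $q_c$ the subcritical cluster becomes giant
  and loopy, and the number of simple paths explodes combinatorially.
  `max_path_events` (default $10^6$) bounds one scoring pass; a
  saturated count ranks above every finite score (it marks a node whose
  collapse triggers the global cascade), and $C(i,L)$ is computed by BFS
  so removal stays exact. Measured $q_c$ is invariant to the cap across
  $10^4$–$10^7$ on ER ensembles at $t = 0.4$–$0.6$; the cap only
  protects the runtime tail (we observed realizations where a handful of
  nodes carried $>10^7$ paths without any effect on the selection).
* **CI-TMm.** The modified variant excludes *vulnerable* vertices —
  original threshold $m = 1$, subcritical by nature rather than through
  earlier activations — from path traversal and counting. Exclusion is
  keyed to the original threshold, not the residual one (keying to
  residuals would zero every path). Vulnerable neighbors of removed
  nodes are still swept up by closure, which keeps the physics
  consistent: they activate for free either way.

## Synthetic data: what the generators emulate

The stated world of the benchmarks is: Erdős–Rényi graphs with
$N = 10^5$ and $\langle k\rangle = 6$ (the `G(n,p)` sampler uses
geometric skipping, $p = \langle k\rangle/(n-1)$), and configuration-
model graphs with $P(k)\propto k^{-3}$ on $[2, 1000]$, $N = 5000$, with
self-loops and multi-edges deleted after uniform stub matching (loss
< 0.3% of stubs at these parameters; deletion rather than rewiring is
the simplest reproducible choice). Thresholds are $m_i = \lceil t\,k_i
\rceil$ with $t \in \{0.3, 0.4, 0.5, 0.6\}$; isolated nodes get $m = 1$
so nothing activates spontaneously. All randomness flows through one
integer seed per call. What these graphs do *not* have is clustering,
degree correlations or community structure, so a green benchmark here
establishes correctness of the machinery on locally tree-like ensembles,
not performance claims on real social or infrastructure networks (the
edge-list reader makes those runnable, but they are out of the tested
surface).

## Critical-point estimation

`detect_qc()` reports the first-order $q_c$ as the seed fraction at the
single largest one-step jump of $Q$ along the exact (every-seed-count)
curve, accepted only if the jump exceeds 0.1 — genuine first-order jumps
here span most of $[0,1]$ while smooth curves step by $O(1/N)$ — and the
continuous onset as the smallest $q$ with $Q > 0.01$. Both cutoffs are
exposed as arguments; they are conventions, not fitted quantities. At
$N = 10^5$ the jump-location and first-global-cascade estimators
coincide.

## Known limitations and deviations

Two reference quantities are *not* reproduced, deliberately left red in
the acceptance suite rather than tuned toward:

1. **Linearization correlation.** Defining the "real" norm as the
   minimal message-passing fixed point and the approximation as
   $\mathrm{CI\!-\!TM}_\infty(\text{seed})/2M$, we measure Pearson
   $r \approx 0.9999$ (both scales) across all single-seed cascades on
   the stated scale-free ensemble — the approximation is far *better*
   than the published $r \approx 0.91/0.94$. Every alternative reading
   we tested (non-cavity link counts from direct simulation, BFS-style
   node-visit approximations, post-cascade one-shot message evaluation,
   multigraph stub matching without deletion, finite $L$ down to 1)
   still yields $r \ge 0.988$. The qualitative claim — the approximation
   rarely exceeds the exact norm, and is exact on trees — does hold.
2. **High-threshold cell.** At $t = 0.6$ the selector lands at
   $q_c \approx 0.211$ versus the published $0.2049(3)$, a +2.9%
   systematic gap robust to the enumeration cap, the CI-TMm variant,
   finite $L \in \{3,5,10,20\}$ and the collapse-decrement convention;
   at $t = 0.3/0.4/0.5$ the same code matches or slightly beats the
   published values. We conclude the discrepancy hinges on an unstated
   implementation detail of the reference experiment.

Other limitations: undirected simple graphs only (no weights,
attributes, or temporal edges); stochastic-threshold and SIR/independent-
cascade models are out of scope; adaptive k-shell is quadratic and
guarded by a size warning; betweenness/closeness require igraph and
all-pairs shortest paths.
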