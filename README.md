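# citm — collective influence maximization in threshold cascades

`citm` identifies maximally influential seed sets for the **Linear
Threshold Model** (LTM) of cascading processes on networks — the regime
of *complex contagion*, where a node activates only after `m_i` of its
neighbors are active and the final cascade size `Q(q)` jumps
discontinuously (a first-order transition) once the seed fraction `q`
crosses a critical value `q_c`. Typical users are computational
epidemiologists, network scientists and marketing/infrastructure
analysts who need to pick a small set of "superspreaders" on graphs with
up to millions of nodes, where exact optimization is NP-hard and
simulation-based greedy search is unaffordable.

## The method

With thresholds `m_i = ⌈t·k_i⌉` the LTM admits cavity (message-passing)
equations on the 2M directed links,

    ν_{i→j} = n_i  OR  [ Σ_{k∈∂i\j} ν_{k→i} ≥ m_i ],

where `ν_{i→j}` indicates that node *i* ends active when *j* is removed
and `n_i` marks seeds. Linearizing this system around the inactive state
yields a non-backtracking link operator `B̂` whose entries are 1 exactly
when the middle node is **subcritical** — it has `m_i − 1` active
neighbors, so one more activation fires it. Iterating the linearized
system shows that a seed's contribution to the activated-link norm
`|ν| = Σ ν_{i→j} / 2M` is carried by **subcritical paths**: chains of
subcritical nodes along which one activation propagates
deterministically. This motivates the collective-influence score

    CI-TM_L(i) = k_i + Σ_{ℓ=1..L} N_ℓ(i),

`N_ℓ(i)` being the number of subcritical paths of length ℓ emanating
from *i*. The seed set is built greedily and *adaptively*: pick the
highest-scoring node, remove it together with the subcritical cluster it
would trigger (decrementing the residual degrees and thresholds of the
survivors), rescore only the affected neighborhoods, repeat. With a
bounded `L` the ranking costs `O(N log N)`.

The package implements, as first-class tested components:

* exact LTM dynamics with an incremental union–find `Q(q)` curve (the
  whole curve costs about one cascade) and critical-point detection;
* the message-passing equations, the `B̂` operator (evaluated on demand,
  never materialized) and the linear norm approximation;
* subcritical-path counting, the adaptive CI-TM selector and the
  modified CI-TMm variant that discounts naturally-vulnerable (`m = 1`)
  vertices;
* baselines: degree (HD), adaptive degree (HDA), k-shell and adaptive
  k-shell, PageRank, betweenness, closeness, uniformly random, and the
  exact marginal-gain greedy;
* synthetic generators (Erdős–Rényi, power-law configuration model),
  plain-text edge-list I/O, and experiment drivers for critical-point
  tables, subcritical-path timelines and activation-time histograms.

## Worked example

```r
library(citm)
g   <- generate_er(n = 20000, mean_degree = 6, rng_seed = 42)
thr <- assign_thresholds(g, t = 0.5)        # m_i = ceiling(k_i / 2)
sel <- select_seeds(g, thr, budget = g$n, L = Inf)
qc  <- detect_qc(q_curve(g, thr, sel))
print(g)
#> <ctm_graph> 20000 nodes, 59827 edges, mean degree 5.983
head(sel, 3)
#>   rank  node score
#> 1    1  5946    18
#> 2    2 15224    18
#> 3    3 12434    19
sprintf("CI-TM  q_c = %.4f", qc$q_c_first_order)
#> "CI-TM  q_c = 0.1032"
sprintf("HDA    q_c = %.4f",
        detect_qc(q_curve(g, thr, rank_hda(g)))$q_c_first_order)
#> "HDA    q_c = 0.1075"
sprintf("Random q_c = %.4f",
        detect_qc(q_curve(g, thr, rank_random(g, 1)))$q_c_first_order)
#> "Random q_c = 0.2213"
spread(g, thr, sel$node[seq_len(2100)])
#> <ctm_cascade> 19994 active, 115 rounds, Q = 0.9980
```

Reading: seeding ~10.3% of nodes in CI-TM order tips the network into a
global cascade, versus ~10.8% for adaptive high degree and ~22% for
random seeding — the `score` column shows each seed's CI-TM value (its
residual degree plus attached subcritical paths) at selection time, and
the final `spread()` confirms that seeding just past `q_c` activates
essentially the whole graph. On ER graphs with `N = 1e5`, `⟨k⟩ = 6` the
package reproduces the reference critical fractions (e.g. CI-TM
`q_c ≈ 0.104`, random `q_c ≈ 0.218–0.220` at `t = 0.5`) in a few seconds
per realization.

## Command line

A thin CLI ships in `inst/cli/citm`:

```sh
Rscript inst/cli/citm generate --model er --n 20000 --k-mean 6 --seed 1 --o edges.tsv
Rscript inst/cli/citm rank --method citm --graph edges.tsv --t 0.5 --o ranking.tsv
Rscript inst/cli/citm norms --graph edges.tsv --t 0.5 --o pairs.tsv
```
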