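# Fixture builders ------------------------------------------------------

path_graph <- function(n) {
  graph_from_edges(cbind(seq_len(n - 1), seq_len(n - 1) + 1L), n = n)
}

cycle_graph <- function(n) {
  graph_from_edges(rbind(cbind(seq_len(n - 1), seq_len(n - 1) + 1L),
                         c(n, 1L)), n = n)
}

star_graph <- function(n_leaves) {
  graph_from_edges(cbind(1L, seq_len(n_leaves) + 1L), n = n_leaves + 1L)
}

complete_graph <- function(n) {
  graph_from_edges(t(combn(n, 2)), n = n)
}

# The worked collective-influence example: node i (1) of degree 3 with one
# subcritical neighbor u (2) that branches to subcritical x (5) and y (6),
# each carrying one further neighbor. CI-TM_0/1/2 = 3/5/7.
fig1e_fixture <- function() {
  g <- graph_from_edges(rbind(
    c(1, 2), c(1, 3), c(1, 4),   # i - u, a, b
    c(2, 5), c(2, 6),            # u - x, y
    c(5, 7), c(6, 8)))           # x - x', y - y'
  m <- c(2L, 1L, 2L, 2L, 1L, 1L, 2L, 2L)
  list(g = g, thr = thresholds(g, m), i = 1L)
}

# uniform random labeled tree via Pruefer sequence
random_tree <- function(n, seed) {
  with_seed(seed, {
    if (n == 1L) return(graph_from_edges(matrix(integer(0), ncol = 2), n = 1L))
    if (n == 2L) return(graph_from_edges(rbind(c(1L, 2L)), n = 2L))
    prf <- sample.int(n, n - 2L, replace = TRUE)
    deg <- rep.int(1L, n) + tabulate(prf, n)
    edges <- matrix(0L, n - 1L, 2L)
    ptr <- 1L
    leaves <- which(deg == 1L)
    for (k in seq_len(n - 2L)) {
      leaf <- min(leaves)
      v <- prf[k]
      edges[ptr, ] <- c(leaf, v); ptr <- ptr + 1L
      leaves <- leaves[leaves != leaf]
      deg[v] <- deg[v] - 1L
      if (deg[v] == 1L) leaves <- c(leaves, v)
    }
    edges[ptr, ] <- sort(leaves)
    graph_from_edges(edges, n = n)
  })
}

random_thresholds <- function(g, seed) {
  with_seed(seed, thresholds(g, pmax(1L, as.integer(
    ceiling(runif(g$n) * pmax(g$deg, 1L))))))
}

# Independent oracles ----------------------------------------------------

# Asynchronous brute-force LTM: one random node per step until no inactive
# node can fire. Monotone dynamics, so this must match the synchronous
# fixed point.
ltm_async_oracle <- function(g, thr, seeds, seed = 1) {
  with_seed(seed, {
    state <- rep(0L, g$n)
    state[seeds] <- 1L
    repeat {
      fireable <- which(state == 0L & vapply(seq_len(g$n), function(v) {
        g$deg[v] > 0L && sum(state[neighbors_of(g, v)]) >= thr$m[v]
      }, logical(1)))
      if (length(fireable) == 0L) break
      state[sample(rep(fireable, 2L), 1L)] <- 1L
    }
    state
  })
}

# restart-from-scratch Q(q) curve
qcurve_restart_oracle <- function(g, thr, ranking) {
  vapply(0:length(ranking), function(s) {
    giant_active_fraction(g, spread(g, thr, head(ranking, s))$state)
  }, numeric(1))
}

# k-shell indices by naive repeated peeling
coreness_oracle <- function(g) {
  deg <- g$deg
  alive <- rep(TRUE, g$n)
  core <- integer(g$n)
  k <- 0L
  while (any(alive)) {
    repeat {
      peel <- which(alive & deg <= k)
      if (length(peel) == 0L) break
      for (v in peel) {
        core[v] <- k
        alive[v] <- FALSE
        nb <- neighbors_of(g, v)
        deg[nb] <- deg[nb] - 1L
      }
    }
    k <- k + 1L
  }
  core
}

# exhaustive minimal seed count for full activation (tiny graphs only)
min_seeds_bruteforce <- function(g, thr) {
  for (s in 0:g$n) {
    combs <- combn(g$n, s)
    for (c in seq_len(ncol(combs))) {
      if (spread(g, thr, combs[, c])$n_active == g$n) return(s)
    }
  }
  g$n
}

# smallest prefix of a ranking that activates the whole graph
min_seeds_from_ranking <- function(g, thr, ranking) {
  if (is.data.frame(ranking)) ranking <- ranking$node
  cv <- q_curve(g, thr, ranking)
  hit <- which(cv$n_active == g$n)
  if (length(hit) == 0L) return(NA_integer_)
  cv$num_seeds[hit[1L]]
}

# degree-greedy with the same collapse/closure semantics as L = 0 CI-TM,
# written independently in R as a cross-implementation oracle
degree_greedy_collapse_oracle <- function(g, thr, budget) {
  st <- selection_state(g, thr)
  picked <- integer(0)
  while (length(picked) < budget && any(st$alive == 1L)) {
    live <- which(st$alive == 1L)
    i <- live[order(-st$rdeg[live], live)][1L]
    picked <- c(picked, i)
    st <- collapse(g, st, i, L = 0)
  }
  picked
}
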