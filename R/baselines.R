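make_ranking <- function(node, score, method) {
  out <- data.frame(rank = seq_along(node), node = as.integer(node),
                    score = score)
  attr(out, "method") <- method
  class(out) <- c("ctm_ranking", "data.frame")
  out
}

#' @export
print.ctm_ranking <- function(x, ...) {
  cat(sprintf("<ctm_ranking> method %s, %d nodes\n",
              attr(x, "method"), nrow(x)))
  if (nrow(x)) print.data.frame(head(x, 10L))
  invisible(x)
}

#' Static high-degree ranking
#'
#' Nodes in descending degree order, ties broken by smallest id.
#' @param g a `ctm_graph`.
#' @return a `ctm_ranking`.
#' @export
rank_hd <- function(g) {
  ord <- order(-g$deg, seq_len(g$n))
  make_ranking(ord, g$deg[ord], "hd")
}

#' Adaptive high-degree ranking
#'
#' Iteratively selects the live node with the largest residual degree,
#' removes it and its edges, and recomputes degrees.
#' @param g a `ctm_graph`.
#' @param budget how many nodes to rank (default all).
#' @return a `ctm_ranking` (score = residual degree at selection).
#' @export
rank_hda <- function(g, budget = g$n) {
  if (budget < 0 || budget > g$n) stop("budget must lie in 0..n")
  res <- cpp_rank_hda(g$xadj, g$adj, as.integer(budget))
  make_ranking(res$order + 1L, res$score, "hda")
}

#' k-shell (k-core) rankings
#'
#' `rank_kcore()` ranks nodes by their k-shell index from one peeling
#' decomposition (ties: degree, then smallest id). The adaptive variant
#' `rank_kcore_adaptive()` recomputes the decomposition of the residual
#' graph after each removal and takes the largest-degree node within the
#' highest shell; it costs O(N) decompositions and is guarded by a
#' warning on large graphs.
#'
#' @param g a `ctm_graph`.
#' @return a `ctm_ranking` (score = shell index).
#' @export
rank_kcore <- function(g) {
  core <- cpp_coreness(g$xadj, g$adj)
  ord <- order(-core, -g$deg, seq_len(g$n))
  make_ranking(ord, core[ord], "ks")
}

#' @param budget how many nodes to rank.
#' @rdname rank_kcore
#' @export
rank_kcore_adaptive <- function(g, budget = g$n) {
  if (budget < 0 || budget > g$n) stop("budget must lie in 0..n")
  if (g$n > 20000L)
    warning("adaptive k-shell is quadratic; this graph is large")
  res <- cpp_rank_ksa(g$xadj, g$adj, as.integer(budget))
  make_ranking(res$order + 1L, res$score, "ksa")
}

#' PageRank ranking
#'
#' Power iteration for the stationary visiting probability of a random
#' walker with teleportation on the undirected graph. Dangling (isolated)
#' nodes redistribute their mass uniformly, so scores always sum to 1.
#'
#' @param g a `ctm_graph`.
#' @param damping damping factor (default 0.85).
#' @param tol sup-norm convergence tolerance (default 1e-10).
#' @param max_iter iteration cap.
#' @return a `ctm_ranking` (score = PageRank probability).
#' @export
rank_pagerank <- function(g, damping = 0.85, tol = 1e-10, max_iter = 1000L) {
  n <- g$n
  if (n == 0L) return(make_ranking(integer(0), numeric(0), "pr"))
  r <- rep.int(1 / n, n)
  deg <- g$deg
  src <- g$adj + 1L # for each directed link, the contributing neighbor
  isolated <- deg == 0L
  for (it in seq_len(max_iter)) {
    w <- ifelse(isolated, 0, r / pmax(deg, 1L))
    contrib <- w[src]
    cs <- cumsum(c(0, contrib))
    inflow <- cs[g$xadj[-1L] + 1L] - cs[g$xadj[-(n + 1L)] + 1L]
    dangling <- sum(r[isolated])
    r_new <- (1 - damping) / n + damping * (inflow + dangling / n)
    delta <- max(abs(r_new - r))
    r <- r_new
    if (delta < tol) break
  }
  ord <- order(-r, seq_len(n))
  make_ranking(ord, r[ord], "pr")
}

#' Uniformly random ranking
#'
#' @param g a `ctm_graph`.
#' @param rng_seed integer seed.
#' @return a `ctm_ranking` (score = NA).
#' @export
rank_random <- function(g, rng_seed) {
  ord <- with_seed(rng_seed, sample.int(g$n))
  make_ranking(ord, rep(NA_real_, g$n), "random")
}

#' Betweenness and closeness centrality rankings
#'
#' Exact shortest-path betweenness (Brandes accumulation, via igraph) and
#' closeness defined as the reciprocal of the mean shortest distance to
#' the other reachable nodes within a node's component. Both require the
#' igraph package and all-pairs shortest paths, so they are only meant
#' for moderate graph sizes.
#'
#' @param g a `ctm_graph`.
#' @return a `ctm_ranking`.
#' @export
rank_betweenness <- function(g) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("rank_betweenness() requires the igraph package")
  b <- igraph::betweenness(as_igraph(g), directed = FALSE)
  ord <- order(-b, seq_len(g$n))
  make_ranking(ord, b[ord], "bc")
}

#' @rdname rank_betweenness
#' @export
rank_closeness <- function(g) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("rank_closeness() requires the igraph package")
  d <- igraph::distances(as_igraph(g))
  cc <- vapply(seq_len(g$n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0L) 0 else 1 / mean(di)
  }, numeric(1))
  ord <- order(-cc, seq_len(g$n))
  make_ranking(ord, cc[ord], "cc")
}

#' Exact greedy seed ranking
#'
#' Sequentially adds the node with the maximal marginal gain in the total
#' number of activated nodes. The LTM is deterministic, so one cascade
#' per candidate suffices; the cost is still O(budget * N * M), which
#' restricts this baseline to small graphs.
#'
#' @param g a `ctm_graph`.
#' @param thr a `ctm_thresholds`.
#' @param budget number of seeds.
#' @return a `ctm_ranking` (score = marginal activated-count gain).
#' @export
rank_greedy <- function(g, thr, budget) {
  check_thresholds(g, thr)
  if (budget < 0 || budget > g$n) stop("budget must lie in 0..n")
  res <- cpp_rank_greedy(g$xadj, g$adj, thr$m, as.integer(budget))
  make_ranking(res$order + 1L, res$gain, "greedy")
}
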