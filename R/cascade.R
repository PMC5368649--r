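check_nodes <- function(g, nodes, what = "nodes") {
  nodes <- as.integer(nodes)
  if (anyNA(nodes) || (length(nodes) && (min(nodes) < 1L || max(nodes) > g$n)))
    stop(sprintf("%s must be node ids in 1..%d", what, g$n))
  nodes
}

check_thresholds <- function(g, thr) {
  if (!inherits(thr, "ctm_thresholds")) stop("thr must be a ctm_thresholds")
  if (length(thr$m) != g$n) stop("thresholds do not match graph size")
  thr
}

#' Deterministic LTM cascade
#'
#' Runs the Linear Threshold Model to its fixed point: seeds are active
#' at time 0 and, in synchronous rounds, every inactive node with at
#' least `m_i` active neighbors activates. The dynamics are monotone, so
#' the fixed point does not depend on the update schedule.
#'
#' @param g a `ctm_graph`.
#' @param thr a `ctm_thresholds`.
#' @param seeds integer vector of seed nodes (duplicates are collapsed).
#' @return object of class `ctm_cascade`: `state` (0/1 per node),
#'   `activation_time` (0 for seeds, `-1` for never-active), `rounds`,
#'   `n_active`, and `Q` (giant active component fraction).
#' @export
spread <- function(g, thr, seeds) {
  check_thresholds(g, thr)
  seeds <- unique(check_nodes(g, seeds, "seeds"))
  res <- cpp_spread(g$xadj, g$adj, thr$m, seeds - 1L)
  giant <- cpp_giant_active(g$xadj, g$adj, res$state)
  structure(
    list(state = res$state, activation_time = res$time, rounds = res$rounds,
         n_active = sum(res$state),
         Q = if (g$n) giant / g$n else 0),
    class = "ctm_cascade")
}

#' @export
print.ctm_cascade <- function(x, ...) {
  cat(sprintf("<ctm_cascade> %d active, %d rounds, Q = %.4f\n",
              x$n_active, x$rounds, x$Q))
  invisible(x)
}

#' Giant active component fraction
#'
#' Size of the largest connected component of the subgraph induced by the
#' active nodes, divided by the total number of nodes.
#'
#' @param g a `ctm_graph`.
#' @param res a `ctm_cascade` from [spread()], or a 0/1 state vector.
#' @return a fraction in `[0, 1]`.
#' @export
giant_active_fraction <- function(g, res) {
  state <- if (inherits(res, "ctm_cascade")) res$state else as.integer(res)
  if (length(state) != g$n) stop("state does not match graph size")
  if (g$n == 0L) return(0)
  cpp_giant_active(g$xadj, g$adj, state) / g$n
}

#' Q(q) along a seeding order
#'
#' Evaluates the giant active component fraction `Q` as the ranked nodes
#' are seeded one at a time, always on the original graph and thresholds.
#' The cascade is continued incrementally between prefixes, which by
#' monotonicity agrees exactly with restarting from scratch at every
#' prefix, and a union-find tracks the giant active component, so the
#' whole curve costs about as much as one cascade.
#'
#' @param g a `ctm_graph`.
#' @param thr a `ctm_thresholds`.
#' @param ranking seeding order: integer node vector or a ranking object
#'   with a `node` column.
#' @return `ctm_qcurve` data frame with columns `num_seeds` (0..length),
#'   `q`, `Q`, `n_active`.
#' @export
q_curve <- function(g, thr, ranking) {
  check_thresholds(g, thr)
  if (is.data.frame(ranking)) ranking <- ranking$node
  ranking <- check_nodes(g, ranking, "ranking")
  if (anyDuplicated(ranking)) stop("ranking must not repeat nodes")
  res <- cpp_q_curve(g$xadj, g$adj, thr$m, ranking - 1L)
  s <- 0:length(ranking)
  out <- data.frame(num_seeds = s, q = if (g$n) s / g$n else 0,
                    Q = if (g$n) res$giant / g$n else 0,
                    n_active = res$n_active)
  class(out) <- c("ctm_qcurve", "data.frame")
  out
}

#' Locate the cascade transitions on a Q(q) curve
#'
#' The first-order critical point is the seed fraction at the single
#' largest one-step jump of `Q` (reported only when that jump exceeds
#' `jump_threshold`; real first-order transitions span most of `[0, 1]`
#' while smooth curves produce only `O(1/N)` steps). The continuous onset
#' is the smallest `q` with `Q > onset_threshold`. Ties break toward the
#' smallest `q`.
#'
#' @param curve a `ctm_qcurve` (or data frame with `q` and `Q`).
#' @param jump_threshold minimal `Q` increment that counts as a
#'   first-order jump (default 0.1).
#' @param onset_threshold `Q` level defining the continuous onset
#'   (default 0.01).
#' @return list with `q_c_first_order` and `q_c_continuous` (either may
#'   be `NA` if not found).
#' @export
detect_qc <- function(curve, jump_threshold = 0.1, onset_threshold = 0.01) {
  if (NROW(curve) == 0L) stop("empty curve")
  q <- curve$q
  Q <- curve$Q
  dq <- diff(Q)
  first_order <- NA_real_
  if (length(dq) && max(dq) > jump_threshold) {
    j <- which.max(dq) # which.max takes the first (smallest q) maximum
    first_order <- q[j + 1L]
  }
  cont <- NA_real_
  above <- which(Q > onset_threshold)
  if (length(above)) cont <- q[above[1L]]
  list(q_c_first_order = first_order, q_c_continuous = cont)
}

#' Seed fraction helper
#'
#' @param g a `ctm_graph`.
#' @param seeds integer seed vector.
#' @return `length(unique(seeds)) / n`.
#' @export
seed_fraction <- function(g, seeds) {
  length(unique(check_nodes(g, seeds, "seeds"))) / g$n
}
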