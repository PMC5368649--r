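# Directed-link bookkeeping. Link e (0-based position in the CSR adjacency)
# is from[e] -> to[e]; rev[e] indexes the opposite direction. Recomputed per
# call; costs O(M log k).
link_table <- function(g) {
  from <- rep.int(seq_len(g$n), g$deg)
  to <- g$adj + 1L
  rev <- cpp_reverse_links(g$xadj, g$adj)
  list(from = from, to = to, rev = rev)
}

#' Solve the LTM message-passing equations
#'
#' Computes the minimal fixed point of the cavity equations on the 2M
#' directed links,
#' \deqn{\nu_{i\to j} = n_i \;\mathrm{OR}\; \Big[\sum_{k\in\partial i
#'   \setminus j} \nu_{k\to i} \ge m_i\Big],}
#' by monotone iteration from the all-zero state (only seed links start
#' active). \eqn{\nu_{i\to j}} indicates that node i ends up active when
#' node j is removed from the network. The OR over all combinations of
#' \eqn{m_i} active neighbors collapses to the counting condition above
#' for binary messages. Messages only ever flip 0 to 1, so the queue
#' schedule used internally reaches the same (minimal) fixed point as any
#' sweep schedule, in at most 2M flips.
#'
#' @param g a `ctm_graph`.
#' @param thr a `ctm_thresholds`.
#' @param seeds integer seed nodes.
#' @param max_sweeps unused guard kept for interface compatibility; the
#'   queue solver always terminates after at most 2M flips.
#' @return object of class `ctm_messages`: data-frame-like fields `from`,
#'   `to`, `nu` over the 2M directed links, per-node incoming sums
#'   `in_count`, and `norm` \eqn{= \sum \nu_{i\to j} / 2M}.
#' @export
solve_messages <- function(g, thr, seeds, max_sweeps = NULL) {
  check_thresholds(g, thr)
  seeds <- unique(check_nodes(g, seeds, "seeds"))
  lt <- link_table(g)
  res <- cpp_solve_messages(g$xadj, g$adj, lt$rev, thr$m, seeds - 1L)
  nlinks <- length(g$adj)
  structure(
    list(from = lt$from, to = lt$to, nu = res$nu, in_count = res$in_count,
         n_links = nlinks,
         norm = if (nlinks) sum(res$nu) / nlinks else 0),
    class = "ctm_messages")
}

#' @export
print.ctm_messages <- function(x, ...) {
  cat(sprintf("<ctm_messages> %d directed links, |nu| = %.5f\n",
              x$n_links, x$norm))
  invisible(x)
}

#' Node states implied by a message fixed point
#'
#' \eqn{\nu_i = n_i} OR \eqn{[\sum_{k\in\partial i} \nu_{k\to i} \ge m_i]}.
#'
#' @inheritParams solve_messages
#' @param msgs a `ctm_messages` fixed point for the same seeds.
#' @return integer 0/1 vector of final node states.
#' @export
node_states_from_messages <- function(g, thr, seeds, msgs) {
  check_thresholds(g, thr)
  seeds <- unique(check_nodes(g, seeds, "seeds"))
  n_i <- integer(g$n)
  n_i[seeds] <- 1L
  as.integer(n_i | (msgs$in_count >= thr$m))
}

#' Linearized link-to-link operator entry
#'
#' Entry \eqn{\hat B_{k\to i, i\to j}} of the linearization of the message
#' equations around the inactive state: 1 iff the two links are
#' consecutive and non-backtracking (`k != j`) and node `i` is subcritical
#' in the absence of `k` and `j`, i.e. its number of active neighbors
#' excluding `k` and `j` equals `m_i - 1`. The 2M-by-2M operator is never
#' materialized; entries are evaluated on demand.
#'
#' @param g a `ctm_graph`.
#' @param thr a `ctm_thresholds`.
#' @param active integer vector of currently active nodes.
#' @param k,i,j nodes with `k` and `j` adjacent to `i`.
#' @return 0 or 1.
#' @export
bhat <- function(g, thr, active, k, i, j) {
  check_thresholds(g, thr)
  active <- unique(check_nodes(g, active, "active"))
  nb <- neighbors_of(g, i)
  if (!(k %in% nb) || !(j %in% nb))
    stop("k and j must both be adjacent to i")
  if (k == j) return(0L)
  a <- sum(nb %in% active & nb != k & nb != j)
  as.integer(a == thr$m[i] - 1L)
}

#' Linear subcritical-path approximation of the activated-link norm
#'
#' For a single seed, approximates \eqn{|\nu_\to|} by the seed's
#' unlimited-depth collective-influence score (its degree plus the total
#' number of subcritical paths emanating from it) divided by 2M. Exact on
#' trees; on loopy graphs it is typically a slight underestimate because
#' loops are neglected.
#'
#' @param g a `ctm_graph`.
#' @param thr a `ctm_thresholds`.
#' @param seed a single seed node.
#' @return approximate norm in `[0, 1]`.
#' @export
linear_norm_approx <- function(g, thr, seed) {
  check_thresholds(g, thr)
  seed <- check_nodes(g, seed, "seed")
  if (length(seed) != 1L) stop("exactly one seed required")
  if (length(g$adj) == 0L) return(0)
  st <- selection_state(g, thr)
  res <- cpp_count_paths(g$xadj, g$adj, st$alive, st$rdeg, st$rm, st$morig,
                         seed - 1L, -1L, Inf, FALSE)
  res$score / length(g$adj)
}

#' Exact vs. linearized norm across all single-seed cascades
#'
#' Seeds every node in turn, computes the exact message-passing norm
#' \eqn{|\nu_\to|} and its linear subcritical-path approximation, and
#' reports Pearson correlations on the linear and (for strictly positive
#' pairs) logarithmic scales.
#'
#' @param g a `ctm_graph`.
#' @param thr a `ctm_thresholds`.
#' @return list with `pairs` (data frame: node, true_norm, approx_norm),
#'   `r_linear`, `r_log`, and `n_log_excluded` (pairs dropped from the
#'   log-scale correlation because one value was 0).
#' @export
norm_comparison <- function(g, thr) {
  check_thresholds(g, thr)
  if (length(g$adj) == 0L) stop("graph has no links")
  lt <- link_table(g)
  true_counts <- cpp_single_seed_message_counts(g$xadj, g$adj, lt$rev, thr$m)
  st <- selection_state(g, thr)
  approx_scores <- cpp_score_all(g$xadj, g$adj, st$alive, st$rdeg, st$rm,
                                 st$morig, -1L, Inf, FALSE)
  nlinks <- length(g$adj)
  tv <- true_counts / nlinks
  av <- approx_scores / nlinks
  pos <- tv > 0 & av > 0
  structure(
    list(pairs = data.frame(node = seq_len(g$n), true_norm = tv,
                            approx_norm = av),
         r_linear = cor(tv, av),
         r_log = if (sum(pos) >= 3L) cor(log(tv[pos]), log(av[pos]))
                 else NA_real_,
         n_log_excluded = sum(!pos)),
    class = "ctm_norm_comparison")
}

#' @export
print.ctm_norm_comparison <- function(x, ...) {
  cat(sprintf(
    "<ctm_norm_comparison> %d seeds, r = %.4f (linear), %.4f (log; %d excluded)\n",
    nrow(x$pairs), x$r_linear, x$r_log, x$n_log_excluded))
  invisible(x)
}
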