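# L is Inf (unlimited) or a non-negative integer; C++ encodes unlimited as -1.
encode_L <- function(L) {
  if (length(L) != 1L || is.na(L) || L < 0) stop("L must be >= 0 or Inf")
  if (is.infinite(L)) -1L else as.integer(L)
}

#' Residual selection state
#'
#' The adaptive selector works in a residual picture: choosing a seed
#' removes it together with the subcritical vertices it triggers, and
#' every surviving neighbor of a removed node has its residual degree and
#' residual threshold decremented once per removed neighbor. A live node
#' is subcritical exactly when its residual threshold equals 1 (one more
#' neighbor activation would fire it), and is certainly activated - hence
#' removed by closure - when it reaches 0.
#'
#' @param g a `ctm_graph`.
#' @param thr a `ctm_thresholds`.
#' @return object of class `ctm_selstate` with integer fields `alive`,
#'   `rdeg`, `rm` (residual thresholds) and `morig`.
#' @export
selection_state <- function(g, thr) {
  check_thresholds(g, thr)
  structure(list(alive = rep.int(1L, g$n), rdeg = g$deg, rm = thr$m,
                 morig = thr$m, removed = integer(0)),
            class = "ctm_selstate")
}

#' Count subcritical paths from a node
#'
#' A subcritical path of length `l >= 1` from node `i` is a simple
#' directed walk `i -> v1 -> ... -> vl -> w` whose interior nodes `v` are
#' all live and subcritical (residual threshold 1), with no node repeated
#' and consecutive links non-backtracking; the terminal `w` is any live
#' neighbor of `vl` other than its predecessor. Activating `i` fires the
#' whole path deterministically, which is why these walks carry a seed's
#' long-range influence. The length-0 contribution is the residual degree
#' of `i`, so the score `CI-TM_L(i) = k_i + sum_l N_l` reduces to the
#' high-degree heuristic at `L = 0`.
#'
#' Path enumeration on loopy graphs can blow up combinatorially near the
#' cascade transition; `max_path_events` caps the number of enumeration
#' steps, and a capped count is flagged `saturated` (with an effectively
#' infinite score for ranking purposes). The reached set is computed by
#' breadth-first search and is exact even when counting saturates.
#'
#' @param g a `ctm_graph`.
#' @param state a `ctm_selstate` (or a `ctm_thresholds`, meaning the
#'   pristine state in which only threshold-1 nodes are subcritical).
#' @param i a live node.
#' @param L maximal path length, or `Inf` for unlimited (termination is
#'   then guaranteed by the simple-path constraint).
#' @param max_path_events enumeration budget (default unlimited).
#' @param variant `"standard"`, or `"modified"` to exclude vulnerable
#'   vertices (original threshold 1) from paths.
#' @return object of class `ctm_pathcount`: `score`, `counts` (`N_l` for
#'   `l = 1..`), `reached` (the subcritical vertices on the paths, i.e.
#'   `C(i, L)` minus `i` itself), `saturated`.
#' @export
count_subcritical_paths <- function(g, state, i, L = Inf,
                                    max_path_events = Inf,
                                    variant = c("standard", "modified")) {
  variant <- match.arg(variant)
  if (inherits(state, "ctm_thresholds")) state <- selection_state(g, state)
  stopifnot(inherits(state, "ctm_selstate"))
  i <- check_nodes(g, i, "i")
  if (length(i) != 1L) stop("exactly one node required")
  if (!state$alive[i]) stop("node is removed from the selection state")
  res <- cpp_count_paths(g$xadj, g$adj, state$alive, state$rdeg, state$rm,
                         state$morig, i - 1L, encode_L(L), max_path_events,
                         variant == "modified")
  structure(list(node = i, L = L, score = res$score, counts = res$counts,
                 reached = res$reached + 1L, saturated = res$saturated),
            class = "ctm_pathcount")
}

#' @export
print.ctm_pathcount <- function(x, ...) {
  cat(sprintf("<ctm_pathcount> node %d: score %s, %d reached%s\n", x$node,
              format(x$score), length(x$reached),
              if (x$saturated) " (saturated)" else ""))
  invisible(x)
}

#' CI-TM scores for all live nodes
#'
#' @param g a `ctm_graph`.
#' @param state a `ctm_selstate` or `ctm_thresholds` (pristine state).
#' @param L maximal path length (`Inf` = unlimited).
#' @param max_path_events per-node enumeration budget.
#' @param variant see [count_subcritical_paths()].
#' @return numeric vector of scores (`NA` for removed nodes). At `L = 0`
#'   this is exactly the residual degree.
#' @export
score_all <- function(g, state, L = Inf, max_path_events = Inf,
                      variant = c("standard", "modified")) {
  variant <- match.arg(variant)
  if (inherits(state, "ctm_thresholds")) state <- selection_state(g, state)
  stopifnot(inherits(state, "ctm_selstate"))
  cpp_score_all(g$xadj, g$adj, state$alive, state$rdeg, state$rm,
                state$morig, encode_L(L), max_path_events,
                variant == "modified")
}

#' Collapse a chosen seed and its subcritical cluster
#'
#' Removes `C(i, L)` (the node plus the subcritical vertices on its
#' subcritical paths), decrements each surviving neighbor's residual
#' degree and threshold once per removed adjacent node, and recursively
#' removes (closure) any survivor whose residual threshold reaches 0 -
#' such a node is certainly activated by the seeds already chosen.
#' Residual thresholds never drop below 0.
#'
#' @param g a `ctm_graph`.
#' @param state a `ctm_selstate`.
#' @param i the node being seeded (must be live).
#' @param summary optional `ctm_pathcount` for `i` whose `reached` set is
#'   reused; otherwise the reach is recomputed.
#' @param L,variant used when recomputing the reach.
#' @return the updated `ctm_selstate`; the nodes removed in this step are
#'   appended to its `removed` field.
#' @export
collapse <- function(g, state, i, summary = NULL, L = Inf,
                     variant = c("standard", "modified")) {
  variant <- match.arg(variant)
  stopifnot(inherits(state, "ctm_selstate"))
  i <- check_nodes(g, i, "i")
  if (!state$alive[i]) stop("node is already removed")
  reached <- if (!is.null(summary)) {
    summary$reached # BFS-derived, exact even when path counting saturated
  } else {
    count_subcritical_paths(g, state, i, L = L, variant = variant)$reached
  }
  res <- cpp_collapse_step(g$xadj, g$adj, state$alive, state$rdeg, state$rm,
                           state$morig, i - 1L, reached - 1L)
  structure(list(alive = res$alive, rdeg = res$rdeg, rm = res$rm,
                 morig = state$morig,
                 removed = c(state$removed, res$removed + 1L)),
            class = "ctm_selstate")
}

#' Adaptive greedy CI-TM seed selection
#'
#' Implements the adaptive collective-influence algorithm for threshold
#' cascades: score every node by `CI-TM_L`, then repeatedly pick the
#' highest-scoring live node (ties broken toward the smallest id), append
#' it to the seed list, collapse it together with its subcritical cluster
#' (see [collapse()]), and rescore only the nodes whose score can have
#' changed - the decremented survivors and the neighborhoods of every
#' subcritical cluster they belong to. With a bounded `L` this is the
#' O(N log N) ranking procedure; unlimited `L` counts paths exhaustively
#' under the simple-path constraint.
#'
#' The `"modified"` variant (CI-TMm) excludes vulnerable vertices - nodes
#' whose original threshold is 1, which are subcritical by nature rather
#' than through earlier activations - from path traversal and counting.
#' On sparse graphs whose vulnerable vertices form small fragmented
#' clusters this avoids wasting seeds on peripheral hubs.
#'
#' @param g a `ctm_graph`.
#' @param thr a `ctm_thresholds`.
#' @param budget number of seeds to select (`<= n`). Selection stops
#'   early if every node has been removed (each removed node is already
#'   guaranteed active, so further seeds would be wasted).
#' @param L maximal subcritical-path length (`Inf` = unlimited).
#' @param variant `"standard"` or `"modified"`.
#' @param max_path_events per-scoring enumeration budget; nodes whose
#'   count saturates rank above all finite scores (see
#'   [count_subcritical_paths()]).
#' @return a ranking: data frame with columns `rank`, `node`,
#'   `score` (the CI-TM value at selection time), with attribute
#'   `method`.
#' @export
select_seeds <- function(g, thr, budget, L = Inf,
                         variant = c("standard", "modified"),
                         max_path_events = 1e6) {
  variant <- match.arg(variant)
  check_thresholds(g, thr)
  if (budget < 0 || budget > g$n) stop("budget must lie in 0..n")
  res <- cpp_select_seeds(g$xadj, g$adj, thr$m, as.integer(budget),
                          encode_L(L), max_path_events,
                          variant == "modified")
  out <- data.frame(rank = seq_along(res$seeds), node = res$seeds + 1L,
                    score = res$score)
  attr(out, "method") <- if (variant == "modified") "citmm" else "citm"
  class(out) <- c("ctm_ranking", "data.frame")
  out
}
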