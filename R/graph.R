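#' @useDynLib citm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom runif sd cor setNames
#' @importFrom utils head
NULL

# Run code with a transient RNG state seeded by `seed`, restoring the
# caller's stream afterwards. Every stochastic entry point funnels its
# randomness through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("rng_seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Build a graph from an edge matrix
#'
#' Constructs the undirected simple graph container used throughout the
#' package. Nodes are `1..n`; the graph stores the edge list, a CSR
#' adjacency (with rows sorted ascending, as the message-passing code
#' requires), and per-node degrees. Self-loops and duplicate edges are
#' dropped with a warning.
#'
#' @param edges two-column integer matrix of node pairs (1-based).
#' @param n number of nodes; defaults to the largest endpoint.
#' @param node_names optional external labels (used by edge-list I/O);
#'   defaults to the 0-based ids `0:(n-1)` so written files follow the
#'   conventional integer edge-list format.
#' @return an object of class `ctm_graph` with fields `n`, `edges`,
#'   `xadj`, `adj` (0-based CSR), `deg`, `m_edges`, `node_names`.
#' @export
graph_from_edges <- function(edges, n = NULL, node_names = NULL) {
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2)
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  if (anyNA(edges)) stop("edges contain missing values")
  if (nrow(edges) > 0 && min(edges) < 1L) stop("node ids must be >= 1")
  if (is.null(n)) n <- if (nrow(edges)) max(edges) else 0L
  n <- as.integer(n)
  if (nrow(edges) && max(edges) > n) stop("edge endpoint exceeds n")
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges)) {
    a <- pmin(edges[, 1], edges[, 2])
    b <- pmax(edges[, 1], edges[, 2])
    key <- (a - 1) * as.double(n) + b
    dup <- duplicated(key)
    if (any(dup)) {
      warning(sprintf("dropping %d duplicate edge(s)", sum(dup)))
      a <- a[!dup]; b <- b[!dup]
    }
    edges <- cbind(a, b)
  }
  m <- nrow(edges)
  from <- c(edges[, 1], edges[, 2])
  to <- c(edges[, 2], edges[, 1])
  ord <- order(from, to)
  deg <- tabulate(from, nbins = n)
  xadj <- c(0L, cumsum(deg))
  g <- structure(
    list(n = n, edges = edges, xadj = as.integer(xadj),
         adj = as.integer(to[ord] - 1L), deg = as.integer(deg),
         m_edges = m,
         node_names = if (!is.null(node_names)) node_names
                      else if (n > 0L) 0:(n - 1L) else integer(0)),
    class = "ctm_graph")
  g
}

#' @export
print.ctm_graph <- function(x, ...) {
  cat(sprintf("<ctm_graph> %d nodes, %d edges, mean degree %.3f\n",
              x$n, x$m_edges, if (x$n) 2 * x$m_edges / x$n else 0))
  invisible(x)
}

#' Check graph invariants
#'
#' Verifies the structural invariants of a [graph_from_edges()] object:
#' no self-loops or duplicate edges, symmetric adjacency, consistent
#' degrees with `sum(deg) == 2 * m_edges`.
#'
#' @param g a `ctm_graph`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_graph <- function(g) {
  stopifnot(inherits(g, "ctm_graph"))
  e <- g$edges
  if (nrow(e)) {
    if (any(e[, 1] == e[, 2])) stop("self-loop present")
    key <- (e[, 1] - 1) * as.double(g$n) + e[, 2]
    if (anyDuplicated(key)) stop("duplicate edge present")
    if (max(e) > g$n) stop("edge endpoint out of range")
  }
  if (sum(g$deg) != 2 * g$m_edges) stop("degree sum != 2M")
  if (length(g$xadj) != g$n + 1L) stop("bad CSR index")
  # adjacency symmetric: every directed link has its reverse
  fr <- rep.int(seq_len(g$n), g$deg)
  key_dir <- (fr - 1) * as.double(g$n) + g$adj + 1
  key_rev <- as.double(g$adj) * g$n + fr
  if (!setequal(key_dir, key_rev)) stop("adjacency not symmetric")
  invisible(TRUE)
}

neighbors_of <- function(g, i) {
  g$adj[seq.int(g$xadj[i] + 1L, length.out = g$deg[i])] + 1L
}

#' Erdős–Rényi random graph
#'
#' Samples `G(n, p)` with `p = mean_degree / (n - 1)` by geometric edge
#' skipping, so the cost is proportional to the number of edges drawn.
#'
#' @param n number of nodes (`>= 1`).
#' @param mean_degree target mean degree, in `(0, n-1]` (0 allowed, and
#'   required, for `n = 1`).
#' @param rng_seed integer seed; identical seeds give identical graphs.
#' @return a `ctm_graph`.
#' @export
generate_er <- function(n, mean_degree, rng_seed) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("n must be a positive integer")
  n <- as.integer(n)
  if (!is.numeric(mean_degree) || length(mean_degree) != 1L ||
      is.na(mean_degree) || mean_degree < 0)
    stop("mean_degree must be a non-negative number")
  if (n == 1L) {
    if (mean_degree != 0) stop("for n = 1, mean_degree must be 0")
    return(graph_from_edges(matrix(integer(0), ncol = 2), n = 1L))
  }
  if (mean_degree > n - 1) stop("mean_degree must be <= n - 1")
  p <- mean_degree / (n - 1)
  e <- with_seed(rng_seed, cpp_er_edges(n, p))
  graph_from_edges(e + 1L, n = n)
}

# discrete power law P(k) proportional to k^-gamma on [k_min, k_max]
sample_powerlaw_degrees <- function(n, gamma, k_min, k_max) {
  if (k_min == k_max) return(rep.int(as.integer(k_min), n))
  ks <- k_min:k_max
  pr <- ks^(-gamma)
  sample(ks, n, replace = TRUE, prob = pr / sum(pr))
}

#' Power-law configuration-model graph
#'
#' Draws a degree sequence from `P(k) ~ k^-gamma` on `[k_min, k_max]`
#' (resampling one node until the stub count is even), matches stubs
#' uniformly at random, and deletes self-loops and multi-edges. The
#' fraction of discarded stubs is reported via a message and stored in
#' the `stubs_discarded` attribute; for gamma = 3 and large n the loss is
#' a vanishing fraction.
#'
#' @param n number of nodes.
#' @param gamma power-law exponent (> 1).
#' @param k_min,k_max degree bounds, `2 <= k_min <= k_max <= n - 1`.
#' @param rng_seed integer seed.
#' @param max_tries resampling attempts to reach an even stub count.
#' @return a `ctm_graph` (attribute `stubs_discarded`: fraction of stubs
#'   lost to self-loop/multi-edge deletion).
#' @export
generate_powerlaw_config <- function(n, gamma, k_min, k_max, rng_seed,
                                     max_tries = 100L) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  if (!(gamma > 1)) stop("gamma must be > 1")
  if (k_min < 2L || k_min > k_max) stop("need 2 <= k_min <= k_max")
  if (k_max > n - 1L) stop("k_max must be <= n - 1")
  with_seed(rng_seed, {
    deg <- sample_powerlaw_degrees(n, gamma, k_min, k_max)
    tries <- 0L
    while (sum(deg) %% 2L == 1L) {
      tries <- tries + 1L
      if (tries > max_tries) stop("could not build an even degree sequence")
      idx <- sample.int(n, 1L)
      deg[idx] <- sample_powerlaw_degrees(1L, gamma, k_min, k_max)
    }
    stubs <- rep.int(seq_len(n), deg)
    stubs <- stubs[sample.int(length(stubs))]
    e <- matrix(stubs, ncol = 2)
    keep <- e[, 1] != e[, 2]
    a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
    key <- (a - 1) * as.double(n) + b
    keep <- keep & !duplicated(key)
    lost <- 2 * sum(!keep) / length(stubs)
    if (sum(!keep) > 0)
      message(sprintf(
        "configuration model: removed %d self/multi-edge(s) (%.3f%% of stubs)",
        sum(!keep), 100 * lost))
    g <- graph_from_edges(cbind(a, b)[keep, , drop = FALSE], n = n)
    attr(g, "stubs_discarded") <- lost
    g
  })
}

#' Read / write plain-text edge lists
#'
#' Files hold one undirected edge per line as two whitespace-separated
#' integers; lines starting with `#` are comments. Node labels need not
#' be dense: they are re-indexed to `1..n` internally and the original
#' labels are kept in `node_names`, which `write_edge_list()` uses, so a
#' write/read round trip preserves the labeled edge set. Self-loops and
#' duplicate lines are dropped with a warning.
#'
#' @param path file path.
#' @return for `read_edge_list`, a `ctm_graph`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(graph_from_edges(matrix(integer(0), ncol = 2), n = 0L,
                            node_names = integer(0)))
  toks <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(toks) != 2L)) stop("each edge line must have two tokens")
  flat <- unlist(toks)
  if (!all(grepl("^[0-9]+$", flat)))
    stop("edge list tokens must be non-negative integers")
  vals <- as.integer(flat)
  a <- vals[c(TRUE, FALSE)]
  b <- vals[c(FALSE, TRUE)]
  labels <- sort(unique(c(a, b)))
  ia <- match(a, labels)
  ib <- match(b, labels)
  graph_from_edges(cbind(ia, ib), n = length(labels), node_names = labels)
}

#' @param g a `ctm_graph`.
#' @rdname read_edge_list
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "ctm_graph"))
  e <- g$edges
  lab <- g$node_names
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# undirected edge list: %d nodes, %d edges",
                     g$n, g$m_edges), con)
  if (nrow(e))
    writeLines(paste(lab[e[, 1]], lab[e[, 2]]), con)
  invisible(path)
}

#' Fractional-threshold assignment
#'
#' Gives every node the activation threshold `m_i = ceiling(t * k_i)`:
#' a node activates once a fraction `t` of its neighbors are active.
#' Isolated nodes get `m = 1`, so they can only ever activate as seeds.
#'
#' @param g a `ctm_graph`.
#' @param t threshold fraction in `(0, 1]`.
#' @return object of class `ctm_thresholds` with fields `t` and `m`.
#' @export
assign_thresholds <- function(g, t) {
  stopifnot(inherits(g, "ctm_graph"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0 || t > 1)
    stop("t must lie in (0, 1]")
  m <- as.integer(pmax(1, ceiling(t * g$deg)))
  structure(list(t = t, m = m), class = "ctm_thresholds")
}

#' Explicit integer thresholds
#'
#' @param g a `ctm_graph`.
#' @param m integer vector of per-node thresholds (all `>= 1`).
#' @return a `ctm_thresholds` (with `t = NA`).
#' @export
thresholds <- function(g, m) {
  stopifnot(inherits(g, "ctm_graph"))
  m <- as.integer(m)
  if (length(m) != g$n || anyNA(m) || any(m < 1L))
    stop("m must give every node a threshold >= 1")
  structure(list(t = NA_real_, m = m), class = "ctm_thresholds")
}

#' Convert to an igraph object
#'
#' Convenience bridge for cross-checking against igraph; requires the
#' igraph package.
#' @param g a `ctm_graph`.
#' @export
as_igraph <- function(g) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for as_igraph()")
  ig <- igraph::make_empty_graph(g$n, directed = FALSE)
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, as.vector(t(g$edges)))
  ig
}
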