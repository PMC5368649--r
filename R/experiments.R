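# method dispatch shared by the experiment drivers and the CLI
rank_for_method <- function(g, thr, method, budget, rng_seed, L = Inf,
                            max_path_events = 1e6) {
  switch(method,
    citm = select_seeds(g, thr, budget, L = L,
                        max_path_events = max_path_events),
    citmm = select_seeds(g, thr, budget, L = L, variant = "modified",
                         max_path_events = max_path_events),
    hd = rank_hd(g),
    hda = rank_hda(g, budget),
    ks = rank_kcore(g),
    ksa = rank_kcore_adaptive(g, budget),
    pr = rank_pagerank(g),
    random = rank_random(g, rng_seed),
    bc = rank_betweenness(g),
    cc = rank_closeness(g),
    greedy = rank_greedy(g, thr, budget),
    stop(sprintf("unknown ranking method '%s'", method))
  )
}

#' Experiment configuration
#'
#' Bundles everything a critical-point experiment needs so a run can be
#' reproduced bit-identically: graph model and parameters, threshold
#' fractions, methods, replicate count and the master seed (per-replicate
#' seeds are derived deterministically from it).
#'
#' @param model `"er"` or `"sf"`.
#' @param n network size.
#' @param mean_degree ER mean degree.
#' @param gamma,k_min,k_max scale-free (configuration model) parameters.
#' @param t_values threshold fractions to sweep.
#' @param methods ranking methods (see [rank_for_method()] names).
#' @param replicates graph realizations per cell.
#' @param random_orderings independent random seeding orders per graph
#'   (only used by the `"random"` method).
#' @param rng_seed master seed.
#' @param L path-length cutoff for CI-TM (`Inf` = unlimited).
#' @param budget_fraction fraction of nodes to rank for the adaptive
#'   selectors (the Q-jump must fall inside this prefix; 1 ranks all).
#' @return a list of class `ctm_config`.
#' @export
experiment_config <- function(model = "er", n = 1e5, mean_degree = 6,
                              gamma = 3, k_min = 2, k_max = 1000,
                              t_values = 0.5,
                              methods = c("citm", "hda", "hd", "random"),
                              replicates = 5, random_orderings = 10,
                              rng_seed = 1, L = Inf, budget_fraction = 1) {
  structure(as.list(environment()), class = "ctm_config")
}

# deterministic per-(replicate, stream) sub-seeds below 2^31
derive_seed <- function(master, rep, stream = 0L) {
  as.integer((as.double(master) * 7919 + rep * 104729 + stream * 1299709)
             %% 2147483647)
}

generate_from_config <- function(config, rep) {
  seed <- derive_seed(config$rng_seed, rep, 0L)
  if (config$model == "er") {
    generate_er(config$n, config$mean_degree, seed)
  } else if (config$model == "sf") {
    generate_powerlaw_config(config$n, config$gamma, config$k_min,
                             config$k_max, seed)
  } else stop("model must be 'er' or 'sf'")
}

#' Critical seed fractions across methods and thresholds
#'
#' For each replicate: generate a graph, assign fractional thresholds,
#' rank with each method, evaluate Q(q) along the ranking on the original
#' graph, and record the first-order critical fraction (largest
#' single-seed Q jump). Reports mean and sd per (method, t) cell.
#'
#' @param config an [experiment_config()].
#' @return data frame: `method`, `t`, `q_c_mean`, `q_c_sd`, `replicates`
#'   (number of q_c samples in the cell).
#' @export
critical_point_table <- function(config) {
  stopifnot(inherits(config, "ctm_config"))
  rows <- list()
  for (rep in seq_len(config$replicates)) {
    g <- generate_from_config(config, rep)
    budget <- as.integer(ceiling(config$budget_fraction * g$n))
    for (t in config$t_values) {
      thr <- assign_thresholds(g, t)
      for (method in config$methods) {
        n_ord <- if (method == "random") config$random_orderings else 1L
        for (ord in seq_len(n_ord)) {
          rk <- rank_for_method(g, thr, method, budget,
                                derive_seed(config$rng_seed, rep,
                                            100L + ord),
                                L = config$L)
          qc <- detect_qc(q_curve(g, thr, rk))
          rows[[length(rows) + 1L]] <-
            data.frame(method = method, t = t, rep = rep,
                       q_c = qc$q_c_first_order)
        }
      }
    }
  }
  raw <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(raw, list(raw$method, raw$t),
                                     drop = TRUE), function(d) {
    data.frame(method = d$method[1], t = d$t[1],
               q_c_mean = mean(d$q_c, na.rm = TRUE),
               q_c_sd = sd(d$q_c, na.rm = TRUE),
               replicates = sum(!is.na(d$q_c)))
  }))
  rownames(agg) <- NULL
  attr(agg, "raw") <- raw
  agg
}

#' Subcritical-path activation timeline
#'
#' Activates nodes sequentially in ranking order; at each ranked
#' activation records the number of subcritical paths attached to the
#' node, then auto-activates the nodes on those paths (so nodes already
#' triggered are skipped). Near the first-order transition the path
#' counts peak; larger `L` raises the peak.
#'
#' @param g a `ctm_graph`.
#' @param thr a `ctm_thresholds`.
#' @param ranking seeding order (vector or ranking object).
#' @param L path-length cutoff.
#' @param max_path_events per-node enumeration cap (capped counts are
#'   reported as `Inf`).
#' @return data frame: `step`, `node`, `q`, `score` (CI-TM value),
#'   `n_paths` (score minus residual degree), `n_activated` (cumulative
#'   activated incl. automatic activations; `NA` rows mark ranked nodes
#'   that were already active).
#' @export
path_timeline <- function(g, thr, ranking, L = Inf, max_path_events = 1e6) {
  check_thresholds(g, thr)
  if (is.data.frame(ranking)) ranking <- ranking$node
  ranking <- check_nodes(g, ranking, "ranking")
  res <- cpp_path_timeline(g$xadj, g$adj, thr$m, ranking - 1L, encode_L(L),
                           max_path_events, FALSE)
  data.frame(step = seq_along(ranking), node = ranking,
             q = seq_along(ranking) / g$n, score = res$score,
             n_paths = res$n_paths, n_activated = res$n_activated)
}

#' Histogram of activation times
#'
#' Tabulates the activation rounds of a cascade; bin 0 counts the seeds.
#'
#' @param g a `ctm_graph`.
#' @param thr a `ctm_thresholds`.
#' @param seeds seed nodes.
#' @return data frame with columns `time` (0..rounds) and `count`.
#' @export
activation_time_histogram <- function(g, thr, seeds) {
  res <- spread(g, thr, seeds)
  tt <- res$activation_time[res$activation_time >= 0L]
  times <- 0:max(0L, res$rounds)
  data.frame(time = times,
             count = vapply(times, function(r) sum(tt == r), integer(1)))
}

#' Top-k overlap of two rankings
#'
#' @param a,b rankings (vectors or ranking objects).
#' @param top_k prefix size, `1 <= top_k <= min(length(a), length(b))`.
#' @return `|top_k(a) intersect top_k(b)| / top_k`.
#' @export
ranking_overlap <- function(a, b, top_k) {
  if (is.data.frame(a)) a <- a$node
  if (is.data.frame(b)) b <- b$node
  if (length(top_k) != 1L || is.na(top_k) || top_k < 1 ||
      top_k > min(length(a), length(b)))
    stop("top_k must lie in 1..min(length(a), length(b))")
  length(intersect(a[seq_len(top_k)], b[seq_len(top_k)])) / top_k
}
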