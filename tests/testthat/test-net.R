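test_that("ER generator respects bounds and degenerate cases", {
  expect_error(generate_er(0, 3, 1), "positive")
  expect_error(generate_er(10, 10, 1), "<= n - 1")
  expect_error(generate_er(1, 2, 1), "mean_degree must be 0")

  # p = 1 forces the complete graph
  g <- generate_er(4, 3, 7)
  expect_equal(g$m_edges, 6L)
  expect_equal(g$deg, rep(3L, 4))
  expect_silent(validate_graph(g))
})

test_that("ER mean degree matches binomial sampling statistics", {
  n <- 2000
  g <- generate_er(n, 6, 11)
  validate_graph(g)
  # E ~ Binomial(n(n-1)/2, p): mean degree within 3 binomial standard errors
  p <- 6 / (n - 1)
  npairs <- n * (n - 1) / 2
  se_edges <- sqrt(npairs * p * (1 - p))
  expect_lt(abs(g$m_edges - npairs * p), 3 * se_edges)
  # reproducibility under the same seed, distinct graphs otherwise
  g2 <- generate_er(n, 6, 11)
  expect_identical(g$edges, g2$edges)
  g3 <- generate_er(n, 6, 12)
  expect_false(identical(g$edges, g3$edges))
})

test_that("ER edge counts concentrate over repeated seeds", {
  n <- 500
  p <- 6 / (n - 1)
  counts <- vapply(1:20, function(s) generate_er(n, 6, s)$m_edges, numeric(1))
  expect_lt(abs(mean(counts) - n * 6 / 2), 4 * sd(counts))
})

test_that("configuration model produces the requested power-law tail", {
  g <- suppressMessages(generate_powerlaw_config(5000, 3, 2, 1000, 5))
  validate_graph(g)
  expect_lt(attr(g, "stubs_discarded"), 0.02)
  # log-log regression of the degree histogram over k in [2, 50]
  tb <- table(g$deg)
  k <- as.numeric(names(tb))
  keep <- k >= 2 & k <= 50 & tb > 0
  fit <- lm(log(as.numeric(tb[keep])) ~ log(k[keep]))
  expect_lt(abs(coef(fit)[2] - (-3)), 0.3)
})

test_that("configuration model degenerate and invalid ranges", {
  # k_min = k_max = 2 gives a union of cycles (2-regular)
  g <- suppressMessages(generate_powerlaw_config(10, 3, 2, 2, 3))
  expect_true(all(g$deg <= 2))
  expect_equal(sum(g$deg) %% 2, 0)
  expect_error(generate_powerlaw_config(5, 3, 6, 10, 1), "n - 1")
  expect_error(generate_powerlaw_config(100, 0.5, 2, 10, 1), "gamma")
})

test_that("edge-list I/O round-trips and cleans input", {
  f <- withr::local_tempfile()
  writeLines(c("# comment", "0 1", "1 2"), f)
  g <- read_edge_list(f)
  expect_equal(g$n, 3L)
  expect_equal(g$m_edges, 2L)
  expect_equal(sort(g$deg), c(1L, 1L, 2L))

  # self-loops and duplicates dropped with warnings
  writeLines(c("2 2", "0 1", "1 0"), f)
  expect_warning(expect_warning(g2 <- read_edge_list(f), "self-loop"),
                 "duplicate")
  expect_equal(g2$m_edges, 1L)

  # labels with gaps are re-indexed but survive a round trip
  writeLines(c("10 20", "20 40"), f)
  g3 <- read_edge_list(f)
  expect_equal(g3$n, 3L)
  expect_equal(g3$node_names, c(10L, 20L, 40L))
  f2 <- withr::local_tempfile()
  write_edge_list(g3, f2)
  g4 <- read_edge_list(f2)
  expect_identical(g4$node_names[g4$edges], g3$node_names[g3$edges])

  writeLines(c("0 x"), f)
  expect_error(read_edge_list(f), "integer")
})

test_that("write/read round trip preserves random graphs", {
  for (s in 1:3) {
    g <- generate_er(60, 4, s)
    f <- withr::local_tempfile()
    write_edge_list(g, f)
    g2 <- read_edge_list(f)
    expect_equal(g2$m_edges, g$m_edges)
    key <- function(gg, lab) sort(paste(pmin(lab[gg$edges[, 1]],
                                             lab[gg$edges[, 2]]),
                                        pmax(lab[gg$edges[, 1]],
                                             lab[gg$edges[, 2]])))
    expect_identical(key(g2, g2$node_names), key(g, g$node_names))
  }
})

test_that("fractional thresholds use the ceiling rule", {
  g <- graph_from_edges(rbind(c(1, 2)), n = 3) # degrees 1, 1, 0
  expect_error(assign_thresholds(g, 0), "t must")
  expect_error(assign_thresholds(g, 1.2), "t must")
  expect_equal(assign_thresholds(g, 0.3)$m, c(1L, 1L, 1L)) # isolated -> 1

  gs <- star_graph(6) # hub degree 6
  expect_equal(assign_thresholds(gs, 0.5)$m[1], 3L)   # ceil(3)
  g5 <- star_graph(5)
  expect_equal(assign_thresholds(g5, 0.5)$m[1], 3L)   # ceil(2.5)
})

test_that("graph_from_edges validates and normalizes", {
  expect_warning(g <- graph_from_edges(rbind(c(1, 1), c(1, 2))), "self-loop")
  expect_equal(g$m_edges, 1L)
  expect_warning(g2 <- graph_from_edges(rbind(c(1, 2), c(2, 1))), "duplicate")
  expect_equal(g2$m_edges, 1L)
  expect_error(graph_from_edges(rbind(c(0, 1))), ">= 1")
  validate_graph(g2)
})
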