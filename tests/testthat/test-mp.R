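test_that("message fixed points match hand evaluation", {
  g <- path_graph(4)
  thr <- thresholds(g, rep(1L, 4))
  msg <- solve_messages(g, thr, integer(0))
  expect_equal(sum(msg$nu), 0L)
  expect_equal(msg$norm, 0)

  msg1 <- solve_messages(g, thr, 1)
  expect_equal(sum(msg1$nu), 3L)
  expect_equal(msg1$norm, 0.5)
  on_links <- data.frame(from = msg1$from, to = msg1$to)[msg1$nu == 1L, ]
  expect_setequal(paste(on_links$from, on_links$to), c("1 2", "2 3", "3 4"))

  # star: seeding the hub activates only hub -> leaf messages
  gs <- star_graph(4)
  ts <- thresholds(gs, rep(1L, 5))
  msgs <- solve_messages(gs, ts, 1)
  expect_equal(sum(msgs$nu), 4L)
  expect_true(all(msgs$from[msgs$nu == 1L] == 1L))
})

test_that("node states follow from the message fixed point", {
  g <- path_graph(4)
  thr <- thresholds(g, rep(1L, 4))
  msg0 <- solve_messages(g, thr, integer(0))
  expect_equal(node_states_from_messages(g, thr, integer(0), msg0),
               rep(0L, 4))
  msg1 <- solve_messages(g, thr, 1)
  expect_equal(node_states_from_messages(g, thr, 1, msg1), rep(1L, 4))
})

test_that("seeded nodes emit all messages (invariant)", {
  g <- generate_er(60, 4, 2)
  thr <- assign_thresholds(g, 0.5)
  seeds <- c(3, 17, 40)
  msg <- solve_messages(g, thr, seeds)
  expect_true(all(msg$nu[msg$from %in% seeds] == 1L))
  expect_gte(msg$norm, 0)
  expect_lte(msg$norm, 1)
})

test_that("combination formulation collapses to the counting condition", {
  # OR over all size-m combinations of incoming messages == (sum >= m),
  # enumerated exhaustively for every k <= 8, m <= k, message pattern
  for (k in 1:8) {
    for (m in 1:k) {
      combs <- combn(k, m)
      for (pattern in 0:(2^k - 1)) {
        nu <- as.integer(intToBits(pattern))[1:k]
        or_comb <- any(apply(combs, 2, function(cc) all(nu[cc] == 1L)))
        expect_identical(or_comb, sum(nu) >= m)
      }
    }
  }
})

test_that("tree exactness: messages, cascades and path counts agree", {
  for (s in 1:100) {
    n <- with_seed(s, sample(5:60, 1))
    g <- random_tree(n, seed = s * 13 + 1)
    thr <- random_thresholds(g, s * 17 + 3)
    seed_node <- with_seed(s * 19 + 5, sample.int(n, 1))
    msg <- solve_messages(g, thr, seed_node)
    # node states from messages equal the direct cascade
    expect_equal(node_states_from_messages(g, thr, seed_node, msg),
                 spread(g, thr, seed_node)$state)
    # |nu| equals the unlimited-depth subcritical path score of the seed
    pc <- count_subcritical_paths(g, thr, seed_node, L = Inf)
    expect_equal(sum(msg$nu), pc$score)
    expect_equal(linear_norm_approx(g, thr, seed_node), msg$norm)
  }
})

test_that("bhat matches the worked link-operator example", {
  # center i with neighbors k1 (active), k2, k3, j; m_i = 2
  g <- star_graph(4)
  thr <- thresholds(g, c(2L, rep(1L, 4)))
  active <- 2L # k1
  expect_equal(bhat(g, thr, active, k = 2, i = 1, j = 5), 0L)
  expect_equal(bhat(g, thr, active, k = 3, i = 1, j = 5), 1L)
  expect_equal(bhat(g, thr, active, k = 4, i = 1, j = 5), 1L)
  # non-backtracking: k == j always 0
  expect_equal(bhat(g, thr, active, k = 5, i = 1, j = 5), 0L)
  expect_error(bhat(g, thr, active, k = 2, i = 3, j = 5), "adjacent")
})

test_that("bhat reduces to the non-backtracking pattern for m = k - 1", {
  g <- complete_graph(4)
  thr <- thresholds(g, rep(2L, 4)) # m_i = k_i - 1
  # with all other neighbors active, bhat(k, i, j) = 1 iff k != j
  for (i in 1:4) {
    nb <- neighbors_of(g, i)
    for (k in nb) for (j in nb) {
      active <- setdiff(nb, c(k, j))
      expect_equal(bhat(g, thr, active, k, i, j),
                   as.integer(k != j))
    }
  }
})

test_that("norm comparison: exact on trees, approx rarely above exact", {
  g <- random_tree(80, 4)
  thr <- random_thresholds(g, 5)
  cmp <- norm_comparison(g, thr)
  expect_equal(cmp$r_linear, 1.0, tolerance = 1e-12)
  expect_equal(cmp$pairs$true_norm, cmp$pairs$approx_norm, tolerance = 1e-12)

  # loopy graph: approximation statistically below the exact norm
  ge <- generate_er(400, 4, 6)
  thr_e <- assign_thresholds(ge, 0.5)
  cmp_e <- norm_comparison(ge, thr_e)
  expect_gte(mean(cmp_e$pairs$approx_norm <=
                  cmp_e$pairs$true_norm + 1e-12), 0.9)
  # determinism
  cmp_e2 <- norm_comparison(ge, thr_e)
  expect_identical(cmp_e$pairs, cmp_e2$pairs)
})
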