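test_that("path counts reproduce the worked 3/5/7 example", {
  fx <- fig1e_fixture()
  for (L in list(0, 1, 2, Inf)) {
    pc <- count_subcritical_paths(fx$g, fx$thr, fx$i, L = L)
    expected <- c(`0` = 3, `1` = 5, `2` = 7, `Inf` = 7)[[as.character(L)]]
    expect_equal(pc$score, expected)
  }
  pc2 <- count_subcritical_paths(fx$g, fx$thr, fx$i, L = 2)
  expect_equal(pc2$counts, c(2, 2))
  expect_setequal(pc2$reached, c(2L, 5L, 6L))
})

test_that("path counts on chains and degenerate nodes", {
  g <- path_graph(4)
  thr <- thresholds(g, rep(1L, 4))
  pc <- count_subcritical_paths(g, thr, 1, L = Inf)
  expect_equal(pc$score, 3) # degree 1 + paths 1->2->3 and 1->2->3->4
  expect_equal(pc$counts, c(1, 1, 0))

  gi <- graph_from_edges(rbind(c(1, 2)), n = 3)
  ti <- thresholds(gi, rep(1L, 3))
  expect_equal(count_subcritical_paths(gi, ti, 3)$score, 0) # isolated
  expect_error(count_subcritical_paths(g, selection_state(g, thr), 9),
               "node ids")
})

test_that("score_all: L = 0 is residual degree; scores grow with L", {
  for (s in 1:4) {
    g <- generate_er(100, 5, s)
    thr <- assign_thresholds(g, 0.4)
    expect_equal(score_all(g, thr, L = 0), as.numeric(g$deg))
    prev <- score_all(g, thr, L = 0)
    for (L in c(1, 2, 4, Inf)) {
      cur <- score_all(g, thr, L = L)
      expect_true(all(cur >= prev - 1e-9))
      prev <- cur
    }
  }
  # symmetric nodes score equally
  gc <- cycle_graph(6)
  tc <- thresholds(gc, rep(1L, 6))
  expect_equal(length(unique(score_all(gc, tc, L = Inf))), 1L)
})

test_that("collapse decrements per removed neighbor and closes", {
  # leaf adjacent to v with residual (k = 4, m = 2): removing the leaf
  # makes v subcritical (3, 1)
  g <- star_graph(4)
  thr <- thresholds(g, c(2L, rep(2L, 4)))
  st <- selection_state(g, thr)
  st2 <- collapse(g, st, 2) # a leaf; no subcritical reach
  expect_equal(st2$alive[2], 0L)
  expect_equal(st2$rdeg[1], 3L)
  expect_equal(st2$rm[1], 1L)

  # closure: v with residual m = 1 adjacent to two removed nodes collapses
  gp <- path_graph(3)
  tp <- thresholds(gp, c(1L, 2L, 1L))
  stp <- selection_state(gp, tp)
  stp2 <- collapse(gp, stp, 1) # removes 1; node 2 becomes (1,1) subcritical
  expect_equal(stp2$alive, c(0L, 1L, 1L))
  stp3 <- collapse(gp, stp2, 3, L = 0) # second neighbor of 2 removed
  expect_equal(stp3$alive[2], 0L) # closed: rm hit 0
  expect_true(all(stp3$rm >= 0L))

  # collapsing an isolated node changes nothing else
  gi <- graph_from_edges(rbind(c(1, 2)), n = 3)
  ti <- thresholds(gi, rep(1L, 3))
  sti <- collapse(gi, selection_state(gi, ti), 3)
  expect_equal(sti$rdeg[1:2], c(1L, 1L))
})

test_that("collapse removes the attached subcritical cluster", {
  fx <- fig1e_fixture()
  st <- collapse(fx$g, selection_state(fx$g, fx$thr), fx$i)
  # i, u, x, y removed; terminals x', y' had m = 2 and lost one neighbor
  expect_equal(st$alive, c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L))
  expect_equal(st$rm[7], 1L)
  expect_setequal(st$removed, c(1L, 2L, 5L, 6L))
})

test_that("selection is deterministic and obeys the budget contract", {
  g <- generate_er(200, 5, 8)
  thr <- assign_thresholds(g, 0.5)
  s1 <- select_seeds(g, thr, 30)
  s2 <- select_seeds(g, thr, 30)
  expect_identical(s1, s2)
  # selection may stop before the budget once every node is removed (all
  # remaining nodes are then guaranteed active)
  expect_lte(nrow(s1), 30L)
  expect_gt(nrow(s1), 0L)
  expect_false(anyDuplicated(s1$node) > 0)
  if (nrow(s1) < 30L) # stopped early: chosen seeds must activate everyone
    expect_equal(spread(g, thr, s1$node)$n_active, g$n)
  expect_error(select_seeds(g, thr, g$n + 1), "budget")
  expect_equal(nrow(select_seeds(g, thr, 0)), 0L)
})

test_that("L = 0 selection equals degree-greedy with the same collapse", {
  for (s in 1:4) {
    g <- generate_er(80, 4, s + 40)
    thr <- assign_thresholds(g, 0.5)
    got <- select_seeds(g, thr, 25, L = 0)$node
    ref <- degree_greedy_collapse_oracle(g, thr, 25)
    expect_identical(got, ref[seq_along(got)])
  }
})

test_that("hub selection on a star triggers the full cascade", {
  g <- star_graph(8)
  thr <- assign_thresholds(g, 0.5) # hub m = 4, leaves m = 1
  sel <- select_seeds(g, thr, 1, L = Inf)
  expect_equal(sel$node, 1L)
  expect_equal(spread(g, thr, sel$node)$n_active, 9L)
})

test_that("tree consistency: score at selection equals activated links", {
  # on a tree, CI-TM_inf of the first selected seed must equal the number
  # of directed links carrying active messages when seeding it
  for (s in 1:10) {
    g <- random_tree(60, seed = s + 200)
    thr <- random_thresholds(g, s + 300)
    sel <- select_seeds(g, thr, 1, L = Inf)
    msg <- solve_messages(g, thr, sel$node[1])
    expect_equal(sel$score[1], sum(msg$nu))
    # and no other node does better
    all_counts <- vapply(seq_len(g$n), function(v)
      sum(solve_messages(g, thr, v)$nu), numeric(1))
    expect_equal(sel$score[1], max(all_counts))
  }
})

test_that("greedy seed counts are near the exhaustive optimum", {
  for (s in 1:6) {
    g <- generate_er(10, 3, s + 70)
    thr <- random_thresholds(g, s + 80)
    opt <- min_seeds_bruteforce(g, thr)
    rk <- select_seeds(g, thr, g$n, L = Inf)
    # ranking may stop early once everything is removed; extend with the
    # leftover nodes in id order for evaluation
    full <- c(rk$node, setdiff(seq_len(g$n), rk$node))
    got <- min_seeds_from_ranking(g, thr, full)
    expect_gte(got, opt)       # greedy can never beat the optimum
    expect_lte(got, opt + 2)
  }
})

test_that("modified variant ignores vulnerable vertices in paths", {
  # peripheral hub: center c with 5 leaf chains (vulnerable), versus a
  # clique-attached node with non-vulnerable subcritical structure
  fx <- fig1e_fixture()
  pc_std <- count_subcritical_paths(fx$g, fx$thr, fx$i, variant = "standard")
  pc_mod <- count_subcritical_paths(fx$g, fx$thr, fx$i, variant = "modified")
  # u, x, y all have original m = 1: no paths survive in the modified count
  expect_equal(pc_mod$score, 3)
  expect_gt(pc_std$score, pc_mod$score)
  expect_length(pc_mod$reached, 0)

  # but nodes that became subcritical only through collapse still count
  g <- path_graph(3)
  thr <- thresholds(g, c(1L, 2L, 1L))
  st <- collapse(g, selection_state(g, thr), 1)
  pc <- count_subcritical_paths(g, st, 3, variant = "modified")
  expect_equal(pc$score, 1 + 0) # node 2: rm = 1, orig m = 2 -> traversed
  expect_equal(pc$reached, 2L)
})

test_that("saturation cap ranks capped nodes first but keeps C exact", {
  g <- cycle_graph(12)
  thr <- thresholds(g, rep(1L, 12))
  pc <- count_subcritical_paths(g, thr, 1, L = Inf, max_path_events = 3)
  expect_true(pc$saturated)
  expect_setequal(pc$reached, 2:12) # BFS reach unaffected by the cap
  sel <- select_seeds(g, thr, 1, max_path_events = 3)
  expect_equal(sel$node, 1L) # all saturate; smallest id wins
})

test_that("effectiveness ordering: CI-TM beats HDA beats Random", {
  qc <- function(g, thr, rk) detect_qc(q_curve(g, thr, rk))$q_c_first_order
  res <- t(vapply(1:10, function(r) {
    g <- generate_er(1e4, 6, 600 + r)
    thr <- assign_thresholds(g, 0.5)
    c(citm = qc(g, thr, select_seeds(g, thr, g$n)),
      hda = qc(g, thr, rank_hda(g)),
      random = qc(g, thr, rank_random(g, 700 + r)))
  }, numeric(3)))
  gap1 <- mean(res[, "hda"] - res[, "citm"])
  gap2 <- mean(res[, "random"] - res[, "hda"])
  expect_gt(gap1, 3 * sd(res[, "hda"] - res[, "citm"]) / sqrt(nrow(res)))
  expect_gt(gap2, 3 * sd(res[, "random"] - res[, "hda"]) / sqrt(nrow(res)))
})
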