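test_that("state score rewards stock coverage and shortness", {
  tgt <- parse_target("CC(=O)O")$mol          # already purchasable
  r0 <- route_from_steps(tgt, list(), demo_stock())
  expect_equal(state_score(r0), 1.0)
  # solved one-step route scores below 1 but above an unsolved one
  r1 <- demo_route()
  expect_true(is_solved(r1))
  expect_lt(state_score(r1), 1.0)
  poor <- route_from_steps(demo_target()$mol,
                           template_policy(demo_target()$mol,
                                           demo_library())[1],
                           stock("CC(=O)O"))   # amine missing from stock
  expect_lt(state_score(poor), state_score(r1))
  # longer solved routes score lower (direct formula evaluation)
  g <- length_squash(0:6)
  expect_true(all(diff(g) < 0))
  expect_equal(g[1], 1.0)
})

test_that("broken bonds score hits its endpoints exactly", {
  B <- c("1-2", "3-4", "5-6")
  all_first <- stats::setNames(c(0L, 0L, 0L), B)
  expect_identical(broken_bonds_score(all_first, B, d_max = 6), 1)
  none <- stats::setNames(integer(0), character(0))
  expect_identical(broken_bonds_score(none, B, d_max = 6), 0)
  # unrelated bonds broken deep in the tree do not rescue the score
  off <- stats::setNames(c(2L), "7-8")
  expect_identical(broken_bonds_score(off, B, d_max = 6), 0)
  expect_error(broken_bonds_score(all_first, character(0)), "empty")
})

test_that("broken bonds score reproduces the published worked examples", {
  # three prompted bonds, D_max = 24 (the worked-example configuration)
  B <- c("1-2", "3-4", "5-6")
  t1 <- stats::setNames(c(0L, 1L), B[1:2])           # 2 of 3, shallow
  t2 <- stats::setNames(c(2L, 4L, 4L), B)            # all 3, deeper
  t3 <- stats::setNames(c(1L, 2L, 3L), B)            # all 3, linear
  expect_equal(round(broken_bonds_score(t1, B, 24), 2), 0.65)
  expect_equal(round(broken_bonds_score(t2, B, 24), 2), 0.86)
  expect_equal(round(broken_bonds_score(t3, B, 24), 2), 0.92)
  # exact values behind the rounded figures
  expect_equal(broken_bonds_score(t1, B, 24), 47 / 72)
  expect_equal(broken_bonds_score(t2, B, 24), 31 / 36)
  expect_equal(broken_bonds_score(t3, B, 24), 11 / 12)
})

test_that("earlier breaking strictly increases the score", {
  B <- c("1-2", "3-4")
  for (d in 1:5) {
    deep <- stats::setNames(c(0L, d), B)
    shallow <- stats::setNames(c(0L, d - 1L), B)
    expect_gt(broken_bonds_score(shallow, B, 6),
              broken_bonds_score(deep, B, 6))
  }
})

test_that("completing the break set never decreases the score", {
  # moving from k-1 broken to all k broken at any depth adds a credit
  # while the productive-component count stays the same
  B <- c("1-2", "3-4", "5-6")
  for (d in 0:5) {
    partial <- stats::setNames(c(0L, 1L), B[1:2])
    full <- stats::setNames(c(0L, 1L, d), B)
    expect_gte(broken_bonds_score(full, B, 6),
               broken_bonds_score(partial, B, 6))
  }
  # an extra bond broken in the first reaction never hurts either
  for (k in 1:2) {
    some <- stats::setNames(rep(2L, k), B[seq_len(k)])
    more <- stats::setNames(c(rep(2L, k), 0L), B[seq_len(k + 1L)])
    expect_gte(broken_bonds_score(more, B, 6),
               broken_bonds_score(some, B, 6))
  }
})

test_that("scores stay inside [0, 1] over generated routes", {
  fx <- small_fixture()
  cfg <- search_config(iteration_limit = 30, seed = 5)
  for (tg in fx$targets[1:3]) {
    sr <- mcts_search(tg$target, tg$constraints, fx$library, fx$stock, cfg)
    for (r in extract_routes(sr, "standard", 5)) {
      sc <- score_route(r, tg$constraints)$scores
      expect_true(sc$state >= 0 && sc$state <= 1)
      expect_true(sc$broken_bonds >= 0 && sc$broken_bonds <= 1)
      expect_equal(sc$combined,
                   0.5 * sc$state + 0.5 * sc$broken_bonds)
    }
  }
})

test_that("rank_routes orders by the requested score", {
  fx <- small_fixture()
  tg <- fx$targets[[1]]
  cfg <- search_config(iteration_limit = 40, seed = 5)
  sr <- mcts_search(tg$target, tg$constraints, fx$library, fx$stock, cfg)
  routes <- lapply(extract_routes(sr, "standard", 10), score_route,
                   constraints = tg$constraints)
  expect_gte(length(routes), 2L)
  st <- vapply(rank_routes(routes, "standard"),
               function(r) r$scores$state, 0)
  expect_true(all(diff(st) <= 0))
  cmb <- vapply(rank_routes(routes, "route_ranking"),
                function(r) r$scores$combined, 0)
  expect_true(all(diff(cmb) <= 0))
  # mo ordering equals the pareto_fronts rank order
  mo <- rank_routes(routes, "mo")
  m <- cbind(vapply(mo, function(r) r$scores$state, 0),
             vapply(mo, function(r) r$scores$broken_bonds, 0))
  rk <- pareto_rank_oracle(m)
  expect_true(all(diff(rk) >= 0))
})
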