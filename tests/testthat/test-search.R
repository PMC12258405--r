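test_that("pareto_fronts agrees with the brute-force dominance oracle", {
  set.seed(99)
  for (rep in 1:6) {
    d <- sample(2:3, 1)
    n <- sample(20:60, 1)
    m <- matrix(stats::runif(n * d), ncol = d)
    if (rep %% 2 == 0)                       # inject exact ties
      m[sample(n, 5), ] <- m[sample(n, 5), ]
    fronts <- pareto_fronts(m)
    rank <- integer(n)
    for (f in fronts) rank[f$indices] <- f$rank
    expect_identical(rank, pareto_rank_oracle(m))
  }
  # hand-checked example
  pts <- rbind(c(0.9, 0.2), c(0.6, 0.5), c(0.5, 0.4), c(0.4, 0.9))
  fr <- pareto_fronts(pts)
  expect_identical(fr[[1]]$indices, c(1L, 2L, 4L))
  expect_identical(fr[[2]]$indices, 3L)
  # identical points share rank 1
  same <- rbind(c(1, 1), c(1, 1), c(1, 1))
  expect_length(pareto_fronts(same), 1L)
  expect_length(pareto_fronts(matrix(numeric(0), ncol = 2)), 0L)
})

test_that("a target already in stock is solved with an empty route", {
  lib <- demo_library()
  stk <- demo_stock()
  tgt <- parse_target("CC(=O)O")$mol
  sr <- mcts_search(tgt, constraint_set(), lib, stk)
  expect_true(search_solved(sr))
  routes <- extract_routes(sr, "standard", 5)
  expect_length(routes, 1L)
  expect_identical(route_length(routes[[1]]), 0L)
  expect_equal(routes[[1]]$scores$state, 1.0)
})

test_that("a depth-1 target with stocked reactants is solved quickly", {
  # oracle: exhaustive depth-1 enumeration of template applications finds
  # exactly one solved disconnection; the search must find it too
  tgt <- demo_target()
  lib <- demo_library()
  stk <- demo_stock()
  enum <- Filter(function(s)
    all(vapply(s$reactants, in_stock, logical(1), stk = stk)),
    template_policy(tgt$mol, lib))
  expect_length(enum, 1L)
  cfg <- search_config(iteration_limit = 10, seed = 2)
  sr <- mcts_search(tgt$mol, tgt$constraints, lib, stk, cfg)
  expect_true(search_solved(sr))
  top <- extract_routes(sr, "standard", 1)[[1]]
  expect_true(is_solved(top))
  expect_identical(route_length(top), 1L)
  expect_identical(names(route_broken_depths(top)), "1-3")
})

test_that("freezing the only disconnectable bond leaves the target
           unsolved", {
  tgt <- parse_target("[CH3:10][C:1](=[O:2])[NH:3][CH3:11]",
                      freeze_pairs = list(c(1, 3)))
  lib <- list(amide_template())
  class(lib) <- "rp_template_library"
  sr <- mcts_search(tgt$mol, tgt$constraints, lib, demo_stock(),
                    search_config(iteration_limit = 10, seed = 2))
  expect_false(search_solved(sr))
  routes <- extract_routes(sr, "standard", 5)
  expect_length(routes, 1L)      # only the bare root state
  expect_false(is_solved(routes[[1]]))
})

test_that("mo search degenerates to single-objective behavior on one
           axis and keeps breaking routes on the front", {
  fx <- hidden_fixture()
  tg <- fx$targets[[1]]
  cfg <- search_config(iteration_limit = 40, seed = 7)
  mo <- mo_mcts_search(tg$target, tg$constraints, fx$library, fx$stock,
                       cfg)
  front <- extract_routes(mo, "mo_front", 5)
  bb <- vapply(front, function(r) r$scores$broken_bonds, 0)
  # the planted prompted bond is breakable: a breaking route must sit on
  # the extracted front even though a shorter non-breaking route exists
  expect_true(any(bb > 0))
  sat <- vapply(front, satisfies_constraints, logical(1),
                constraints = tg$constraints)
  expect_true(any(sat))
  # a one-objective config behaves like mcts_search on that objective
  cfg1 <- search_config(iteration_limit = 20, seed = 3)
  s1 <- mcts_search(tg$target, tg$constraints, fx$library, fx$stock, cfg1)
  cfg1b <- cfg1; cfg1b$objectives <- "state"
  s2 <- retroprompt:::.run_search(tg$target, tg$constraints, fx$library,
                                  fx$stock, cfg1b, "standard")
  expect_identical(
    vapply(extract_routes(s1, "standard", 5), route_length, 0L),
    vapply(extract_routes(s2, "standard", 5), route_length, 0L))
})

test_that("searches are reproducible under a fixed seed", {
  fx <- small_fixture()
  tg <- fx$targets[[2]]
  cfg <- search_config(iteration_limit = 30, seed = 11)
  r1 <- extract_routes(mo_mcts_search(tg$target, tg$constraints,
                                      fx$library, fx$stock, cfg),
                       "mo_front", 5)
  r2 <- extract_routes(mo_mcts_search(tg$target, tg$constraints,
                                      fx$library, fx$stock, cfg),
                       "mo_front", 5)
  expect_identical(lapply(r1, retroprompt:::route_key),
                   lapply(r2, retroprompt:::route_key))
  expect_identical(lapply(r1, function(r) r$scores),
                   lapply(r2, function(r) r$scores))
})

test_that("routes respect max_depth and solved means all leaves stocked", {
  fx <- small_fixture()
  cfg <- search_config(max_depth = 3, iteration_limit = 40, seed = 4)
  for (tg in fx$targets[1:3]) {
    sr <- mcts_search(tg$target, tg$constraints, fx$library, fx$stock, cfg)
    for (r in extract_routes(sr, "standard", 10)) {
      rx <- route_reactions(r)
      if (length(rx))
        expect_lte(max(vapply(rx, function(x) x$depth, 0L)),
                   cfg$max_depth - 1L)
      leaves_ok <- vapply(route_leaves(r), function(l)
        isTRUE(l$in_stock), logical(1))
      expect_identical(is_solved(r), all(leaves_ok))
    }
  }
})

test_that("more search budget never hurts the best extracted state score
           on average over seeds", {
  fx <- small_fixture()
  tg <- fx$targets[[4]]
  best_state <- function(iters, seed) {
    sr <- mcts_search(tg$target, tg$constraints, fx$library, fx$stock,
                      search_config(iteration_limit = iters, seed = seed))
    max(vapply(extract_routes(sr, "standard", 10),
               function(r) r$scores$state, 0))
  }
  seeds <- 1:4
  lo <- mean(vapply(seeds, best_state, 0, iters = 5))
  hi <- mean(vapply(seeds, best_state, 0, iters = 50))
  expect_gte(hi, lo - 1e-9)
})
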