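test_that("route JSON serialization round-trips losslessly", {
  r <- demo_route()
  r$metadata$strategy <- "standard"
  js <- route_to_json(r)
  r2 <- route_from_json(js)
  expect_identical(retroprompt:::route_key(r2), retroprompt:::route_key(r))
  expect_identical(r2$metadata$strategy, "standard")
  expect_identical(route_to_json(r2), js)
  # unknown extra keys survive (forward compatibility)
  obj <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  obj$tree$vendor_note <- "keep me"
  obj$tree$children[[1]]$yield <- 0.83
  r3 <- route_from_json(jsonlite::toJSON(obj, auto_unbox = TRUE))
  expect_identical(r3$tree$vendor_note, "keep me")
  back <- jsonlite::fromJSON(route_to_json(r3), simplifyVector = FALSE)
  expect_identical(back$tree$vendor_note, "keep me")
  expect_equal(back$tree$children[[1]]$yield, 0.83)
})

test_that("hand-written depth-1 route fixtures deserialize to the
           expected shape and schema errors carry a path", {
  js <- paste0('{"tree":{"type":"mol","smiles":"[CH3:1][OH:2]",',
               '"in_stock":false,"children":[{"type":"reaction",',
               '"broken":[[1,2]],"children":[{"type":"mol",',
               '"smiles":"[CH4:1]","in_stock":true,"children":[]},',
               '{"type":"mol","smiles":"[OH2:2]","in_stock":true,',
               '"children":[]}]}]},"scores":{},"metadata":{}}')
  r <- route_from_json(js)
  expect_identical(route_length(r), 1L)
  expect_true(is_solved(r))
  expect_identical(names(route_broken_depths(r)), "1-2")
  expect_error(route_from_json('{"tree":{"type":"mol","children":[]}}'),
               "smiles")
  expect_error(route_from_json(
    '{"tree":{"type":"banana","smiles":"C"}}'), "type")
})

test_that("satisfies_constraints quantifies over break and freeze sets", {
  fx <- small_fixture()
  tg <- fx$targets[[1]]
  rr <- tg$reference_route
  expect_true(satisfies_constraints(rr, constraint_set()))
  expect_true(satisfies_constraints(rr, tg$constraints))
  # an unbroken extra bond fails the universal quantifier
  aug <- constraint_set(c(tg$constraints$`break`, "997-998"))
  expect_false(satisfies_constraints(rr, aug))
  # breaking a frozen bond fails even with all break bonds covered
  broken <- names(route_broken_depths(rr))
  other <- setdiff(broken, tg$constraints$`break`)
  if (length(other)) {
    bad <- constraint_set(tg$constraints$`break`, other[1])
    expect_false(satisfies_constraints(rr, bad))
  }
  # monotone: satisfying a union implies satisfying each part
  expect_true(satisfies_constraints(
    rr, constraint_set(tg$constraints$`break`[1])))
})

test_that("route similarity is symmetric, bounded, and bond-similarity of
           a route with itself is one", {
  fx <- small_fixture()
  cfg <- search_config(iteration_limit = 40, seed = 9)
  tg <- fx$targets[[1]]
  sr <- mcts_search(tg$target, tg$constraints, fx$library, fx$stock, cfg)
  routes <- extract_routes(sr, "standard", 4)
  expect_gte(length(routes), 2L)
  for (i in seq_along(routes)) for (j in seq_along(routes)) {
    s <- route_similarity(routes[[i]], routes[[j]])
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, route_similarity(routes[[j]], routes[[i]]))
  }
  # self-similarity quirk: bond part is 1, atom part < 1 for multi-step
  # routes because intermediates pad the normalization
  multi <- Filter(function(r) route_length(r) >= 2, routes)
  for (r in multi) {
    s_self <- route_similarity(r, r)
    expect_lt(s_self, 1)
    expect_gte(s_self, 0.5)     # bond component contributes exactly 1/2
  }
  # incomparable targets
  expect_error(route_similarity(routes[[1]], demo_route()),
               "incomparable")
})

test_that("gamma and kappa match hand-computed tables", {
  fx <- small_fixture()
  cfg <- search_config(iteration_limit = 40, seed = 9)
  tg <- fx$targets[[1]]
  sr <- mcts_search(tg$target, tg$constraints, fx$library, fx$stock, cfg)
  routes <- extract_routes(sr, "standard", 3)
  expect_gte(length(routes), 2L)
  S <- outer(seq_along(routes), seq_along(routes),
             Vectorize(function(i, j)
               route_similarity(routes[[i]], routes[[j]])))
  # gamma against a 2-route reference: max-then-mean by hand
  ref <- routes[1:2]
  g_hand <- 1 - mean(apply(S[, 1:2, drop = FALSE], 1, max))
  expect_equal(dissimilarity_to_reference(routes, ref), g_hand)
  # kappa: min over others, then mean
  k_hand <- 1 - mean(vapply(seq_along(routes), function(i)
    min(S[i, -i]), 0))
  expect_equal(route_diversity(routes), k_hand)
  # order invariance
  perm <- rev(seq_along(routes))
  expect_equal(route_diversity(routes[perm]), route_diversity(routes))
  expect_equal(dissimilarity_to_reference(routes[perm], rev(ref)),
               dissimilarity_to_reference(routes, ref))
  # self-reference gamma is near zero but governed by the quirk
  g_self <- dissimilarity_to_reference(routes, routes)
  expect_gte(g_self, 0); expect_lt(g_self, 0.3)
  # duplicated identical routes floor the diversity
  dup <- c(routes[1], routes[1])
  expect_equal(route_diversity(dup),
               1 - route_similarity(routes[[1]], routes[[1]]))
  expect_error(route_diversity(routes[1]), "two routes")
  expect_error(dissimilarity_to_reference(list(), routes), "non-empty")
})

test_that("disjoint disconnection sets zero the bond component", {
  mk <- function(broken_pairs, leaf_maps) {
    leaves <- lapply(leaf_maps, function(ms) list(
      type = "mol",
      smiles = canonical_smiles(parse_smiles(paste0(
        "[CH3:", ms[1], "][CH3:", ms[2], "]"))),
      in_stock = TRUE, children = list()))
    structure(list(tree = list(
      type = "mol", smiles = "[CH3:1][CH2:2][CH2:3][CH3:4]",
      in_stock = FALSE,
      children = list(list(type = "reaction", broken = broken_pairs,
                           children = leaves))),
      scores = list(), metadata = list()), class = "rp_route")
  }
  r1 <- mk("1-2", list(c(1, 9), c(2, 3)))
  r2 <- mk("3-4", list(c(1, 2), c(3, 9)))
  # bond similarity 0; atom overlap partial => strictly below 1/2
  expect_lt(route_similarity(r1, r2), 0.5)
  same <- route_similarity(r1, r1)
  disj <- route_similarity(r1, r2)
  expect_gt(same, disj)
})
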