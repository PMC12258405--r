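test_that("fixture generation is deterministic and plants solved,
           constraint-consistent reference routes", {
  fx <- generate_fixture(4, depth_range = 1:2, seed = 77)
  fx2 <- generate_fixture(4, depth_range = 1:2, seed = 77)
  expect_identical(
    vapply(fx$targets, function(t) canonical_smiles(t$target), ""),
    vapply(fx2$targets, function(t) canonical_smiles(t$target), ""))
  expect_identical(
    lapply(fx$targets, function(t) t$constraints),
    lapply(fx2$targets, function(t) t$constraints))
  for (tg in fx$targets) {
    expect_true(is_solved(tg$reference_route))
    expect_true(satisfies_constraints(tg$reference_route, tg$constraints))
    # replayed leaves are purchasable (oracle: walk the tree vs stock)
    for (l in retroprompt:::route_mol_nodes(tg$reference_route)) {
      if (!length(l$children))
        expect_true(in_stock(parse_smiles(l$smiles), fx$stock))
    }
  }
  # a single depth-1 target: one reaction, both reactants in stock
  f1 <- generate_fixture(1, depth_range = 1, seed = 5)
  expect_identical(route_length(f1$targets[[1]]$reference_route), 1L)
})

test_that("convergent disconnection score prefers balanced splits", {
  expect_equal(convergent_disconnection_score(c(10, 10)), 1.0)
  expect_lt(convergent_disconnection_score(c(18, 2)),
            convergent_disconnection_score(c(10, 10)))
  # monotone in imbalance
  vals <- vapply(0:8, function(d)
    convergent_disconnection_score(c(10 + d, 10 - d)), 0)
  expect_true(all(diff(vals) < 0))
  # three-way split via the documented generalization
  expect_equal(convergent_disconnection_score(c(6, 6, 6)), 1.0)
  expect_equal(convergent_disconnection_score(c(9, 6, 3)), 1 - 6 / 18)
  # single reactant scores minimal
  expect_equal(convergent_disconnection_score(c(12)), 0)
  # on an rp_step
  tgt <- demo_target()
  st <- template_policy(tgt$mol, demo_library())[[1]]
  expect_equal(convergent_disconnection_score(st),
               1 - abs(4 - 2) / 6)
})

test_that("extract_constraints picks the convergent reaction and frozen
           bonds the reference route never touches", {
  fx <- cached_fixture("deep", function()
    generate_fixture(3, depth_range = 3, seed = 123))
  for (tg in fx$targets) {
    rr <- tg$reference_route
    set.seed(1)
    cs <- extract_constraints(rr, n_break = 2, n_freeze = 1)
    expect_true(satisfies_constraints(rr, cs))
    # oracle: score all reactions, argmax CDS must supply the first bond
    cds <- retroprompt:::.route_cds(rr)
    rxs <- route_reactions(rr)
    best <- which.max(cds + 1e-9 * (-vapply(rxs, function(x) x$depth, 0L)))
    expect_true(any(rxs[[best]]$node$broken %in% cs$`break`))
    # frozen bonds exist in the target and are never broken en route
    tgt <- parse_smiles(rr$tree$smiles)
    expect_true(all(cs$freeze %in% mapped_bonds(tgt)))
    expect_length(intersect(cs$freeze,
                            names(route_broken_depths(rr))), 0L)
  }
  expect_error(extract_constraints(fx$targets[[1]]$reference_route,
                                   n_break = 1, n_freeze = 1))
})

test_that("depth-1 routes yield their single broken bond as the
           constraint", {
  f1 <- generate_fixture(1, depth_range = 1, seed = 5)
  rr <- f1$targets[[1]]$reference_route
  cs <- extract_constraints(rr, n_break = 1)
  expect_identical(cs$`break`, names(route_broken_depths(rr)))
})

test_that("evaluation reports consistent percentages and batch
           aggregates", {
  fx <- small_fixture()
  cfg <- search_config(iteration_limit = 25, seed = 3)
  rep <- evaluate_strategies(fx, c("standard", "mo-search"),
                             config = cfg, n_extract = 5, batch_size = 3)
  expect_s3_class(rep$per_strategy, "tbl_df")
  expect_identical(nrow(rep$per_strategy), 2L)
  expect_true(all(rep$per_strategy$percent_solved >= 0 &
                    rep$per_strategy$percent_solved <= 100))
  # constrained-and-solved can never exceed solved
  expect_true(all(rep$per_strategy$percent_solved_and_constrained <=
                    rep$per_strategy$percent_solved + 1e-9))
  # per-target rows recompute to the per-strategy aggregate
  std <- rep$per_target[rep$per_target$strategy == "standard", ]
  expect_equal(
    rep$per_strategy$percent_solved[
      rep$per_strategy$strategy == "standard"],
    100 * mean(std$solved))
  # batches are disjoint and cover all targets
  expect_identical(as.integer(sort(unique(std$batch))),
                   seq_len(max(std$batch)))
  expect_identical(sum(rep$per_batch$batch_n[
    rep$per_batch$strategy == "standard"]), nrow(std))
  # determinism of the whole evaluation (up to wall-clock timings)
  rep2 <- evaluate_strategies(fx, c("standard", "mo-search"),
                              config = cfg, n_extract = 5, batch_size = 3)
  drop_time <- function(df) df[setdiff(names(df),
                                       c("time", "median_search_time"))]
  expect_identical(drop_time(rep$per_strategy),
                   drop_time(rep2$per_strategy))
  expect_identical(drop_time(rep$per_target), drop_time(rep2$per_target))
})

test_that("fixture bundles round-trip through disk", {
  fx <- generate_fixture(2, depth_range = 1:2, seed = 9)
  dir <- tempfile("fixture")
  on.exit(unlink(dir, recursive = TRUE))
  write_fixture(fx, dir)
  expect_true(all(file.exists(file.path(
    dir, c("library.json", "stock.smi", "targets.jsonl")))))
  fx2 <- read_fixture(dir)
  expect_identical(length(fx2$targets), length(fx$targets))
  expect_identical(
    vapply(fx2$targets, function(t) mol_identity(t$target), ""),
    vapply(fx$targets, function(t) mol_identity(t$target), ""))
  expect_identical(lapply(fx2$targets, function(t) t$constraints),
                   lapply(fx$targets, function(t) t$constraints))
  expect_true(all(vapply(fx2$targets, function(t)
    satisfies_constraints(t$reference_route, t$constraints), logical(1))))
  # byte-identical regeneration under the same seed
  d2 <- tempfile("fixture"); on.exit(unlink(d2, recursive = TRUE),
                                     add = TRUE)
  write_fixture(generate_fixture(2, depth_range = 1:2, seed = 9), d2)
  for (f in c("library.json", "stock.smi", "targets.jsonl"))
    expect_identical(readLines(file.path(dir, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
})
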