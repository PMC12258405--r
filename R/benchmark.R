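# Benchmark machinery: convergent disconnection score, constraint
# extraction from reference routes, strategy execution and the evaluation
# report with batch statistics.

#' Convergent disconnection score of a retro step
#'
#' 1 for a perfectly balanced two-way split by heavy-atom count, decreasing
#' with imbalance: `1 - (max_i a_i - min_i a_i) / sum_i a_i` over the
#' reactant heavy-atom counts, generalized to any number of reactants.
#' Single-reactant steps score 0.
#'
#' @param step an `rp_step`, or a numeric vector of reactant heavy-atom
#'   counts.
#' @return numeric in [0, 1].
#' @export
convergent_disconnection_score <- function(step) {
  sizes <- if (inherits(step, "rp_step"))
    vapply(step$reactants, heavy_atoms, 0L) else as.numeric(step)
  if (length(sizes) < 2L) return(0)
  1 - (max(sizes) - min(sizes)) / sum(sizes)
}

# CDS of every reaction in a route (reactant sizes from the child nodes)
.route_cds <- function(route) {
  vapply(route_reactions(route), function(rx) {
    sizes <- vapply(rx$node$children, function(k)
      heavy_atoms(parse_smiles(k$smiles)), 0L)
    convergent_disconnection_score(sizes)
  }, 0)
}

#' Extract bond constraints from a reference route
#'
#' Bonds to break are the changed bonds of the reactions with maximal
#' convergent disconnection score (one bond per reaction, up to `n_break`
#' distinct reactions, ties resolved toward shallower reactions); bonds to
#' freeze are sampled uniformly from the target bonds unchanged along the
#' entire route.  The reference route satisfies the returned constraint
#' set by construction.
#'
#' @param reference_route solved `rp_route` with a fully mapped target.
#' @param n_break number of bonds to break (>= 1).
#' @param n_freeze number of bonds to freeze (< n_break).
#' @return `rp_constraints`.
#' @export
extract_constraints <- function(reference_route, n_break = 1L,
                                n_freeze = 0L) {
  stopifnot(n_break >= 1L, n_freeze < n_break)
  rxs <- route_reactions(reference_route)
  target <- parse_smiles(reference_route$tree$smiles)
  tkeys <- mapped_bonds(target)
  changed <- lapply(rxs, function(rx) intersect(rx$node$broken, tkeys))
  has_changed <- lengths(changed) > 0L
  if (!any(has_changed))
    stop("extraction error: no changed target bonds in this route",
         call. = FALSE)
  cds <- .route_cds(reference_route)
  depth <- vapply(rxs, function(rx) rx$depth, 0L)
  ord <- order(-cds, depth)
  ord <- ord[has_changed[ord]]
  pick <- ord[seq_len(min(n_break, length(ord)))]
  break_keys <- vapply(pick, function(i) sort(changed[[i]])[1], "")
  all_broken <- unique(unlist(lapply(rxs, function(rx) rx$node$broken)))
  unchanged <- setdiff(tkeys, all_broken)
  freeze_keys <- character(0)
  if (n_freeze > 0L) {
    if (!length(unchanged)) {
      warning("no unchanged bonds available; freezing fewer bonds than ",
              "requested", call. = FALSE)
    } else {
      freeze_keys <- sample(unchanged, min(n_freeze, length(unchanged)))
    }
  }
  cs <- constraint_set(break_keys, setdiff(freeze_keys, break_keys),
                       target = target)
  stopifnot(satisfies_constraints(reference_route, cs))
  cs
}

#' Strategy names understood by the benchmark runner
#' @return character vector.
#' @export
strategy_names <- function() {
  c("standard", "route-ranking", "mo-search", "da", "da-mo")
}

#' Run one search strategy on one target
#'
#' `standard` = template policy + single-objective MCTS, top routes by
#' state score; `route-ranking` = same search, routes ranked by the
#' equal-weight combined score; `mo-search` = MO-MCTS on (state, broken
#' bonds), Pareto-front extraction; `da` = disconnection-aware
#' multi-expansion + single-objective MCTS; `da-mo` = disconnection-aware
#' multi-expansion + MO-MCTS.  The frozen bonds filter is active in every
#' strategy.
#'
#' @param strategy one of [strategy_names()].
#' @param target `rp_mol` (mapped) or `rp_benchmark_target`.
#' @param constraints `rp_constraints` (ignored when `target` is a
#'   benchmark target).
#' @param library `rp_template_library`.
#' @param stk `rp_stock`.
#' @param config `rp_config`.
#' @param n_extract routes to extract.
#' @return list with `routes` (scored, ranked) and `search` (`rp_search`).
#' @export
run_strategy <- function(strategy, target, constraints = NULL,
                         library = NULL, stk = NULL,
                         config = search_config(), n_extract = 5) {
  strategy <- match.arg(strategy, strategy_names())
  if (inherits(target, "rp_benchmark_target")) {
    constraints <- target$constraints
    target <- target$target
  }
  if (is.null(constraints)) constraints <- constraint_set()
  mo_ok <- length(constraints$`break`) > 0L
  sr <- switch(strategy,
    "standard" = ,
    "route-ranking" = mcts_search(target, constraints, library, stk,
                                  config, mode = "standard"),
    "mo-search" = if (mo_ok)
        mo_mcts_search(target, constraints, library, stk, config,
                       mode = "standard")
      else mcts_search(target, constraints, library, stk, config,
                       mode = "standard"),
    "da" = mcts_search(target, constraints, library, stk, config,
                       mode = "disconnection_aware"),
    "da-mo" = if (mo_ok)
        mo_mcts_search(target, constraints, library, stk, config,
                       mode = "disconnection_aware")
      else mcts_search(target, constraints, library, stk, config,
                       mode = "disconnection_aware"))
  extraction <- switch(strategy,
    "standard" = "standard", "da" = "standard",
    "route-ranking" = "route_ranking",
    "mo-search" = "mo_front", "da-mo" = "mo_front")
  if (!mo_ok && extraction == "mo_front") extraction <- "standard"
  routes <- extract_routes(sr, extraction, n_extract)
  list(routes = routes, search = sr)
}

#' Evaluate strategies on a set of benchmark targets
#'
#' Runs every strategy on every target and reports, per strategy: the
#' percentage of targets solved, the percentage solved with all bond
#' constraints satisfied, the mean number of extracted routes that are
#' solved and satisfy the constraints, and the median search time.
#' Metrics are additionally aggregated over disjoint batches of targets
#' (mean and standard deviation across batches) to expose their
#' variability.
#'
#' @param fixture `rp_fixture`, or a list of `rp_benchmark_target` (then
#'   `library` and `stk` must be given).
#' @param strategies subset of [strategy_names()].
#' @param config `rp_config`; its seed governs every search.
#' @param n_extract routes extracted per search.
#' @param batch_size targets per batch for the spread statistics.
#' @param library,stk used when `fixture` is a plain target list.
#' @return object of class `rp_eval` with tibbles `per_target`,
#'   `per_strategy`, `per_batch`.
#' @export
evaluate_strategies <- function(fixture,
                                strategies = c("standard", "mo-search"),
                                config = search_config(),
                                n_extract = 5, batch_size = 128,
                                library = NULL, stk = NULL) {
  strategies <- match.arg(strategies, strategy_names(), several.ok = TRUE)
  if (inherits(fixture, "rp_fixture")) {
    targets <- fixture$targets
    library <- fixture$library
    stk <- fixture$stock
  } else targets <- fixture
  stopifnot(length(targets) >= 1, !is.null(library), !is.null(stk))
  rows <- list()
  for (si in seq_along(strategies)) {
    strat <- strategies[[si]]
    for (ti in seq_along(targets)) {
      tg <- targets[[ti]]
      t0 <- Sys.time()
      res <- tryCatch(
        run_strategy(strat, tg, library = library, stk = stk,
                     config = config, n_extract = n_extract),
        error = function(e) e)
      el <- as.numeric(Sys.time() - t0, units = "secs")
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          target = ti, strategy = strat, solved = NA,
          solved_constrained = NA, n_satisfying = NA_integer_,
          n_routes = 0L, time = el,
          error = conditionMessage(res))
        next
      }
      ok <- vapply(res$routes, is_solved, logical(1))
      sat <- vapply(res$routes, satisfies_constraints, logical(1),
                    constraints = tg$constraints)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        target = ti, strategy = strat, solved = any(ok),
        solved_constrained = any(ok & sat),
        n_satisfying = sum(ok & sat), n_routes = length(res$routes),
        time = el, error = NA_character_)
    }
  }
  per_target <- do.call(rbind, rows)
  per_target$batch <- (per_target$target - 1L) %/% batch_size + 1L
  agg <- function(df) tibble::tibble(
    percent_solved = 100 * mean(df$solved, na.rm = TRUE),
    percent_solved_and_constrained =
      100 * mean(df$solved_constrained, na.rm = TRUE),
    mean_constraint_satisfying_routes =
      mean(df$n_satisfying, na.rm = TRUE),
    median_search_time = stats::median(df$time, na.rm = TRUE))
  per_strategy <- do.call(rbind, lapply(split(per_target,
                                              per_target$strategy),
    function(df) cbind(tibble::tibble(strategy = df$strategy[1]), agg(df))))
  per_batch <- do.call(rbind, lapply(
    split(per_target, list(per_target$strategy, per_target$batch),
          drop = TRUE),
    function(df) cbind(tibble::tibble(strategy = df$strategy[1],
                                      batch = df$batch[1],
                                      batch_n = nrow(df)), agg(df))))
  rownames(per_strategy) <- rownames(per_batch) <- NULL
  structure(list(per_target = tibble::as_tibble(per_target),
                 per_strategy = tibble::as_tibble(per_strategy),
                 per_batch = tibble::as_tibble(per_batch),
                 batch_size = batch_size, n_extract = n_extract,
                 seed = config$seed),
            class = "rp_eval")
}

#' @export
print.rp_eval <- function(x, ...) {
  cat("<rp_eval> ", length(unique(x$per_target$target)), " target(s), ",
      "batch size ", x$batch_size, ", seed ", x$seed, "\n", sep = "")
  print(x$per_strategy)
  invisible(x)
}

#' Write an evaluation report to CSV and JSON
#' @param report `rp_eval`.
#' @param stem output path without extension; writes `<stem>.csv`
#'   (per-strategy table) and `<stem>.json` (full report).
#' @return invisibly, the two paths.
#' @export
write_eval_report <- function(report, stem) {
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  utils::write.csv(report$per_strategy, csv, row.names = FALSE)
  jsonlite::write_json(
    list(per_strategy = report$per_strategy,
         per_batch = report$per_batch,
         per_target = report$per_target,
         batch_size = report$batch_size, seed = report$seed),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, js))
}

# ---------------------------------------------------------------------------
# fixture bundle on disk

#' Write a benchmark fixture bundle to a directory
#'
#' `library.json` (template library), `stock.smi` (one SMILES per line) and
#' `targets.jsonl` (one JSON object per target: mapped SMILES, constraint
#' pairs, reference route, provenance).
#'
#' @param fixture `rp_fixture`.
#' @param dir output directory (created if missing).
#' @return invisibly, `dir`.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_template_library(fixture$library, file.path(dir, "library.json"))
  write_stock(fixture$stock, file.path(dir, "stock.smi"))
  keypairs <- function(keys) lapply(keys, function(k)
    as.integer(strsplit(k, "-", fixed = TRUE)[[1]]))
  lines <- vapply(fixture$targets, function(tg) {
    as.character(jsonlite::toJSON(list(
      target = canonical_smiles(tg$target),
      bonds_to_break = keypairs(tg$constraints$`break`),
      bonds_to_freeze = keypairs(tg$constraints$freeze),
      reference_route = jsonlite::fromJSON(
        route_to_json(tg$reference_route), simplifyVector = FALSE),
      provenance = tg$provenance),
      auto_unbox = TRUE, digits = NA))
  }, "")
  writeLines(lines, file.path(dir, "targets.jsonl"))
  invisible(dir)
}

#' Read a benchmark fixture bundle from a directory
#' @param dir directory written by [write_fixture()].
#' @return list with `library`, `stock`, `targets`; each target has
#'   `target` (`rp_mol`), `constraints`, `reference_route`, `provenance`.
#' @export
read_fixture <- function(dir) {
  lib <- read_template_library(file.path(dir, "library.json"))
  stk <- read_stock(file.path(dir, "stock.smi"))
  targets <- lapply(readLines(file.path(dir, "targets.jsonl"),
                              warn = FALSE), function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    mol <- parse_smiles(obj$target)
    cs <- constraint_set(
      vapply(obj$bonds_to_break, function(p)
        bond_key(p[[1]], p[[2]]), ""),
      if (length(obj$bonds_to_freeze))
        vapply(obj$bonds_to_freeze, function(p)
          bond_key(p[[1]], p[[2]]), "") else NULL,
      target = mol)
    rr <- structure(list(
      tree = .node_from_list(obj$reference_route$tree, "$tree"),
      scores = obj$reference_route$scores %||% list(),
      metadata = obj$reference_route$metadata %||% list()),
      class = "rp_route")
    structure(list(target = mol, constraints = cs, reference_route = rr,
                   provenance = obj$provenance, depth =
                     obj$provenance$depth),
              class = "rp_benchmark_target")
  })
  structure(list(library = lib, stock = stk, targets = targets,
                 seed = NA_integer_, hidden = NA), class = "rp_fixture")
}
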