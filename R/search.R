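# Monte-Carlo tree search over retro steps: single-objective (state score)
# and multi-objective (state score + broken bonds score) variants, route
# extraction, and Pareto front machinery.
#
# Search nodes hold a frontier of unsolved molecules (each with its own
# transform depth); expansion applies the multi-expansion policy plus the
# frozen bonds filter to the first frontier molecule; the reward of a node
# is the immediate evaluation of its state (no rollout), backed up as a
# running mean, following the convention of template-based MCTS planners.
# The multi-objective selection rule computes a per-objective UCB vector
# for every child and draws uniformly (seeded) among the Pareto
# non-dominated children.

#' Search configuration
#'
#' @param max_depth maximum number of reaction steps per molecule branch.
#' @param iteration_limit MCTS iterations.
#' @param time_limit wall-clock budget in seconds.
#' @param ucb_constant exploration constant.
#' @param seed integer seed; every stochastic choice in a search flows from
#'   it.
#' @param expansion_k number of single-step predictions per expansion.
#' @param beam beam width of the disconnection-aware policy.
#' @param objectives character vector of objective names, a subset of
#'   c("state", "broken-bonds"); more than one switches to MO search.
#' @return list of class `rp_config`.
#' @export
search_config <- function(max_depth = 6, iteration_limit = 100,
                          time_limit = 300, ucb_constant = 1.4,
                          seed = 1L, expansion_k = 50, beam = 5,
                          objectives = "state") {
  stopifnot(max_depth >= 1, time_limit > 0, iteration_limit >= 1,
            length(objectives) >= 1,
            all(objectives %in% c("state", "broken-bonds")))
  structure(list(max_depth = as.integer(max_depth),
                 iteration_limit = as.integer(iteration_limit),
                 time_limit = time_limit, ucb_constant = ucb_constant,
                 seed = as.integer(seed),
                 expansion_k = as.integer(expansion_k),
                 beam = as.integer(beam), objectives = objectives),
            class = "rp_config")
}

# expansion cache: one entry per (molecule identity + maps, mode, freeze)
.expansion_cache <- new.env(parent = emptyenv())

#' Clear the package-level expansion cache
#' @return invisibly NULL.
#' @export
clear_expansion_cache <- function() {
  rm(list = ls(.expansion_cache), envir = .expansion_cache)
  invisible(NULL)
}

.expand_cached <- function(mol, constraints, library, config, mode,
                           lib_id) {
  key <- paste(canonical_smiles(mol), mode, lib_id,
               paste(constraints$`break`, collapse = ","),
               paste(constraints$freeze, collapse = ","), sep = "|")
  hit <- .expansion_cache[[key]]
  if (!is.null(hit)) return(hit)
  steps <- multi_expand(mol, constraints, library, k = config$expansion_k,
                        beam = config$beam, mode = mode)
  steps <- frozen_filter(steps, constraints$freeze)
  assign(key, steps, envir = .expansion_cache)
  steps
}

# internal: new search node (environment for in-place statistics)
.new_node <- function(frontier, path, n_stock_leaves, n_obj, parent) {
  e <- new.env(parent = emptyenv())
  e$frontier <- frontier          # list of list(mol, depth)
  e$path <- path                  # list of rp_step
  e$n_stock_leaves <- n_stock_leaves
  e$children <- NULL              # list of nodes (after expansion)
  e$steps <- NULL
  e$expanded <- FALSE
  e$terminal <- length(frontier) == 0L
  e$visits <- 0L
  e$value_acc <- numeric(n_obj)
  e$parent <- parent
  e
}

.node_scores <- function(node, constraints, config) {
  L <- length(node$path)
  n_leaves <- node$n_stock_leaves + length(node$frontier)
  frac <- if (n_leaves == 0L) 1 else node$n_stock_leaves / n_leaves
  st <- .W_STOCK * frac + .W_LEN * length_squash(L)
  if (length(config$objectives) == 1L && config$objectives == "state")
    return(st)
  depths <- integer(0)
  for (i in seq_along(node$path)) {
    s <- node$path[[i]]
    for (b in s$broken)
      if (!b %in% names(depths)) depths[b] <- s$applied_depth
  }
  bb <- if (length(constraints$`break`))
    broken_bonds_score(depths, constraints$`break`, config$max_depth)
    else 0
  vec <- c(st, bb)
  names(vec) <- NULL
  vec[match(config$objectives, c("state", "broken-bonds"))]
}

# Pareto non-dominated indices of a score matrix (maximization)
.nondominated <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(1L)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    ge <- sweep(m, 2, m[i, ], FUN = ">=")
    gt <- sweep(m, 2, m[i, ], FUN = ">")
    dominators <- rowSums(ge) == ncol(m) & rowSums(gt) > 0
    if (any(dominators)) keep[i] <- FALSE
  }
  which(keep)
}

#' Iterated Pareto fronts of a set of score vectors
#'
#' Non-dominated sorting under maximization on every axis: rank 1 is the
#' set of vectors not dominated by any other; subsequent ranks are obtained
#' by iteratively removing the primary front.  Non-strict ties share a
#' rank (a point never dominates an identical copy of itself).
#'
#' @param points numeric matrix (rows = points) or list of equal-length
#'   numeric vectors.
#' @return list of fronts; each front is a list with `rank`, `indices`
#'   (row indices into the input, in input order) and `points` (the score
#'   matrix rows).
#' @export
pareto_fronts <- function(points) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, points)
  points <- as.matrix(points)
  if (!nrow(points)) return(list())
  remaining <- seq_len(nrow(points))
  fronts <- list()
  r <- 0L
  while (length(remaining)) {
    r <- r + 1L
    nd <- .nondominated(points[remaining, , drop = FALSE])
    idx <- remaining[nd]
    fronts[[r]] <- list(rank = r, indices = idx,
                        points = points[idx, , drop = FALSE])
    remaining <- setdiff(remaining, idx)
  }
  class(fronts) <- "rp_pareto"
  fronts
}

#' @export
print.rp_pareto <- function(x, ...) {
  cat("<rp_pareto> ", length(x), " front(s); sizes: ",
      paste(vapply(x, function(f) length(f$indices), 0L), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

.ucb <- function(child_means, child_visits, parent_visits, C) {
  bonus <- C * sqrt(log(parent_visits + 1) / child_visits)
  child_means + bonus
}

.select_child <- function(node, C, n_obj) {
  visits <- vapply(node$children, function(c) c$visits, 0L)
  if (any(visits == 0L)) return(node$children[[which(visits == 0L)[1]]])
  if (n_obj == 1L) {
    means <- vapply(node$children, function(c) c$value_acc / c$visits, 0)
    u <- .ucb(means, visits, node$visits, C)
    return(node$children[[which.max(u)]])
  }
  m <- t(vapply(node$children, function(c) c$value_acc / c$visits,
                numeric(n_obj)))
  u <- m + C * sqrt(log(node$visits + 1) / visits)
  nd <- .nondominated(u)
  pick <- if (length(nd) == 1L) nd else nd[sample.int(length(nd), 1L)]
  node$children[[pick]]
}

.expand_node <- function(node, constraints, library, stk, config, mode,
                         lib_id, n_obj) {
  node$expanded <- TRUE
  if (!length(node$frontier)) { node$terminal <- TRUE; return() }
  head <- node$frontier[[1]]
  if (head$depth >= config$max_depth) { node$terminal <- TRUE; return() }
  steps <- .expand_cached(head$mol, constraints, library, config, mode,
                          lib_id)
  if (!length(steps)) { node$terminal <- TRUE; return() }
  rest <- node$frontier[-1]
  kids <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    s$applied_depth <- head$depth
    new_front <- list()
    n_stock <- node$n_stock_leaves
    for (r in s$reactants) {
      if (in_stock(r, stk)) n_stock <- n_stock + 1L
      else new_front[[length(new_front) + 1L]] <-
          list(mol = r, depth = head$depth + 1L)
    }
    kids[[i]] <- .new_node(c(new_front, rest), c(node$path, list(s)),
                           n_stock, n_obj, node)
  }
  node$children <- kids
  node$steps <- steps
}

.backprop <- function(node, reward) {
  while (!is.null(node)) {
    node$visits <- node$visits + 1L
    node$value_acc <- node$value_acc + reward
    node <- node$parent
  }
}

.run_search <- function(target, constraints, library, stk, config, mode) {
  set.seed(config$seed)
  n_obj <- length(config$objectives)
  lib_id <- paste0(length(library), ":",
                   paste(vapply(library, `[[`, "", "name"), collapse = ","))
  frontier <- if (in_stock(target, stk)) list()
              else list(list(mol = target, depth = 0L))
  root <- .new_node(frontier,  list(),
                    as.integer(length(frontier) == 0L), n_obj, NULL)
  t0 <- Sys.time()
  iter <- 0L
  while (iter < config$iteration_limit &&
         as.numeric(Sys.time() - t0, units = "secs") < config$time_limit) {
    iter <- iter + 1L
    node <- root
    while (node$expanded && !node$terminal && length(node$children)) {
      node <- .select_child(node, config$ucb_constant, n_obj)
    }
    if (!node$expanded && !node$terminal) {
      .expand_node(node, constraints, library, stk, config, mode, lib_id,
                   n_obj)
      if (!is.null(node$children) && length(node$children))
        node <- .select_child(node, config$ucb_constant, n_obj)
    }
    reward <- .node_scores(node, constraints, config)
    .backprop(node, reward)
    if (root$terminal) break
  }
  structure(list(root = root, target = target, constraints = constraints,
                 stock = stk, config = config, mode = mode,
                 iterations = iter,
                 elapsed = as.numeric(Sys.time() - t0, units = "secs")),
            class = "rp_search")
}

#' Single-objective MCTS retrosynthesis search
#'
#' Select / expand / evaluate / backpropagate until the iteration or time
#' budget is exhausted (never stopping at the first solution); expansion
#' uses the multi-expansion policy followed by the frozen bonds filter; the
#' reward is the state score of the reached state.
#'
#' @param target `rp_mol` (atom-mapped), e.g. from [parse_target()].
#' @param constraints `rp_constraints`.
#' @param library `rp_template_library`.
#' @param stk `rp_stock`.
#' @param config `rp_config`; its `objectives` are forced to "state".
#' @param mode expansion mode passed to [multi_expand()].
#' @return object of class `rp_search`.
#' @export
mcts_search <- function(target, constraints, library, stk,
                        config = search_config(),
                        mode = c("standard", "disconnection_aware")) {
  mode <- match.arg(mode)
  config$objectives <- "state"
  .run_search(target, constraints, library, stk, config, mode)
}

#' Multi-objective MCTS retrosynthesis search
#'
#' As [mcts_search()] but rewards are score vectors (state score and broken
#' bonds score); child selection computes per-objective UCB values and
#' draws uniformly among Pareto non-dominated children.
#'
#' @inheritParams mcts_search
#' @param config `rp_config`; objectives default to both scores.
#' @return object of class `rp_search`.
#' @export
mo_mcts_search <- function(target, constraints, library, stk,
                           config = search_config(),
                           mode = c("standard", "disconnection_aware")) {
  mode <- match.arg(mode)
  if (length(config$objectives) < 2L)
    config$objectives <- c("state", "broken-bonds")
  if (!length(constraints$`break`))
    stop("multi-objective search needs a non-empty break set for the ",
         "broken bonds objective", call. = FALSE)
  .run_search(target, constraints, library, stk, config, mode)
}

#' @export
print.rp_search <- function(x, ...) {
  cat("<rp_search> ", canonical_smiles(x$target, with_maps = FALSE),
      ": ", x$iterations, " iterations in ", round(x$elapsed, 2), "s, ",
      if (search_solved(x)) "solved" else "unsolved", "\n", sep = "")
  invisible(x)
}

# collect all instantiated nodes of a search tree
.all_nodes <- function(tree) {
  out <- list()
  walk <- function(nd) {
    out[[length(out) + 1L]] <<- nd
    for (k in nd$children %||% list()) walk(k)
  }
  walk(tree$root)
  out
}

#' Was any solved state visited during the search?
#' @param tree `rp_search`.
#' @return logical.
#' @export
search_solved <- function(tree) {
  any(vapply(.all_nodes(tree), function(n)
    length(n$frontier) == 0L && n$visits > 0L, logical(1))) ||
    length(tree$root$frontier) == 0L
}

#' Extract ranked routes from a search tree
#'
#' Every visited state corresponds to one route (its step path).  Strategy
#' `"standard"` returns the top-n by state score, `"route_ranking"` the
#' top-n by the equal-weight combined score, and `"mo_front"` all routes on
#' the primary Pareto front of (state, broken bonds), padded from
#' successive ranks up to n.  Duplicate reaction trees are removed.
#'
#' @param tree `rp_search`.
#' @param strategy extraction strategy.
#' @param n number of routes to return.
#' @return list of scored `rp_route`.
#' @export
extract_routes <- function(tree, strategy = c("standard", "route_ranking",
                                              "mo_front"), n = 10) {
  strategy <- match.arg(strategy)
  stopifnot(n >= 1)
  nodes <- Filter(function(nd) nd$visits > 0L || length(nd$path) == 0L,
                  .all_nodes(tree))
  routes <- list()
  seen <- character(0)
  d_max <- tree$config$max_depth
  for (nd in nodes) {
    r <- route_from_steps(tree$target, nd$path, tree$stock,
                          metadata = list(mode = tree$mode,
                                          seed = tree$config$seed))
    key <- route_key(r)
    if (key %in% seen) next
    seen <- c(seen, key)
    routes[[length(routes) + 1L]] <-
      score_route(r, tree$constraints, d_max)
  }
  if (!length(routes)) return(routes)
  if (strategy == "standard")
    return(utils::head(rank_routes(routes, "standard"), n))
  if (strategy == "route_ranking")
    return(utils::head(rank_routes(routes, "route_ranking"), n))
  ranked <- rank_routes(routes, "mo")
  st <- vapply(ranked, function(r) r$scores$state, 0)
  bb <- vapply(ranked, function(r) r$scores$broken_bonds, 0)
  fronts <- pareto_fronts(cbind(st, bb))
  primary <- length(fronts[[1]]$indices)
  utils::head(ranked, max(primary, min(n, length(ranked))))
}
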