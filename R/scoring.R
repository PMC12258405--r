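# Route objectives.
#
# state score      -- rewards solved, short routes: 0.95 * (fraction of leaf
#                     molecules in stock) + 0.05 * g(L), with g a logistic
#                     squash of the route length L normalized so g(0) = 1.
# broken bonds     -- depth-weighted reward for disconnecting the prompted
#                     bonds early in the tree (see broken_bonds_score).
# combined         -- equal-weight linear combination of the two.

.W_STOCK <- 0.95
.W_LEN <- 0.05

#' Length squash used by the state score
#'
#' Decreasing logistic squash with g(0) = 1; midpoint and scale are
#' configurable knobs of the length penalty.
#'
#' @param L route length (number of reactions).
#' @param midpoint,scale logistic parameters.
#' @return numeric in (0, 1].
#' @export
length_squash <- function(L, midpoint = 4, scale = 1.2) {
  f <- function(x) 1 / (1 + exp((x - midpoint) / scale))
  f(L) / f(0)
}

#' State score of a route
#'
#' `0.95 * fraction of leaves in stock + 0.05 * g(L)`.  A target already in
#' stock (zero reactions) scores exactly 1.
#'
#' @param route `rp_route`.
#' @return numeric in [0, 1].
#' @export
state_score <- function(route) {
  leaves <- route_leaves(route)
  frac <- mean(vapply(leaves, function(l) isTRUE(l$in_stock), logical(1)))
  unname(.W_STOCK * frac + .W_LEN * length_squash(route_length(route)))
}

#' Broken bonds score of a route
#'
#' Given the prompted bonds to break B, every bond broken by a reaction at
#' depth d contributes a credit (1 - d / D_max); when some prompted bonds
#' stay unbroken they incur one joint penalty term equal to breaking at the
#' maximum depth, (1 - D_max / D_max) = 0.  The sum is normalized by the
#' number of productive components: |broken| when all prompted bonds break,
#' |broken| + 1 otherwise.  The score is 1 exactly when every prompted bond
#' breaks in the first reaction and 0 exactly when none breaks.
#'
#' @param route `rp_route`, or a named integer vector of bond-key ->
#'   break-depth pairs (as from [route_broken_depths()]).
#' @param break_set non-empty character vector of prompted bond keys.
#' @param d_max maximum depth used for the depth weighting; defaults to the
#'   search default depth.
#' @return numeric in [0, 1].
#' @export
broken_bonds_score <- function(route, break_set, d_max = 6) {
  if (!length(break_set))
    stop("broken bonds score is undefined for an empty break set",
         call. = FALSE)
  depths <- if (inherits(route, "rp_route")) route_broken_depths(route)
            else route
  hit <- depths[names(depths) %in% break_set]
  if (length(hit) && any(hit >= d_max))
    stop("reaction depth ", max(hit), " exceeds d_max = ", d_max,
         call. = FALSE)
  n_broken <- length(hit)
  partial <- n_broken < length(break_set)
  if (n_broken == 0L) return(0)
  credits <- sum(1 - hit / d_max)
  penalty <- if (partial) 1 - d_max / d_max else 0
  unname((credits + penalty) / (n_broken + as.integer(partial)))
}

#' Combined (equal-weight) route score
#' @param state,broken numeric scores in [0, 1].
#' @return `0.5 * state + 0.5 * broken`.
#' @export
combined_score <- function(state, broken) 0.5 * state + 0.5 * broken

#' Score a route under a constraint set
#'
#' @param route `rp_route`.
#' @param constraints `rp_constraints` (break set may be empty, in which
#'   case the broken-bonds and combined scores are NA).
#' @param d_max maximum depth for the broken-bonds weighting.
#' @return the route with its `scores` field populated (state,
#'   broken_bonds, combined).
#' @export
score_route <- function(route, constraints = NULL, d_max = 6) {
  st <- state_score(route)
  bb <- if (!is.null(constraints) && length(constraints$`break`))
    broken_bonds_score(route, constraints$`break`, d_max) else NA_real_
  route$scores <- list(state = st, broken_bonds = bb,
                       combined = if (is.na(bb)) NA_real_
                                  else combined_score(st, bb))
  route
}

#' Rank routes under a strategy
#'
#' `standard` sorts by state score, `route_ranking` by the equal-weight
#' combined score, `mo` by Pareto rank over (state, broken bonds) with the
#' primary front first.  Ties break on the canonical route serialization,
#' so the order is stable and reproducible.
#'
#' @param routes list of scored `rp_route` (see [score_route()]).
#' @param strategy "standard", "route_ranking" or "mo".
#' @return the routes, reordered.
#' @export
rank_routes <- function(routes, strategy = c("standard", "route_ranking",
                                             "mo")) {
  strategy <- match.arg(strategy)
  if (!length(routes)) return(routes)
  keys <- vapply(routes, route_key, "")
  st <- vapply(routes, function(r) r$scores$state, 0)
  if (strategy == "standard") return(routes[order(-st, keys)])
  bb <- vapply(routes, function(r) r$scores$broken_bonds %||% NA_real_, 0)
  if (strategy == "route_ranking") {
    cmb <- vapply(routes, function(r) r$scores$combined %||% NA_real_, 0)
    return(routes[order(-cmb, keys)])
  }
  fronts <- pareto_fronts(cbind(st, bb))
  rank <- integer(length(routes))
  for (f in seq_along(fronts)) rank[fronts[[f]]$indices] <- f
  routes[order(rank, -st, keys)]
}

#' Tidy score table for a set of routes
#' @param routes list of scored `rp_route`.
#' @return tibble with one row per route.
#' @export
route_score_table <- function(routes) {
  tibble::tibble(
    route = seq_along(routes),
    solved = vapply(routes, is_solved, logical(1)),
    n_reactions = vapply(routes, route_length, 0L),
    state = vapply(routes, function(r) r$scores$state %||% NA_real_, 0),
    broken_bonds = vapply(routes, function(r)
      r$scores$broken_bonds %||% NA_real_, 0),
    combined = vapply(routes, function(r)
      r$scores$combined %||% NA_real_, 0))
}
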