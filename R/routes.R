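# Reaction trees: the bipartite molecule/reaction tree rooted at the
# target, its JSON serialization, constraint-satisfaction checks, and the
# route similarity / dissimilarity / diversity metrics.

#' Construct a route from a target and an ordered list of retro steps
#'
#' Steps are replayed against the growing tree with a depth-first frontier
#' discipline (a step's not-in-stock reactants are queued in front), which
#' mirrors how the search expands states, so a search node's path converts
#' losslessly into its reaction tree.
#'
#' @param target `rp_mol` (atom-mapped) root of the tree.
#' @param steps list of `rp_step` in application order.
#' @param stk `rp_stock` used to flag leaf molecules.
#' @param metadata named list stored on the route.
#' @return object of class `rp_route`.
#' @export
route_from_steps <- function(target, steps, stk, metadata = list()) {
  mk_node <- function(mol) {
    e <- new.env(parent = emptyenv())
    e$smiles <- canonical_smiles(mol)
    e$in_stock <- in_stock(mol, stk)
    e$children <- list()
    e
  }
  root <- mk_node(target)
  queue <- if (root$in_stock) list() else list(root)
  for (s in steps) {
    if (!length(queue))
      stop("route replay error: no expandable molecule left for step ",
           s$template_name, call. = FALSE)
    node <- queue[[1]]; queue <- queue[-1]
    if (!identical(node$smiles, canonical_smiles(s$product)))
      stop("route replay error: step product ",
           canonical_smiles(s$product), " does not match frontier molecule ",
           node$smiles, call. = FALSE)
    rxn <- new.env(parent = emptyenv())
    rxn$metadata <- list(template_name = s$template_name,
                         source_policy = s$source_policy,
                         prior = s$prior)
    rxn$broken <- s$broken
    kids <- lapply(s$reactants, mk_node)
    rxn$children <- kids
    node$children <- list(rxn)
    fresh <- Filter(function(k) !k$in_stock, kids)
    queue <- c(fresh, queue)
  }
  freeze <- function(e) {
    out <- as.list(e)
    out$children <- lapply(out$children, freeze)
    out
  }
  tree <- freeze(root)
  tree$type <- "mol"
  fix_types <- function(nd, ty) {
    nd$type <- ty
    nd$children <- lapply(nd$children, fix_types,
                          ty = if (ty == "mol") "reaction" else "mol")
    nd
  }
  tree <- fix_types(tree, "mol")
  structure(list(tree = tree, scores = list(), metadata = metadata),
            class = "rp_route")
}

#' @export
print.rp_route <- function(x, ...) {
  rx <- route_reactions(x)
  cat("<rp_route> ", x$tree$smiles, "\n  ", length(rx), " reaction(s), ",
      if (is_solved(x)) "solved" else "unsolved", sep = "")
  if (length(x$scores))
    cat("  scores: ", paste(names(x$scores),
                            signif(unlist(x$scores), 3),
                            sep = "=", collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' All reaction nodes of a route with their depths
#'
#' Depth is the number of reaction ancestors: the reaction applied directly
#' to the target has depth 0.
#'
#' @param route `rp_route`.
#' @return list of `list(node, depth)`.
#' @export
route_reactions <- function(route) {
  out <- list()
  walk <- function(nd, d) {
    if (identical(nd$type, "reaction")) {
      out[[length(out) + 1L]] <<- list(node = nd, depth = d)
      for (k in nd$children) walk(k, d + 1L)
    } else {
      for (k in nd$children) walk(k, d)
    }
  }
  walk(route$tree, 0L)
  out
}

#' Leaf molecules of a route
#' @param route `rp_route`.
#' @return list of mol nodes without children.
#' @export
route_leaves <- function(route) {
  out <- list()
  walk <- function(nd) {
    if (identical(nd$type, "mol") && !length(nd$children))
      out[[length(out) + 1L]] <<- nd
    for (k in nd$children) walk(k)
  }
  walk(route$tree)
  out
}

# all molecule nodes (root, intermediates, leaves)
route_mol_nodes <- function(route) {
  out <- list()
  walk <- function(nd) {
    if (identical(nd$type, "mol")) out[[length(out) + 1L]] <<- nd
    for (k in nd$children) walk(k)
  }
  walk(route$tree)
  out
}

#' Number of reactions in a route
#' @param route `rp_route`.
#' @return integer.
#' @export
route_length <- function(route) length(route_reactions(route))

#' Is a route solved (every leaf in stock)?
#' @param route `rp_route`.
#' @return logical.
#' @export
is_solved <- function(route) {
  all(vapply(route_leaves(route), function(l) isTRUE(l$in_stock),
             logical(1)))
}

#' Broken bonds of a route, with the depth at which each breaks
#' @param route `rp_route`.
#' @return named integer vector: bond key -> reaction depth.
#' @export
route_broken_depths <- function(route) {
  out <- integer(0)
  for (rx in route_reactions(route)) {
    for (b in rx$node$broken) {
      if (!b %in% names(out)) out[b] <- rx$depth
    }
  }
  out
}

#' Does a route satisfy a constraint set?
#'
#' TRUE iff every bond to break is broken by some reaction of the route and
#' no reaction breaks a frozen bond.
#'
#' @param route `rp_route`.
#' @param constraints `rp_constraints`.
#' @return logical.
#' @export
satisfies_constraints <- function(route, constraints) {
  bd <- names(route_broken_depths(route))
  all(constraints$`break` %in% bd) &&
    !length(intersect(constraints$freeze, bd))
}

# canonical serialization string (deduplication / stable tie-breaks)
route_key <- function(route) {
  ser <- function(nd) {
    if (identical(nd$type, "mol")) {
      paste0("M(", nd$smiles, ")[",
             paste(vapply(nd$children, ser, ""), collapse = ""), "]")
    } else {
      paste0("R{", paste(sort(nd$broken), collapse = ","), "}[",
             paste(sort(vapply(nd$children, ser, "")), collapse = ""), "]")
    }
  }
  ser(route$tree)
}

# ---------------------------------------------------------------------------
# JSON serialization

.node_to_list <- function(nd) {
  nd$children <- lapply(nd$children, .node_to_list)
  if (identical(nd$type, "reaction") && length(nd$broken))
    nd$broken <- lapply(nd$broken, function(k)
      as.integer(strsplit(k, "-", fixed = TRUE)[[1]]))
  nd
}

.node_from_list <- function(nd, path) {
  if (is.null(nd$type) || !nd$type %in% c("mol", "reaction"))
    stop("route schema violation at ", path,
         ": missing or invalid 'type'", call. = FALSE)
  if (identical(nd$type, "mol") && is.null(nd$smiles))
    stop("route schema violation at ", path, ": mol node without 'smiles'",
         call. = FALSE)
  if (!is.null(nd$broken)) {
    nd$broken <- vapply(nd$broken, function(p) {
      p <- unlist(p)
      if (length(p) != 2L)
        stop("route schema violation at ", path,
             ": 'broken' entries must be pairs", call. = FALSE)
      bond_key(p[1], p[2])
    }, character(1))
  }
  if (is.null(nd$children)) nd$children <- list()
  if (identical(nd$type, "mol")) nd$in_stock <- isTRUE(nd$in_stock)
  kids <- nd$children
  expect <- if (nd$type == "mol") "reaction" else "mol"
  nd$children <- lapply(seq_along(kids), function(i) {
    k <- .node_from_list(kids[[i]], paste0(path, "/children[", i, "]"))
    if (!identical(k$type, expect))
      stop("route schema violation at ", path, ": ", nd$type,
           " node with ", k$type, " child", call. = FALSE)
    k
  })
  nd
}

#' Serialize a route to JSON
#'
#' Nested molecule/reaction dictionaries; molecule nodes carry mapped
#' canonical SMILES and in-stock flags, reaction nodes their template name,
#' source policy and broken-bond pairs.  Unknown extra keys survive a
#' round trip.
#'
#' @param route `rp_route`.
#' @param path optional file; when NULL the JSON string is returned.
#' @return JSON string (invisibly the path when writing to file).
#' @export
route_to_json <- function(route, path = NULL) {
  obj <- list(tree = .node_to_list(route$tree), scores = route$scores,
              metadata = route$metadata)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Deserialize a route from JSON
#' @param json JSON string, or a file path when `file = TRUE`.
#' @param file treat `json` as a file path?
#' @return `rp_route`.
#' @export
route_from_json <- function(json, file = FALSE) {
  txt <- if (file) paste(readLines(json, warn = FALSE), collapse = "\n")
         else json
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (is.null(obj$tree))
    stop("route schema violation at $: missing 'tree'", call. = FALSE)
  tree <- .node_from_list(obj$tree, "$tree")
  structure(list(tree = tree,
                 scores = obj$scores %||% list(),
                 metadata = obj$metadata %||% list()),
            class = "rp_route")
}

#' Write a route collection as newline-delimited JSON
#' @param routes list of `rp_route`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_routes <- function(routes, path) {
  writeLines(vapply(routes, route_to_json, ""), path)
  invisible(path)
}

#' Read a route collection from newline-delimited JSON
#' @param path input path.
#' @return list of `rp_route`.
#' @export
read_routes <- function(path) {
  ln <- readLines(path, warn = FALSE)
  lapply(ln[nzchar(ln)], route_from_json)
}

# ---------------------------------------------------------------------------
# similarity metrics

# set of target-atom disconnection keys of a route
.route_disconnections <- function(route) {
  unique(unlist(lapply(route_reactions(route),
                       function(rx) rx$node$broken))) %||% character(0)
}

# target-atom (map number) set of a molecule node
.node_map_set <- function(nd) {
  m <- parse_smiles(nd$smiles)
  m$map[m$map > 0L]
}

.jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Similarity between two routes for the same target
#'
#' The mean of a bond component and an atom component.  The bond component
#' is the Jaccard overlap of the two routes' target-atom disconnection
#' sets.  The atom component compares the partitions of target atoms
#' induced by the two routes' leaf molecules: each leaf is matched to its
#' best Jaccard counterpart in the other route and the matched scores are
#' summed in both directions, normalized by the TOTAL number of molecule
#' nodes in both routes.  Molecules carrying no target atoms count in the
#' normalization but cannot contribute, so even the self-similarity of a
#' multi-step route is below one -- a documented quirk of this family of
#' metrics.
#'
#' @param r1,r2 `rp_route` objects sharing a target.
#' @return numeric in [0, 1]; symmetric.
#' @export
route_similarity <- function(r1, r2) {
  t1 <- mol_identity(parse_smiles(r1$tree$smiles))
  t2 <- mol_identity(parse_smiles(r2$tree$smiles))
  if (!identical(t1, t2))
    stop("incomparable routes: different target molecules", call. = FALSE)
  b1 <- .route_disconnections(r1); b2 <- .route_disconnections(r2)
  bond_sim <- .jaccard(b1, b2)
  tmaps <- .node_map_set(r1$tree)   # only target-identified atoms count
  L1 <- lapply(route_leaves(r1), function(l)
    intersect(.node_map_set(l), tmaps))
  L2 <- lapply(route_leaves(r2), function(l)
    intersect(.node_map_set(l), tmaps))
  best <- function(a, Bs) {
    if (!length(a) || !length(Bs)) return(0)
    max(vapply(Bs, function(b)
      if (!length(b)) 0 else length(intersect(a, b)) / length(union(a, b)),
      0))
  }
  n_tot <- length(route_mol_nodes(r1)) + length(route_mol_nodes(r2))
  atom_sim <- (sum(vapply(L1, best, 0, Bs = L2)) +
                 sum(vapply(L2, best, 0, Bs = L1))) / n_tot
  (bond_sim + atom_sim) / 2
}

#' Dissimilarity of a route set to a reference set
#'
#' `1 - mean over routes of the maximum similarity to any reference route`:
#' the average dissimilarity between each route and its most similar
#' reference route.
#'
#' @param routes,reference_routes non-empty lists of `rp_route` sharing a
#'   target.
#' @return numeric in [0, 1].
#' @export
dissimilarity_to_reference <- function(routes, reference_routes) {
  if (!length(routes) || !length(reference_routes))
    stop("both route sets must be non-empty", call. = FALSE)
  zmax <- vapply(routes, function(r)
    max(vapply(reference_routes, route_similarity, 0, r1 = r)), 0)
  1 - mean(zmax)
}

#' Diversity of a route set
#'
#' `1 - mean over routes of the minimum similarity to the other routes of
#' the set`: the average dissimilarity between each route and its least
#' similar companion.
#'
#' @param routes list of at least two `rp_route`.
#' @return numeric in [0, 1].
#' @export
route_diversity <- function(routes) {
  if (length(routes) < 2L)
    stop("diversity needs at least two routes", call. = FALSE)
  zmin <- vapply(seq_along(routes), function(i)
    min(vapply(routes[-i], route_similarity, 0, r1 = routes[[i]])), 0)
  1 - mean(zmin)
}
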