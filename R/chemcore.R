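# Bond identity and constraint layer.
#
# Bond constraints are anchored on atom-map numbers, which persist through
# template rewrites, so a bond keeps its identity across every step of a
# route.  A BondKey is the unordered pair of map numbers "i-j" (i < j);
# map number 0 is reserved for unmapped atoms, which never participate in
# constraint logic.

#' Build a bond key from two atom-map numbers
#'
#' @param i,j positive atom-map numbers (order irrelevant).
#' @return Character scalar "i-j" with i < j.
#' @examples bond_key(3, 1)
#' @export
bond_key <- function(i, j) {
  i <- as.integer(i); j <- as.integer(j)
  if (any(is.na(c(i, j))) || i <= 0L || j <= 0L)
    stop("map numbers must be positive integers (0 is reserved)",
         call. = FALSE)
  if (i == j) stop("a bond key needs two distinct atoms", call. = FALSE)
  paste0(min(i, j), "-", max(i, j))
}

.keys_from_pairs <- function(pairs) {
  if (is.null(pairs) || !length(pairs)) return(character(0))
  if (is.matrix(pairs)) pairs <- lapply(seq_len(nrow(pairs)),
                                        function(r) pairs[r, ])
  if (!is.list(pairs)) pairs <- list(pairs)
  unique(vapply(pairs, function(p) bond_key(p[1], p[2]), character(1)))
}

#' Bond keys realized in a molecule
#'
#' All bonds whose two endpoints both carry atom-map numbers, as bond keys.
#'
#' @param mol an `rp_mol`.
#' @return character vector of bond keys.
#' @export
mapped_bonds <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(character(0))
  ma <- mol$map[b[, 1]]; mb <- mol$map[b[, 2]]
  keep <- ma > 0L & mb > 0L
  if (!any(keep)) return(character(0))
  vapply(which(keep), function(k) bond_key(ma[k], mb[k]), character(1))
}

#' Construct a constraint set
#'
#' @param bonds_to_break,bonds_to_freeze bond keys (character "i-j") or
#'   lists/matrices of map-number pairs.
#' @param target optional `rp_mol`; when given, every key must correspond to
#'   an existing bond of the target.
#' @return An object of class `rp_constraints` with elements `break` and
#'   `freeze`.
#' @export
constraint_set <- function(bonds_to_break = NULL, bonds_to_freeze = NULL,
                           target = NULL) {
  brk <- if (is.character(bonds_to_break)) unique(bonds_to_break)
         else .keys_from_pairs(bonds_to_break)
  frz <- if (is.character(bonds_to_freeze)) unique(bonds_to_freeze)
         else .keys_from_pairs(bonds_to_freeze)
  both <- intersect(brk, frz)
  if (length(both))
    stop("conflicting constraints: bond(s) ", paste(both, collapse = ", "),
         " declared both to break and to freeze", call. = FALSE)
  if (!is.null(target)) {
    have <- mapped_bonds(target)
    missing <- setdiff(c(brk, frz), have)
    if (length(missing))
      stop("constraint error: no such mapped bond(s) in target: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list("break" = sort(brk), freeze = sort(frz)),
            class = "rp_constraints")
}

#' @export
print.rp_constraints <- function(x, ...) {
  cat("<rp_constraints> break: {", paste(x$`break`, collapse = ", "),
      "}  freeze: {", paste(x$freeze, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Parse a target molecule together with its bond constraints
#'
#' Accepts either explicit map-number pairs on a (partially) atom-mapped
#' SMILES, or the "!" tag dialect where both atoms of each bond to break
#' carry a `!` suffix.  Tagged atoms are converted to auto-assigned map
#' numbers, and every bond between two tagged atoms becomes one bond to
#' break.  All remaining heavy atoms then receive fresh map numbers so the
#' whole target is tracked through the route (needed for route similarity
#' and for disconnection-aware expansion).
#'
#' @param text SMILES of the target, with atom maps and/or "!" tags.
#' @param break_pairs,freeze_pairs optional lists of map-number pairs (or
#'   character bond keys) declaring bonds to break / freeze.
#' @return list with elements `mol` (fully mapped `rp_mol`) and
#'   `constraints` (`rp_constraints`).
#' @examples
#' parse_target("[CH3:10][C:1](=[O:2])[NH:3][CH3:11]",
#'               break_pairs = list(c(1, 3)))
#' parse_target("CC(=O)!N!C")
#' @export
parse_target <- function(text, break_pairs = NULL, freeze_pairs = NULL) {
  mol <- parse_smiles(text)
  # auto-map: tagged atoms first, then everything unmapped
  nxt <- max(0L, mol$map) + 1L
  for (i in seq_len(mol$n)) {
    if (mol$map[i] == 0L) { mol$map[i] <- nxt; nxt <- nxt + 1L }
  }
  mol$cache <- new.env(parent = emptyenv())
  tag_breaks <- character(0)
  if (any(mol$tag)) {
    tb <- mol$bonds
    for (k in seq_len(nrow(tb))) {
      a <- tb[k, 1]; b <- tb[k, 2]
      if (mol$tag[a] && mol$tag[b])
        tag_breaks <- c(tag_breaks, bond_key(mol$map[a], mol$map[b]))
    }
    if (!length(tag_breaks))
      stop("constraint error: '!'-tagged atoms do not form any bond",
           call. = FALSE)
    mol$tag <- rep(FALSE, mol$n)
  }
  brk <- unique(c(tag_breaks,
                  if (is.character(break_pairs)) break_pairs
                  else .keys_from_pairs(break_pairs)))
  frz <- if (is.character(freeze_pairs)) freeze_pairs
         else .keys_from_pairs(freeze_pairs)
  cs <- constraint_set(brk, frz, target = mol)
  list(mol = mol, constraints = cs)
}

#' Bonds broken by a retro reaction
#'
#' A mapped product bond i-j is broken when no single reactant contains a
#' bond between map numbers i and j -- whether the two atoms end up in
#' different reactants or the bond is simply severed inside one reactant
#' (ring opening).  A bond whose order changes but which persists is not
#' broken: constraints track disconnections, not order changes.
#'
#' @param product `rp_mol` with atom maps.
#' @param reactants list of `rp_mol` carrying the propagated maps.
#' @return character vector of broken bond keys.
#' @export
broken_bonds <- function(product, reactants) {
  if (inherits(reactants, "rp_mol")) reactants <- list(reactants)
  pmaps <- product$map[product$map > 0L]
  rmaps <- unlist(lapply(reactants, function(m) m$map[m$map > 0L]))
  lost <- setdiff(pmaps, rmaps)
  if (length(lost))
    stop("mapping-loss error: map number(s) ",
         paste(lost, collapse = ", "),
         " present in product but absent from all reactants", call. = FALSE)
  pb <- mapped_bonds(product)
  if (!length(pb)) return(character(0))
  rb <- unique(unlist(lapply(reactants, mapped_bonds)))
  sort(setdiff(pb, rb))
}

#' Does a retro step violate any frozen bond?
#'
#' @param step an `rp_step` (or any list with a `broken` field of bond keys).
#' @param freeze character vector of frozen bond keys.
#' @return TRUE iff the step's broken set intersects the freeze set.
#' @export
violates_freeze <- function(step, freeze) {
  length(intersect(step$broken, freeze)) > 0L
}
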