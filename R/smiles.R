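# Molecular graph layer: a compact SMILES dialect with atom maps.
#
# The dialect covers the neutral organic subset (B, C, N, O, P, S, F, Cl,
# Br, I; aromatic c, n, o, s), single/double/triple/aromatic bonds, ring
# closures (1-9 and %nn), branches, bracket atoms with explicit hydrogen
# counts and atom-map numbers ([NH2:3]), and a "!" suffix marking atoms of
# bonds to break.  No charges, no isotopes, no stereodescriptors: bond
# constraints and template rewrites are constitutional, and every molecule
# the package manipulates lives in this subset.

.RP_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                 F = 1, Cl = 1, Br = 1, I = 1)
.RP_ORGANIC <- names(.RP_VALENCE)
.RP_AROMATIC_OK <- c("C", "N", "O", "S")

#' Construct a molecule object from parsed atom and bond tables
#'
#' Internal constructor; users normally call [parse_smiles()].
#'
#' @param element character vector of element symbols.
#' @param aromatic logical vector, one per atom.
#' @param hcount integer vector of hydrogen counts (NA = derive from the
#'   valence model).
#' @param map integer vector of atom-map numbers (0 = unmapped).
#' @param tag logical vector, TRUE for atoms carrying a "!" break tag.
#' @param bonds 3-column numeric matrix (a, b, order) with order 1, 2, 3 or
#'   1.5 for aromatic bonds.
#' @param hexplicit logical vector, TRUE where hcount was written explicitly
#'   (kept for pattern semantics).
#' @return An object of class `rp_mol`.
#' @keywords internal
new_mol <- function(element, aromatic, hcount, map, tag, bonds,
                    hexplicit = rep(FALSE, length(element))) {
  n <- length(element)
  stopifnot(length(aromatic) == n, length(map) == n)
  if (is.null(dim(bonds))) bonds <- matrix(bonds, ncol = 3)
  storage.mode(bonds) <- "double"
  colnames(bonds) <- c("a", "b", "order")
  m <- list(element = as.character(element), aromatic = as.logical(aromatic),
            hcount = as.integer(hcount), map = as.integer(map),
            tag = as.logical(tag), hexplicit = as.logical(hexplicit),
            bonds = bonds, n = n, cache = new.env(parent = emptyenv()))
  class(m) <- "rp_mol"
  m <- derive_hydrogens(m)
  m
}

#' @export
print.rp_mol <- function(x, ...) {
  cat("<rp_mol> ", write_smiles(x), "  (", x$n, " atoms, ",
      nrow(x$bonds), " bonds)\n", sep = "")
  invisible(x)
}

# bond order sum per atom (aromatic bonds count 1.5)
.bond_order_sums <- function(mol) {
  s <- numeric(mol$n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds[k, 3]
      s[mol$bonds[k, 1]] <- s[mol$bonds[k, 1]] + o
      s[mol$bonds[k, 2]] <- s[mol$bonds[k, 2]] + o
    }
  }
  s
}

# Fill NA hydrogen counts from the valence model and validate the rest.
derive_hydrogens <- function(mol) {
  s <- .bond_order_sums(mol)
  need <- is.na(mol$hcount)
  if (any(need)) {
    val <- .RP_VALENCE[mol$element[need]]
    h <- as.integer(val - round(s[need]))
    if (any(h < -0.5))
      stop("valence exceeded for atom(s) ",
           paste(which(need)[h < 0], collapse = ", "), call. = FALSE)
    h[h < 0] <- 0L
    mol$hcount[need] <- h
  }
  mol
}

# hydrogen count the valence model would assign (for bracket elision)
.default_h <- function(mol) {
  s <- .bond_order_sums(mol)
  as.integer(pmax(0, .RP_VALENCE[mol$element] - round(s)))
}

#' Parse a SMILES string in the package dialect
#'
#' @param text SMILES string.  Atom maps `[C:1]` and the `!` break-tag
#'   suffix are accepted.
#' @return An `rp_mol` object.
#' @param pattern parse as a template pattern?  In pattern mode a bracket
#'   atom without an explicit `H` count leaves the hydrogen count
#'   unconstrained instead of pinning it to zero.
#' @examples
#' parse_smiles("CC(=O)Nc1ccccc1")
#' parse_smiles("[CH3:10][C:1](=[O:2])[NH:3][CH3:11]")
#' @export
parse_smiles <- function(text, pattern = FALSE) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text))
    stop("SMILES must be a single non-empty string", call. = FALSE)
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(ch)

  el <- character(); ar <- logical(); hc <- integer(); mp <- integer()
  tg <- logical(); hx <- logical()
  ba <- integer(); bb <- integer(); bo <- numeric(); bdef <- logical()
  prev <- NA_integer_
  pend <- NA_real_
  stack <- integer()
  ring <- list()        # digit -> list(atom, order)

  bail <- function(msg, pos) {
    stop(sprintf("invalid SMILES %s at position %d: %s",
                 sQuote(text), pos, msg), call. = FALSE)
  }
  add_bond <- function(i, j, order, was_default) {
    ba[length(ba) + 1L] <<- i; bb[length(bb) + 1L] <<- j
    bo[length(bo) + 1L] <<- order
    bdef[length(bdef) + 1L] <<- was_default
  }
  add_atom <- function(e, arom, h, map, tag, hexp) {
    el[length(el) + 1L] <<- e; ar[length(ar) + 1L] <<- arom
    hc[length(hc) + 1L] <<- h; mp[length(mp) + 1L] <<- map
    tg[length(tg) + 1L] <<- tag; hx[length(hx) + 1L] <<- hexp
    idx <- length(el)
    if (!is.na(prev)) {
      if (!is.na(pend)) add_bond(prev, idx, pend, FALSE)
      else if (ar[prev] && arom) add_bond(prev, idx, 1.5, TRUE)
      else add_bond(prev, idx, 1, FALSE)
    }
    prev <<- idx
    pend <<- NA_real_
    idx
  }

  i <- 1L
  while (i <= n) {
    c1 <- ch[i]
    if (c1 == " ") { i <- i + 1L; next }
    if (c1 %in% c("-", "=", "#", ":", "/", "\\")) {
      pend <- switch(c1, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5, 1)
      i <- i + 1L; next
    }
    if (c1 == "(") {
      if (is.na(prev)) bail("branch before any atom", i)
      stack <- c(stack, prev); i <- i + 1L; next
    }
    if (c1 == ")") {
      if (!length(stack)) bail("unmatched ')'", i)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (grepl("[0-9]", c1) || c1 == "%") {
      if (c1 == "%") {
        if (i + 2L > n) bail("truncated %nn ring closure", i)
        digit <- paste0(ch[i + 1L], ch[i + 2L]); i <- i + 3L
      } else { digit <- c1; i <- i + 1L }
      if (is.na(prev)) bail("ring closure before any atom", i)
      if (is.null(ring[[digit]])) {
        ring[[digit]] <- list(atom = prev, order = pend)
      } else {
        op <- ring[[digit]]
        o <- if (!is.na(pend)) pend else if (!is.na(op$order)) op$order
             else NA_real_
        if (!is.na(pend) && !is.na(op$order) && pend != op$order)
          bail("conflicting ring-closure bond orders", i)
        wasdef <- is.na(o)
        if (is.na(o)) o <- if (ar[op$atom] && ar[prev]) 1.5 else 1
        add_bond(op$atom, prev, o, wasdef)
        ring[[digit]] <- NULL
      }
      pend <- NA_real_
      next
    }
    if (c1 == "!") {
      if (is.na(prev)) bail("'!' before any atom", i)
      tg[prev] <- TRUE; i <- i + 1L; next
    }
    if (c1 == "[") {
      j <- i + 1L
      while (j <= n && ch[j] != "]") j <- j + 1L
      if (j > n) bail("unclosed bracket atom", i)
      body <- paste0(ch[(i + 1L):(j - 1L)], collapse = "")
      mm <- regmatches(body, regexec(
        "^([A-IK-PR-Zb-ik-pr-z][a-z]?)(H([0-9]*))?(:([0-9]+))?$", body))[[1]]
      if (!length(mm)) bail(sprintf("unparseable bracket atom [%s]", body), i)
      sym <- mm[2]
      arom <- sym == tolower(sym)
      e <- if (arom) paste0(toupper(substr(sym, 1, 1)),
                            substring(sym, 2)) else sym
      if (!e %in% .RP_ORGANIC)
        bail(sprintf("unsupported element '%s'", sym), i)
      if (arom && !e %in% .RP_AROMATIC_OK)
        bail(sprintf("'%s' cannot be aromatic", sym), i)
      hgiven <- nzchar(mm[3])
      h <- if (hgiven) { if (nzchar(mm[4])) as.integer(mm[4]) else 1L
           } else if (pattern) NA_integer_ else 0L
      map <- if (nzchar(mm[6])) as.integer(mm[6]) else 0L
      if (!is.na(map) && map < 0L) bail("negative map number", i)
      add_atom(e, arom, h, map, FALSE, if (pattern) hgiven else TRUE)
      i <- j + 1L
      next
    }
    # organic-subset atom, possibly two characters (Cl, Br)
    two <- if (i < n) paste0(c1, ch[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      add_atom(two, FALSE, NA_integer_, 0L, FALSE, FALSE)
      i <- i + 2L; next
    }
    if (c1 %in% .RP_ORGANIC) {
      add_atom(c1, FALSE, NA_integer_, 0L, FALSE, FALSE)
      i <- i + 1L; next
    }
    if (c1 %in% c("c", "n", "o", "s")) {
      add_atom(toupper(c1), TRUE, NA_integer_, 0L, FALSE, FALSE)
      i <- i + 1L; next
    }
    bail(sprintf("unexpected character '%s'", c1), i)
  }
  if (length(stack)) bail("unclosed branch", n)
  if (length(ring)) bail("unclosed ring bond(s)", n)
  if (!length(el)) bail("no atoms", 1L)
  dup <- mp[mp > 0]
  if (anyDuplicated(dup))
    stop("duplicate atom-map number(s): ",
         paste(unique(dup[duplicated(dup)]), collapse = ", "), call. = FALSE)

  bonds <- cbind(a = ba, b = bb, order = bo)
  # default bonds between two aromatic atoms are aromatic only inside rings;
  # chain bonds (e.g. biphenyl written without "-") demote to single
  if (length(bdef) && any(bdef)) {
    for (k in which(bdef)) {
      if (bonds[k, 3] == 1.5 && !.bond_in_ring(length(el), bonds, k))
        bonds[k, 3] <- 1
    }
  }
  new_mol(el, ar, hc, mp, tg, bonds, hx)
}

# is bond k part of a cycle?  (endpoints stay connected without it)
.bond_in_ring <- function(n, bonds, k) {
  a <- bonds[k, 1]; b <- bonds[k, 2]
  adj <- vector("list", n)
  for (j in seq_len(nrow(bonds))) {
    if (j == k) next
    adj[[bonds[j, 1]]] <- c(adj[[bonds[j, 1]]], bonds[j, 2])
    adj[[bonds[j, 2]]] <- c(adj[[bonds[j, 2]]], bonds[j, 1])
  }
  seen <- logical(n); queue <- a; seen[a] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  seen[b]
}

# ---------------------------------------------------------------------------
# canonicalization

# dense rank of a character key vector
.dense_rank <- function(key) match(key, sort(unique(key)))

.adjacency <- function(mol) {
  adj <- vector("list", mol$n)
  ords <- vector("list", mol$n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- as.integer(mol$bonds[k, 1]); b <- as.integer(mol$bonds[k, 2])
      o <- mol$bonds[k, 3]
      adj[[a]] <- c(adj[[a]], b); ords[[a]] <- c(ords[[a]], o)
      adj[[b]] <- c(adj[[b]], a); ords[[b]] <- c(ords[[b]], o)
    }
  }
  list(nbr = adj, ord = ords)
}

.refine_ranks <- function(mol, ranks, adj) {
  repeat {
    sig <- vapply(seq_len(mol$n), function(i) {
      nb <- adj$nbr[[i]]
      if (!length(nb)) return("")
      paste(sort(sprintf("%04d/%.1f", ranks[nb], adj$ord[[i]])),
            collapse = ",")
    }, character(1))
    new <- .dense_rank(sprintf("%04d|%s", ranks, sig))
    if (max(new) == max(ranks) && all(new == ranks)) return(ranks)
    if (max(new) == max(ranks)) return(new)
    ranks <- new
  }
}

.initial_ranks <- function(mol, adj) {
  deg <- lengths(adj$nbr)
  bs <- .bond_order_sums(mol)
  .dense_rank(sprintf("%s|%d|%d|%d|%.1f", mol$element, mol$aromatic,
                      deg, mol$hcount, bs))
}

# canonical SMILES via invariant refinement with branching tie-break
.canon_string <- function(mol, ranks, adj, with_maps) {
  ranks <- .refine_ranks(mol, ranks, adj)
  if (max(ranks) == mol$n)
    return(.write_from_ranks(mol, ranks, adj, with_maps))
  tied <- which(ranks == min(ranks[duplicated(ranks) |
                                     duplicated(ranks, fromLast = TRUE)]))
  best <- NULL
  for (a in tied) {
    r2 <- ranks + as.integer(ranks > ranks[a] |
                               (ranks == ranks[a] & seq_len(mol$n) != a))
    # individualize a: keep its rank, push the rest of its class up
    r2 <- .dense_rank(sprintf("%04d", r2))
    s <- .canon_string(mol, r2, adj, with_maps)
    if (is.null(best) || s < best) best <- s
  }
  best
}

.atom_token <- function(mol, i, with_maps) {
  e <- mol$element[i]
  sym <- if (mol$aromatic[i]) tolower(e) else e
  map <- if (with_maps) mol$map[i] else 0L
  needs <- map > 0L || mol$hcount[i] != .default_h(mol)[i]
  if (!needs) return(sym)
  h <- mol$hcount[i]
  paste0("[", sym,
         if (h == 1L) "H" else if (h > 1L) paste0("H", h) else "",
         if (map > 0L) paste0(":", map) else "", "]")
}

.bond_token <- function(mol, a, b, order) {
  if (order == 2) return("=")
  if (order == 3) return("#")
  if (order == 1.5) {
    if (mol$aromatic[a] && mol$aromatic[b]) return("") else return(":")
  }
  if (mol$aromatic[a] && mol$aromatic[b]) return("-")
  ""
}

.write_from_ranks <- function(mol, ranks, adj, with_maps) {
  n <- mol$n
  dh <- .default_h(mol)
  visited <- logical(n)
  order_visit <- integer(0)
  parent <- rep(NA_integer_, n)
  # DFS to classify tree/ring edges, neighbors in rank order
  ring_open <- list()   # per atom: list of c(partner, order, digit)
  ring_close <- list()
  ring_count <- 0L
  tree_children <- vector("list", n)
  dfs <- function(u) {
    visited[u] <<- TRUE
    order_visit[length(order_visit) + 1L] <<- u
    nb <- adj$nbr[[u]]; os <- adj$ord[[u]]
    ix <- order(ranks[nb])
    for (t in ix) {
      v <- nb[t]; o <- os[t]
      if (!visited[v]) {
        parent[v] <<- u
        tree_children[[u]] <<- c(tree_children[[u]], v)
        dfs(v)
      } else if (!identical(parent[u], v)) {
        # back edge, record once (at the later-visited endpoint u)
        already <- any(vapply(c(ring_close[[as.character(u)]] %||% list(),
                                ring_open[[as.character(u)]] %||% list()),
                              function(z) z[1] == v, logical(1)))
        if (!already) {
          ring_count <<- ring_count + 1L
          ring_open[[as.character(v)]] <<-
            c(ring_open[[as.character(v)]] %||% list(),
              list(c(u, o, ring_count)))
          ring_close[[as.character(u)]] <<-
            c(ring_close[[as.character(u)]] %||% list(),
              list(c(v, o, ring_count)))
        }
      }
    }
  }
  start <- which.min(ranks)
  dfs(start)
  if (!all(visited))
    stop("disconnected molecule cannot be written as one SMILES",
         call. = FALSE)

  digit_tok <- function(d) if (d < 10) as.character(d) else sprintf("%%%02d", d)
  emit <- function(u) {
    out <- .atom_token(mol, u, with_maps)
    for (z in ring_open[[as.character(u)]] %||% list())
      out <- paste0(out, .bond_token(mol, u, z[1], z[2]), digit_tok(z[3]))
    for (z in ring_close[[as.character(u)]] %||% list())
      out <- paste0(out, .bond_token(mol, u, z[1], z[2]), digit_tok(z[3]))
    kids <- tree_children[[u]]
    if (length(kids)) {
      for (t in seq_along(kids)) {
        v <- kids[t]
        ko <- adj$ord[[u]][match(v, adj$nbr[[u]])]
        sub <- paste0(.bond_token(mol, u, v, ko), emit(v))
        out <- if (t < length(kids)) paste0(out, "(", sub, ")")
               else paste0(out, sub)
      }
    }
    out
  }
  emit(start)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a molecule as SMILES (non-canonical, parse order)
#' @param mol an `rp_mol`.
#' @param with_maps keep atom-map numbers?
#' @return SMILES string.
#' @export
write_smiles <- function(mol, with_maps = TRUE) {
  canonical_smiles(mol, with_maps = with_maps)
}

#' Canonical SMILES for a molecule
#'
#' Canonical ranks come from iterative invariant refinement (element,
#' aromaticity, degree, hydrogen count, bond-order sum, then neighbour rank
#' multisets), with remaining ties resolved by branching individualization
#' and taking the lexicographically smallest output, so the result is
#' independent of input atom order.  Atom-map numbers ride along with their
#' atoms and do not influence the ranks.
#'
#' @param mol an `rp_mol`.
#' @param with_maps include atom-map numbers in the output?
#' @return SMILES string.
#' @export
canonical_smiles <- function(mol, with_maps = TRUE) {
  key <- if (with_maps) "canon_maps" else "canon_plain"
  hit <- mol$cache[[key]]
  if (!is.null(hit)) return(hit)
  adj <- .adjacency(mol)
  s <- .canon_string(mol, .initial_ranks(mol, adj), adj, with_maps)
  assign(key, s, envir = mol$cache)
  s
}

#' Identity token for stock membership
#'
#' Canonical SMILES with atom maps stripped: two molecules with the same
#' connectivity but different constraint maps share one identity, so bond
#' constraints never affect stock lookup.
#'
#' @param mol an `rp_mol`.
#' @return character identity token.
#' @export
mol_identity <- function(mol) canonical_smiles(mol, with_maps = FALSE)

#' Number of heavy atoms in a molecule
#' @param mol an `rp_mol`.
#' @return integer count.
#' @export
heavy_atoms <- function(mol) mol$n

# connected components as a list of rp_mol (maps preserved); used to split
# rewrite products into reactants
split_components <- function(mol) {
  n <- mol$n
  comp <- integer(n)
  cur <- 0L
  adj <- .adjacency(mol)$nbr
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur
        queue <- c(queue, w) }
    }
  }
  lapply(seq_len(cur), function(ci) {
    keep <- which(comp == ci)
    idx <- match(seq_len(n), keep)
    bm <- mol$bonds[comp[mol$bonds[, 1]] == ci, , drop = FALSE]
    if (nrow(bm)) {
      bm[, 1] <- idx[bm[, 1]]; bm[, 2] <- idx[bm[, 2]]
    }
    new_mol(mol$element[keep], mol$aromatic[keep], mol$hcount[keep],
            mol$map[keep], mol$tag[keep], bm)
  })
}

# igraph representation with vertex/edge colors for VF2 matching (cached)
mol_graph <- function(mol) {
  hit <- mol$cache[["graph"]]
  if (!is.null(hit)) return(hit)
  g <- igraph::make_empty_graph(n = mol$n, directed = FALSE)
  if (nrow(mol$bonds))
    g <- igraph::add_edges(g, as.integer(t(mol$bonds[, 1:2, drop = FALSE])))
  vc <- match(mol$element, .RP_ORGANIC) * 2L + as.integer(mol$aromatic)
  ec <- as.integer(mol$bonds[, 3] * 2)    # 2,3(aromatic),4,6
  out <- list(g = g, vcol = vc, ecol = ec)
  assign("graph", out, envir = mol$cache)
  out
}
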