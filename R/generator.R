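# Synthetic benchmark generator: a toy retro-template library, a stock of
# building blocks, and targets forward-composed from the stock through the
# template inverses, so every target carries a planted, solved reference
# route.  Atom provenance is tracked with unique ids through every
# composition, which anchors the planted bonds in the final target's map
# space.

#' Default retro-template library of the synthetic benchmark
#'
#' Six classic disconnections (amide coupling, ester formation, Suzuki
#' aryl-aryl coupling, aromatic substitution, reductive amination,
#' Williamson ether formation) as mapped rewrite rules with prior weights.
#'
#' @return `rp_template_library`.
#' @export
default_template_library <- function() {
  template_library(data.frame(
    name = c("amide_coupling", "ester_formation", "suzuki_coupling",
             "aromatic_substitution", "reductive_amination",
             "ether_formation"),
    retro_smarts = c(
      "[C:1](=[O:2])[N:3]>>[C:1](=[O:2])O.[N:3]",
      "[C:1](=[O:2])[O:3][C:4]>>[C:1](=[O:2])O.[O:3][C:4]",
      "[c:1]-[c:2]>>[c:1]Br.[c:2]B(O)O",
      "[c:1][N:2]>>[c:1]Cl.[N:2]",
      "[CH2:1][N:2]>>[C:1]=O.[N:2]",
      "[c:1][O:2][CH2:3]>>[c:1][O:2].Br[CH2:3]"),
    prior_weight = c(3, 2, 2, 1.5, 1.5, 1),
    reaction_class = c("acylation", "acylation", "coupling",
                       "substitution", "amination", "substitution"),
    stringsAsFactors = FALSE))
}

#' Default building blocks of the synthetic benchmark
#' @return character vector of SMILES.
#' @export
default_building_blocks <- function() {
  c(# carboxylic acids
    "CC(=O)O", "CCC(=O)O", "CC(C)C(=O)O", "OC(=O)c1ccccc1",
    "OC(=O)c1ccc(C)cc1", "OC(=O)CCc1ccccc1", "OC(=O)C1CCCC1",
    # amines
    "CN", "CCN", "CCCN", "CC(C)N", "Nc1ccccc1", "NCc1ccccc1",
    "C1CCNCC1", "C1COCCN1", "CNC", "NCCc1ccccc1",
    # alcohols
    "CO", "CCO", "CC(C)O", "OCC1CCCC1", "OCCc1ccccc1",
    # phenols
    "Oc1ccccc1", "Cc1ccc(O)cc1", "Oc1ccc(F)cc1",
    # aryl bromides
    "Brc1ccccc1", "Cc1ccc(Br)cc1", "Brc1ccc(F)cc1", "Brc1ccc(OC)cc1",
    # arylboronic acids
    "OB(O)c1ccccc1", "OB(O)c1ccc(C)cc1", "OB(O)c1ccc(F)cc1",
    # activated aryl chlorides
    "Clc1ccncc1", "Clc1ncccc1", "Cc1cc(Cl)ncc1",
    # aldehydes
    "CC=O", "CCC=O", "O=Cc1ccccc1", "O=Cc1ccc(C)cc1",
    # alkyl bromides
    "CCBr", "CCCBr", "BrCc1ccccc1", "BrCCc1ccccc1",
    # bifunctional linkers (keep multi-step compositions alive)
    "Nc1ccc(cc1)C(=O)O", "OC(=O)c1ccc(Br)cc1", "O=Cc1ccc(Br)cc1",
    "Oc1ccc(Br)cc1", "NCCO", "OCc1ccc(Br)cc1", "Nc1ccc(cc1)B(O)O",
    "OC(=O)c1ccc(Cl)nc1", "CNCc1ccc(Br)cc1", "OB(O)c1ccc(C=O)cc1",
    # blocks with internal cleavable motifs (alternative disconnections)
    "CC(=O)Nc1ccc(Br)cc1", "COC(=O)c1ccc(Br)cc1", "COc1ccc(B(O)O)cc1",
    "CCOC(=O)c1ccc(N)cc1", "CC(=O)NCCC(=O)O", "COc1ccc(C=O)cc1",
    "CC(=O)Nc1ccc(C=O)cc1")
}

# functional-group patterns; list position of each template map = role
.FG_PATTERNS <- list(
  acid     = "[C:1](=[O:2])[OH1:3]",
  amine1   = "[NH2:1]",
  amine2   = "[NH1:1]",
  alcohol  = "[C:1][OH1:2]",
  phenol   = "[c:1][OH1:2]",
  aldehyde = "[CH1:1]=[O:2]",
  aryl_br  = "[c:1][Br:2]",
  alkyl_br = "[CH2:1][Br:2]",
  boronic  = "[c:1][B:2]([OH1:3])[OH1:4]",
  aryl_cl  = "[c:1][Cl:2]")

.fg_pattern_mols <- function() {
  hit <- .expansion_cache[[".fg_patterns"]]
  if (!is.null(hit)) return(hit)
  pm <- lapply(.FG_PATTERNS, parse_smiles, pattern = TRUE)
  assign(".fg_patterns", pm, envir = .expansion_cache)
  pm
}

# neighbor test: is atom i adjacent to a carbonyl carbon?
.next_to_carbonyl <- function(mol, i) {
  b <- mol$bonds
  nb <- c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
  for (c in nb) {
    if (mol$element[c] != "C" || mol$aromatic[c]) next
    cb <- b[(b[, 1] == c | b[, 2] == c) & b[, 3] == 2, , drop = FALSE]
    for (k in seq_len(nrow(cb))) {
      other <- if (cb[k, 1] == c) cb[k, 2] else cb[k, 1]
      if (mol$element[other] == "O") return(TRUE)
    }
  }
  FALSE
}

# find functional groups: list of integer vectors (position = template map)
find_fg <- function(mol, fg) {
  pats <- .fg_pattern_mols()
  pnames <- if (fg == "amine") c("amine1", "amine2") else fg
  out <- list()
  for (pn in pnames) {
    pat <- pats[[pn]]
    for (emb in pattern_embeddings(pat, mol)) {
      atoms <- integer(max(pat$map))
      for (q in seq_len(pat$n))
        if (pat$map[q] > 0L) atoms[pat$map[q]] <- emb[q]
      if (startsWith(pn, "amine")) {
        if (.next_to_carbonyl(mol, atoms[1])) next
      }
      if (pn == "alcohol" && .next_to_carbonyl(mol, atoms[2])) next
      if (pn == "alcohol") {
        # exclude the acid hydroxyl (C would be a carbonyl carbon)
        cb <- mol$bonds
        dbl <- cb[(cb[, 1] == atoms[1] | cb[, 2] == atoms[1]) &
                    cb[, 3] == 2, , drop = FALSE]
        if (nrow(dbl)) next
      }
      out[[length(out) + 1L]] <- atoms
    }
  }
  unique(out)
}

# forward recipes: (family, A-side fg, B-side fg)
.FORWARD_RECIPES <- list(
  amide_coupling        = c(a = "acid",     b = "amine"),
  ester_formation       = c(a = "acid",     b = "alcohol"),
  suzuki_coupling       = c(a = "aryl_br",  b = "boronic"),
  aromatic_substitution = c(a = "aryl_cl",  b = "amine"),
  reductive_amination   = c(a = "aldehyde", b = "amine"),
  ether_formation       = c(a = "phenol",   b = "alkyl_br"))

# merge two uid-tracked molecules with removals and one new bond
.merge_umols <- function(A, removeA, aA, B, removeB, aB, order = 1) {
  keepA <- setdiff(seq_len(A$mol$n), removeA)
  keepB <- setdiff(seq_len(B$mol$n), removeB)
  idxA <- match(seq_len(A$mol$n), keepA)
  idxB <- match(seq_len(B$mol$n), keepB)
  off <- length(keepA)
  fb <- function(m, keep, idx, offn) {
    b <- m$bonds
    if (!nrow(b)) return(b)
    ok <- b[, 1] %in% keep & b[, 2] %in% keep
    b <- b[ok, , drop = FALSE]
    if (nrow(b)) { b[, 1] <- idx[b[, 1]] + offn; b[, 2] <- idx[b[, 2]] + offn }
    b
  }
  bonds <- rbind(fb(A$mol, keepA, idxA, 0L), fb(B$mol, keepB, idxB, off),
                 c(idxA[aA], idxB[aB] + off, order))
  nA <- length(keepA); nB <- length(keepB)
  mol <- new_mol(c(A$mol$element[keepA], B$mol$element[keepB]),
                 c(A$mol$aromatic[keepA], B$mol$aromatic[keepB]),
                 rep(NA_integer_, nA + nB), rep(0L, nA + nB),
                 rep(FALSE, nA + nB), bonds)
  list(mol = mol, uid = c(A$uid[keepA], B$uid[keepB]),
       formed = c(A$uid[aA], B$uid[aB]))
}

# apply one forward recipe; fgA/fgB are matched atom vectors
.forward_apply <- function(family, A, fgA, B, fgB) {
  switch(family,
    amide_coupling = .merge_umols(A, fgA[3], fgA[1], B, integer(0), fgB[1]),
    ester_formation = .merge_umols(A, fgA[3], fgA[1], B, integer(0),
                                   fgB[2]),
    suzuki_coupling = .merge_umols(A, fgA[2], fgA[1], B, fgB[2:4], fgB[1]),
    aromatic_substitution = .merge_umols(A, fgA[2], fgA[1], B, integer(0),
                                         fgB[1]),
    reductive_amination = .merge_umols(A, fgA[2], fgA[1], B, integer(0),
                                       fgB[1]),
    ether_formation = .merge_umols(A, integer(0), fgA[2], B, fgB[2],
                                   fgB[1]),
    stop("unknown recipe ", family, call. = FALSE))
}

# fix NA hydrogens on merge (new_mol was given NA for every atom, which is
# exact for our block set: no explicit-H atoms survive merges)

.umol_from_smiles <- function(smiles, uid_start) {
  m <- parse_smiles(smiles)
  list(mol = m, uid = seq.int(uid_start, length.out = m$n))
}

# one random composition step: returns NULL when nothing is feasible
.random_step <- function(M, blocks_u, family_pool) {
  cand <- list()
  for (family in family_pool) {
    roles <- .FORWARD_RECIPES[[family]]
    fga_m <- find_fg(M$mol, roles["a"])
    fgb_m <- find_fg(M$mol, roles["b"])
    if (length(fga_m)) {
      for (bi in seq_along(blocks_u)) {
        fgb <- blocks_u[[bi]]$fg[[roles["b"]]]
        if (length(fgb))
          cand[[length(cand) + 1L]] <- list(family = family, side = "a",
                                            block = bi)
      }
    }
    if (length(fgb_m)) {
      for (bi in seq_along(blocks_u)) {
        fga <- blocks_u[[bi]]$fg[[roles["a"]]]
        if (length(fga))
          cand[[length(cand) + 1L]] <- list(family = family, side = "b",
                                            block = bi)
      }
    }
  }
  if (!length(cand)) return(NULL)
  cand[[sample.int(length(cand), 1L)]]
}

.pick <- function(lst) lst[[sample.int(length(lst), 1L)]]

#' Generate a synthetic benchmark fixture
#'
#' Forward-composes stock building blocks through the template inverses
#' into targets of the requested depths; every target carries a planted,
#' solved reference route and a constraint set extracted from it (bonds to
#' break from the reactions with maximal convergent disconnection score,
#' bonds to freeze sampled from the bonds unchanged along the whole route).
#' With `hidden = TRUE` the first (deepest) composition is forced to be
#' convergent, later steps attach small blocks, and the last intermediate
#' is added to the stock, so a short route that avoids the prompted bond
#' exists and constraint-satisfying routes are strictly longer.
#'
#' @param n_targets number of benchmark targets.
#' @param depth_range integer vector of allowed route depths (reactions).
#' @param seed integer seed; the fixture is a pure function of it.
#' @param hidden plant short decoy routes that skip the prompted bond?
#' @param n_break bonds to break per target (NULL = sample 1..3 capped at
#'   the route depth, mirroring realistic constraint counts).
#' @param n_freeze bonds to freeze (capped at n_break - 1).
#' @param library retro-template library (default [default_template_library()]).
#' @param blocks building-block SMILES (default [default_building_blocks()]).
#' @return list of class `rp_fixture` with elements `library`, `stock`,
#'   `targets` (list of `rp_benchmark_target`), `seed`.
#' @export
generate_fixture <- function(n_targets, depth_range = 1:3, seed = 1L,
                             hidden = FALSE, n_break = NULL, n_freeze = 1L,
                             library = default_template_library(),
                             blocks = default_building_blocks()) {
  stopifnot(n_targets >= 1, all(depth_range >= 1))
  if (hidden && any(depth_range < 2))
    stop("hidden fixtures need depth >= 2", call. = FALSE)
  set.seed(seed)
  blocks_u <- lapply(blocks, function(s) {
    u <- .umol_from_smiles(s, 1L)
    u$fg <- lapply(stats::setNames(nm = c("acid", "amine", "alcohol",
                                          "phenol", "aldehyde", "aryl_br",
                                          "alkyl_br", "boronic", "aryl_cl")),
                   function(f) find_fg(u$mol, f))
    u$size <- u$mol$n
    u
  })
  families <- names(.FORWARD_RECIPES)
  base_stock <- stock(blocks)
  extra_stock <- character(0)
  targets <- list()
  seen_targets <- character(0)
  tries <- 0L
  while (length(targets) < n_targets) {
    tries <- tries + 1L
    if (tries > 60L * n_targets)
      stop("generation error: could not compose enough distinct targets; ",
           "the requested depths may be infeasible for this library",
           call. = FALSE)
    depth <- if (length(depth_range) == 1L) depth_range
             else sample(depth_range, 1L)
    res <- NULL
    for (attempt in 1:25) {       # keep the drawn depth, retry composition
      res <- tryCatch(.compose_target(depth, blocks_u, families, hidden),
                      error = function(e) NULL)
      if (!is.null(res)) break
    }
    if (is.null(res)) next
    id <- mol_identity(res$M$mol)
    if (id %in% seen_targets || !is.null(base_stock$set[[id]])) next
    nb <- if (!is.null(n_break)) min(n_break, depth)
          else if (hidden) 1L
          else sample(seq_len(min(3L, depth)), 1L)
    nf <- max(0L, min(n_freeze, nb - 1L, length(.unchanged_keys(res))))
    tgt <- tryCatch(
      .finalize_target(res, nb, nf, seed_tag = seed, hidden = hidden),
      error = function(e) NULL)
    if (is.null(tgt)) next
    seen_targets <- c(seen_targets, id)
    if (hidden) {
      # plant decoy one-step routes: every depth-0 disconnection that
      # avoids the prompted bond gets its pieces added to the stock, so
      # short constraint-skipping routes outnumber the deep planted one
      dec <- Filter(function(s)
        !length(intersect(s$broken, tgt$constraints$`break`)),
        template_policy(tgt$target, library, k = 50))
      dec <- dec[seq_len(min(10L, length(dec)))]
      extra_stock <- c(extra_stock, tgt$hidden_intermediate,
                       unlist(lapply(dec, function(s)
                         vapply(s$reactants, mol_identity, ""))))
    }
    targets[[length(targets) + 1L]] <- tgt
  }
  stk <- stock(c(blocks, extra_stock))
  # reference-route in-stock flags and satisfaction checks need the final
  # stock, so routes are materialized last
  targets <- lapply(targets, function(tgt) {
    tgt$reference_route <- .build_reference_route(tgt, stk)
    if (!hidden && !is_solved(tgt$reference_route))
      stop("generation invariant violated: reference route unsolved",
           call. = FALSE)
    if (!satisfies_constraints(tgt$reference_route, tgt$constraints))
      stop("generation invariant violated: reference route breaks its own ",
           "constraints", call. = FALSE)
    tgt
  })
  structure(list(library = library, stock = stk, targets = targets,
                 seed = seed, hidden = hidden), class = "rp_fixture")
}

# compose a single target; returns M (umol), steps, uid bookkeeping
.compose_target <- function(depth, blocks_u, families, hidden) {
  uid_next <- 1L
  fresh_block <- function(bi) {
    b <- blocks_u[[bi]]
    u <- list(mol = b$mol, uid = seq.int(uid_next, length.out = b$mol$n),
              fg = b$fg)
    uid_next <<- uid_next + b$mol$n
    u
  }
  steps <- list()
  block_uids <- list()   # per step: uid sets of the two inputs
  # first step
  sizes <- vapply(blocks_u, function(b) b$size, 0)
  fam1_pool <- sample(families)
  M <- NULL
  for (family in fam1_pool) {
    roles <- .FORWARD_RECIPES[[family]]
    ai <- which(vapply(blocks_u, function(b)
      length(b$fg[[roles["a"]]]) > 0, logical(1)))
    bi <- which(vapply(blocks_u, function(b)
      length(b$fg[[roles["b"]]]) > 0, logical(1)))
    if (hidden) {
      ai <- ai[sizes[ai] >= 7]; bi <- bi[sizes[bi] >= 7]
      ok <- expand.grid(ai = ai, bi = bi)
      ok <- ok[abs(sizes[ok$ai] - sizes[ok$bi]) <= 3, , drop = FALSE]
      if (!nrow(ok)) next
      row <- ok[sample.int(nrow(ok), 1L), ]
      ai <- row$ai; bi <- row$bi
    } else {
      if (!length(ai) || !length(bi)) next
      ai <- .pick(as.list(ai)); bi <- .pick(as.list(bi))
    }
    A <- fresh_block(ai); B <- fresh_block(bi)
    fgA <- .pick(A$fg[[roles["a"]]]); fgB <- .pick(B$fg[[roles["b"]]])
    M <- .forward_apply(family, A, fgA, B, fgB)
    steps[[1]] <- list(family = family, left = A, right = B,
                       formed = M$formed)
    block_uids[[1]] <- list(A$uid, B$uid)
    break
  }
  if (is.null(M)) stop("no feasible first step")
  if (depth > 1L) for (s in 2:depth) {
    pool_idx <- if (hidden)
      which(vapply(blocks_u, function(b) b$size <= 5, logical(1)))
      else seq_along(blocks_u)
    ch <- .random_step(M, blocks_u[pool_idx], sample(families))
    if (is.null(ch)) stop("no feasible continuation")
    family <- ch$family
    roles <- .FORWARD_RECIPES[[family]]
    Bk <- fresh_block(pool_idx[ch$block])
    if (ch$side == "a") {
      fgA <- .pick(find_fg(M$mol, roles["a"]))
      fgB <- .pick(Bk$fg[[roles["b"]]])
      prevM <- M
      M <- .forward_apply(family, M, fgA, Bk, fgB)
      steps[[s]] <- list(family = family, left = prevM, right = Bk,
                         formed = M$formed, prev_side = "left")
    } else {
      fgB <- .pick(find_fg(M$mol, roles["b"]))
      fgA <- .pick(Bk$fg[[roles["a"]]])
      prevM <- M
      M <- .forward_apply(family, Bk, fgA, M, fgB)
      steps[[s]] <- list(family = family, left = Bk, right = prevM,
                         formed = M$formed, prev_side = "right")
    }
  }
  if (M$mol$n > 70) stop("target too large")
  formed_uids <- unlist(lapply(steps, function(st) st$formed))
  if (!all(formed_uids %in% M$uid))
    stop("formed bond lost during composition")
  list(M = M, steps = steps, depth = depth)
}

# target bonds (as uid pairs) never formed by a composition step
.unchanged_keys <- function(res) {
  M <- res$M
  formed <- vapply(res$steps, function(st)
    paste(sort(st$formed), collapse = "_"), "")
  keys <- character(0)
  b <- M$mol$bonds
  for (k in seq_len(nrow(b))) {
    pair <- sort(c(M$uid[b[k, 1]], M$uid[b[k, 2]]))
    key <- paste(pair, collapse = "_")
    if (!key %in% formed) keys <- c(keys, key)
  }
  keys
}

# finalize: assign target maps, extract constraints
.finalize_target <- function(res, n_break, n_freeze, seed_tag, hidden) {
  M <- res$M
  M$mol$map <- seq_len(M$mol$n)
  M$mol$cache <- new.env(parent = emptyenv())
  uid2map <- stats::setNames(seq_len(M$mol$n), M$uid)
  # convergent disconnection score per step (reactant heavy-atom balance)
  cds <- vapply(res$steps, function(st) {
    sizes <- c(st$left$mol$n, st$right$mol$n)
    1 - (max(sizes) - min(sizes)) / sum(sizes)
  }, 0)
  depths <- rev(seq_along(res$steps)) - 1L   # last step = depth 0
  ord <- order(-cds, depths)
  pick <- ord[seq_len(min(n_break, length(ord)))]
  break_keys <- vapply(pick, function(i) {
    f <- res$steps[[i]]$formed
    bond_key(uid2map[as.character(f[1])], uid2map[as.character(f[2])])
  }, "")
  unchanged <- .unchanged_keys(res)
  freeze_keys <- character(0)
  if (n_freeze > 0L && length(unchanged)) {
    sel <- sample(unchanged, min(n_freeze, length(unchanged)))
    freeze_keys <- vapply(strsplit(sel, "_", fixed = TRUE), function(p)
      bond_key(uid2map[p[1]], uid2map[p[2]]), "")
    freeze_keys <- setdiff(freeze_keys, break_keys)
  }
  constraints <- constraint_set(break_keys, freeze_keys, target = M$mol)
  hidden_intermediate <- if (hidden) {
    last <- res$steps[[length(res$steps)]]
    big <- if (last$left$mol$n >= last$right$mol$n) last$left else last$right
    mol_identity(big$mol)
  } else NULL
  structure(list(target = M$mol, constraints = constraints,
                 steps = res$steps, uid = M$uid, uid2map = uid2map,
                 depth = res$depth,
                 hidden_intermediate = hidden_intermediate,
                 provenance = list(seed = seed_tag, depth = res$depth,
                                   hidden = hidden,
                                   recipe = vapply(res$steps, `[[`, "",
                                                   "family"))),
            class = "rp_benchmark_target")
}

#' @export
print.rp_benchmark_target <- function(x, ...) {
  cat("<rp_benchmark_target> ", mol_identity(x$target), "\n  depth ",
      x$depth, ", recipe: ", paste(x$provenance$recipe, collapse = " -> "),
      "\n  break {", paste(x$constraints$`break`, collapse = ", "),
      "}  freeze {", paste(x$constraints$freeze, collapse = ", "), "}\n",
      sep = "")
  invisible(x)
}

# materialize the planted reference route as an rp_route
.build_reference_route <- function(tgt, stk) {
  uid2map <- tgt$uid2map
  mapped <- function(u) {
    m <- u$mol
    m$map <- as.integer(uid2map[as.character(u$uid)])
    m$map[is.na(m$map)] <- 0L
    m$cache <- new.env(parent = emptyenv())
    m
  }
  mol_node <- function(u, children = list()) {
    list(type = "mol", smiles = canonical_smiles(mapped(u)),
         in_stock = in_stock(u$mol, stk), children = children)
  }
  n <- length(tgt$steps)
  # reaction node of step i; the input recorded as the previous
  # intermediate becomes a mol node wrapping step i-1's reaction
  node_for_step <- function(i) {
    st <- tgt$steps[[i]]
    kids <- list()
    for (side in c("left", "right")) {
      u <- st[[side]]
      if (i > 1L && identical(st$prev_side, side)) {
        kids[[length(kids) + 1L]] <-
          mol_node(u, children = list(node_for_step(i - 1L)))
      } else {
        kids[[length(kids) + 1L]] <- mol_node(u)
      }
    }
    f <- st$formed
    list(type = "reaction",
         metadata = list(template_name = st$family,
                         source_policy = "reference"),
         broken = bond_key(uid2map[as.character(f[1])],
                           uid2map[as.character(f[2])]),
         children = kids)
  }
  root <- mol_node(list(mol = tgt$target, uid = tgt$uid),
                   children = list(node_for_step(n)))
  structure(list(tree = root, scores = list(),
                 metadata = list(reference = TRUE,
                                 seed = tgt$provenance$seed)),
            class = "rp_route")
}

#' @export
print.rp_fixture <- function(x, ...) {
  cat("<rp_fixture> ", length(x$targets), " target(s), ",
      length(x$stock$smiles), " stock molecules, seed ", x$seed,
      if (x$hidden) ", hidden-route variant" else "", "\n", sep = "")
  invisible(x)
}
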