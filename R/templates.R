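# Retro reaction templates: mapped rewrite rules in the package SMILES
# dialect, "product_pattern>>reactant_pattern(.reactant_pattern)".
#
# Pattern atoms written in brackets carry template map indices ([C:1]);
# a bracket hydrogen count on the product side is an exact requirement
# ([CH2:1] matches only carbons with two hydrogens), while on the reactant
# side hydrogens are re-derived from the valence model after the rewrite.
# Matching itself is bought from igraph's VF2 with vertex colors
# (element + aromaticity) and edge colors (bond order); embeddings are then
# filtered by the hydrogen requirements in R.

#' Compile a retro template
#'
#' @param name template identifier.
#' @param retro_smarts rewrite rule "product>>reactants" in the package
#'   dialect.
#' @param prior_weight positive relative plausibility weight.
#' @param reaction_class free-text label.
#' @return An object of class `rp_template`.
#' @examples
#' retro_template("amide", "[C:1](=[O:2])[N:3]>>[C:1](=[O:2])O.[N:3]", 1)
#' @export
retro_template <- function(name, retro_smarts, prior_weight = 1,
                           reaction_class = "") {
  if (!is.numeric(prior_weight) || prior_weight <= 0)
    stop("prior_weight must be > 0", call. = FALSE)
  halves <- strsplit(retro_smarts, ">>", fixed = TRUE)[[1]]
  if (length(halves) != 2L)
    stop("retro_smarts must contain exactly one '>>'", call. = FALSE)
  prod <- parse_smiles(halves[1], pattern = TRUE)
  reac <- lapply(strsplit(halves[2], ".", fixed = TRUE)[[1]],
                 parse_smiles, pattern = TRUE)
  ptm <- prod$map
  for (r in reac) {
    rt <- r$map[r$map > 0L]
    bad <- setdiff(rt, ptm)
    if (length(bad))
      stop("reactant-pattern map index ", paste(bad, collapse = ","),
           " missing from product pattern in template ", name, call. = FALSE)
  }
  structure(list(name = name, retro_smarts = retro_smarts,
                 prior_weight = prior_weight,
                 reaction_class = reaction_class,
                 product = prod, reactants = reac),
            class = "rp_template")
}

#' @export
print.rp_template <- function(x, ...) {
  cat("<rp_template> ", x$name, ": ", x$retro_smarts,
      "  (w=", x$prior_weight, ")\n", sep = "")
  invisible(x)
}

#' Build a template library from a data frame
#'
#' @param df data frame with columns name, retro_smarts, prior_weight,
#'   reaction_class.
#' @return list of `rp_template` with class `rp_template_library`.
#' @export
template_library <- function(df) {
  stopifnot(all(c("name", "retro_smarts", "prior_weight") %in% names(df)))
  if (is.null(df$reaction_class)) df$reaction_class <- ""
  lib <- lapply(seq_len(nrow(df)), function(i)
    retro_template(df$name[i], df$retro_smarts[i], df$prior_weight[i],
                   df$reaction_class[i]))
  class(lib) <- "rp_template_library"
  lib
}

#' Read a template library from JSON or CSV
#' @param path file path; format chosen by extension (.json or .csv).
#' @return `rp_template_library`.
#' @export
read_template_library <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  template_library(df)
}

#' Write a template library to JSON or CSV
#' @param library `rp_template_library`.
#' @param path output path (.json or .csv).
#' @return invisibly, `path`.
#' @export
write_template_library <- function(library, path) {
  df <- as.data.frame(library)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA,
                         pretty = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
as.data.frame.rp_template_library <- function(x, ...) {
  data.frame(name = vapply(x, `[[`, "", "name"),
             retro_smarts = vapply(x, `[[`, "", "retro_smarts"),
             prior_weight = vapply(x, function(t) t$prior_weight, 0),
             reaction_class = vapply(x, `[[`, "", "reaction_class"),
             stringsAsFactors = FALSE)
}

# embeddings of a pattern molecule in a target molecule:
# list of integer vectors, emb[p] = target atom matched by pattern atom p
pattern_embeddings <- function(pattern, mol) {
  if (pattern$n > mol$n) return(list())
  gp <- mol_graph(pattern); gm <- mol_graph(mol)
  iso <- igraph::subgraph_isomorphisms(
    gp$g, gm$g, method = "vf2",
    vertex.color1 = gm$vcol, vertex.color2 = gp$vcol,
    edge.color1 = gm$ecol, edge.color2 = gp$ecol)
  embs <- lapply(iso, as.integer)
  # exact-H requirements from bracket atoms in the pattern
  hreq <- which(pattern$hexplicit)
  if (length(hreq)) {
    embs <- Filter(function(e)
      all(mol$hcount[e[hreq]] == pattern$hcount[hreq]), embs)
  }
  embs
}

# single-bond lookup helper: row index of bond a-b in mol$bonds, 0 if absent
.bond_row <- function(bonds, a, b) {
  if (!nrow(bonds)) return(0L)
  hit <- which((bonds[, 1] == a & bonds[, 2] == b) |
                 (bonds[, 1] == b & bonds[, 2] == a))
  if (length(hit)) hit[1] else 0L
}

#' Apply a retro template to a molecule
#'
#' One `rp_step` per distinct embedding of the product pattern; atom maps on
#' the product are carried onto the corresponding reactant atoms, new
#' template atoms enter unmapped, and duplicate reactant multisets are
#' deduplicated.  Embeddings that would produce a chemically invalid
#' reactant (valence model violation) are dropped with a warning.
#'
#' @param template `rp_template`.
#' @param mol `rp_mol` to disconnect.
#' @param prior prior probability attached to the resulting steps.
#' @return list of `rp_step` (possibly empty).
#' @export
apply_template <- function(template, mol, prior = 1) {
  embs <- pattern_embeddings(template$product, mol)
  if (!length(embs)) return(list())
  out <- list()
  seen <- character(0)
  for (emb in embs) {
    res <- tryCatch(.rewrite(template, mol, emb),
                    error = function(e) {
                      warning("template ", template$name,
                              " produced an invalid reactant (",
                              conditionMessage(e), "); embedding dropped",
                              call. = FALSE)
                      NULL
                    })
    if (is.null(res)) next
    # map-aware multiset key: symmetric sites with different constraint
    # anchors stay distinct, true duplicate embeddings collapse
    key <- paste(sort(vapply(res, canonical_smiles, "")), collapse = " + ")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- new_step(
      product = mol, reactants = res, prior = prior,
      source_policy = "template", template_name = template$name)
  }
  out
}

# perform the graph rewrite for one embedding; returns list of reactant mols
.rewrite <- function(template, mol, emb) {
  prod <- template$product
  # product atom index by template map
  tmap_atom <- integer(0)
  for (p in seq_len(prod$n))
    if (prod$map[p] > 0L) tmap_atom[prod$map[p]] <- emb[p]

  el <- mol$element; ar <- mol$aromatic; hc <- mol$hcount
  mp <- mol$map; tg <- mol$tag
  bonds <- mol$bonds
  touched <- logical(mol$n)

  # reactant-side bond set keyed by template maps: "i-j" -> order
  rbonds <- list()
  new_atoms <- list()      # per reactant fragment: local idx -> global idx
  for (fi in seq_along(template$reactants)) {
    frag <- template$reactants[[fi]]
    loc2glob <- integer(frag$n)
    for (q in seq_len(frag$n)) {
      if (frag$map[q] > 0L) {
        loc2glob[q] <- tmap_atom[frag$map[q]]
      } else {
        el <- c(el, frag$element[q]); ar <- c(ar, frag$aromatic[q])
        hc <- c(hc, NA_integer_); mp <- c(mp, 0L); tg <- c(tg, FALSE)
        loc2glob[q] <- length(el)
        touched <- c(touched, TRUE)
      }
    }
    if (nrow(frag$bonds)) for (k in seq_len(nrow(frag$bonds))) {
      qa <- frag$bonds[k, 1]; qb <- frag$bonds[k, 2]
      ga <- loc2glob[qa]; gb <- loc2glob[qb]
      rbonds[[paste0(min(ga, gb), "_", max(ga, gb))]] <- frag$bonds[k, 3]
    }
    new_atoms[[fi]] <- loc2glob
  }

  # product-pattern bonds: delete or retype those not reproduced on the
  # reactant side
  if (nrow(prod$bonds)) for (k in seq_len(nrow(prod$bonds))) {
    ga <- emb[prod$bonds[k, 1]]; gb <- emb[prod$bonds[k, 2]]
    key <- paste0(min(ga, gb), "_", max(ga, gb))
    row <- .bond_row(bonds, ga, gb)
    want <- rbonds[[key]]
    if (is.null(want)) {
      bonds <- bonds[-row, , drop = FALSE]
      touched[ga] <- TRUE; touched[gb] <- TRUE
    } else if (bonds[row, 3] != want) {
      bonds[row, 3] <- want
      touched[ga] <- TRUE; touched[gb] <- TRUE
    }
    rbonds[[key]] <- NULL
  }
  # remaining reactant-side bonds are additions (bonds to new atoms, or new
  # bonds between mapped atoms)
  for (key in names(rbonds)) {
    ab <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
    row <- .bond_row(bonds, ab[1], ab[2])
    if (row == 0L) {
      bonds <- rbind(bonds, c(ab[1], ab[2], rbonds[[key]]))
      touched[ab[1]] <- TRUE; touched[ab[2]] <- TRUE
    } else if (bonds[row, 3] != rbonds[[key]]) {
      bonds[row, 3] <- rbonds[[key]]
      touched[ab[1]] <- TRUE; touched[ab[2]] <- TRUE
    }
  }
  hc[touched] <- NA_integer_
  combined <- new_mol(el, ar, hc, mp, tg, bonds)
  split_components(combined)
}

#' Construct a retro step
#'
#' @param product `rp_mol`.
#' @param reactants list of `rp_mol`.
#' @param prior numeric in (0, 1].
#' @param source_policy "template" or "disconnection_aware".
#' @param template_name originating template.
#' @return `rp_step` with its broken-bond set populated.
#' @export
new_step <- function(product, reactants, prior, source_policy,
                     template_name) {
  stopifnot(length(reactants) >= 1L)
  structure(list(product = product, reactants = reactants,
                 prior = prior, source_policy = source_policy,
                 template_name = template_name,
                 broken = broken_bonds(product, reactants)),
            class = "rp_step")
}

#' @export
print.rp_step <- function(x, ...) {
  cat("<rp_step> ", canonical_smiles(x$product, with_maps = FALSE), " => ",
      paste(vapply(x$reactants, mol_identity, ""), collapse = " + "),
      "  [", x$template_name, ", prior ", signif(x$prior, 3),
      ", breaks {", paste(x$broken, collapse = ","), "}]\n", sep = "")
  invisible(x)
}

# canonical multiset key for a step's reactants (deduplication)
step_key <- function(step) {
  paste(sort(vapply(step$reactants, canonical_smiles, "")), collapse = " + ")
}
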