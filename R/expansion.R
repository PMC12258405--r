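# Expansion policies: ranked template policy, the deterministic
# disconnection-aware policy, the multi-expansion combiner, and the frozen
# bonds filter.
#
# The disconnection-aware policy plays the role of a prompt-based
# single-step model: each prompted bond present in the molecule is handled
# separately and only predictions that actually disconnect it are returned,
# capped at the beam width.  Priors are normalized per policy before the
# two outputs are concatenated, which weights the policies equally.

#' Ranked template expansion policy
#'
#' Applies every template in the library, assigns each resulting step a
#' prior equal to its template's weight normalized over all successful
#' applications for this molecule, and returns the top-k steps sorted by
#' prior (ties broken by canonical reactant SMILES for reproducibility).
#'
#' @param mol `rp_mol` to expand.
#' @param library `rp_template_library`.
#' @param k maximum number of steps returned (default 50).
#' @return list of `rp_step`.
#' @export
template_policy <- function(mol, library, k = 50) {
  stopifnot(k >= 1, length(library) >= 1)
  steps <- list()
  for (tpl in library) {
    app <- apply_template(tpl, mol)
    for (s in app) {
      s$prior <- tpl$prior_weight
      steps[[length(steps) + 1L]] <- s
    }
  }
  if (!length(steps)) return(list())
  w <- vapply(steps, function(s) s$prior, 0)
  p <- w / sum(w)
  for (i in seq_along(steps)) steps[[i]]$prior <- p[i]
  steps <- .sort_steps(steps)
  steps[seq_len(min(k, length(steps)))]
}

# sort by prior desc, then template policy before disconnection-aware, then
# lexicographic reactant key (deterministic runs)
.sort_steps <- function(steps) {
  pr <- vapply(steps, function(s) s$prior, 0)
  pol <- vapply(steps, function(s) s$source_policy == "disconnection_aware",
                logical(1))
  key <- vapply(steps, step_key, "")
  steps[order(-pr, pol, key)]
}

#' Disconnection-aware expansion policy
#'
#' Deterministic stand-in for a prompt-based disconnection-aware single-step
#' model: every prompted bond to break that is present in the molecule is
#' handled separately, and for each such bond up to `beam` template
#' applications whose broken set contains that bond are returned.  Priors
#' are normalized within this policy's output and steps are labelled
#' `source_policy = "disconnection_aware"`.  Returns an empty list when the
#' molecule contains none of the prompted bonds.
#'
#' @param mol `rp_mol` (atom-mapped).
#' @param break_set character vector of prompted bond keys.
#' @param library `rp_template_library`.
#' @param beam per-bond cap on returned steps (default 5).
#' @return list of `rp_step`.
#' @export
disconnection_policy <- function(mol, break_set, library, beam = 5) {
  stopifnot(beam >= 1)
  present <- intersect(break_set, mapped_bonds(mol))
  if (!length(present)) return(list())
  cand <- template_policy(mol, library, k = .Machine$integer.max)
  out <- list()
  for (b in sort(present)) {
    hits <- Filter(function(s) b %in% s$broken, cand)
    hits <- hits[seq_len(min(beam, length(hits)))]
    out <- c(out, hits)
  }
  if (!length(out)) return(list())
  w <- vapply(out, function(s) s$prior, 0)
  p <- w / sum(w)
  for (i in seq_along(out)) {
    out[[i]]$prior <- p[i]
    out[[i]]$source_policy <- "disconnection_aware"
  }
  .sort_steps(out)
}

#' Multi-expansion: combine template and disconnection-aware policies
#'
#' In `"standard"` mode this is exactly the template policy.  In
#' `"disconnection_aware"` mode the two policies' outputs (each with priors
#' normalized within its policy, i.e. equal weighting) are concatenated,
#' sorted by prior, deduplicated on identical reactant multisets (keeping
#' the higher-prior copy) and truncated to `k` steps.
#'
#' @param mol `rp_mol`.
#' @param constraints `rp_constraints` (the break set feeds the
#'   disconnection-aware policy).
#' @param library `rp_template_library`.
#' @param k overall cap (default 50).
#' @param beam per-bond beam of the disconnection-aware policy.
#' @param mode `"standard"` or `"disconnection_aware"`.
#' @return list of `rp_step` with non-increasing priors.
#' @export
multi_expand <- function(mol, constraints, library, k = 50, beam = 5,
                         mode = c("standard", "disconnection_aware")) {
  mode <- match.arg(mode)
  tp <- template_policy(mol, library, k)
  if (mode == "standard") return(tp)
  dp <- disconnection_policy(mol, constraints$`break`, library, beam)
  all <- .sort_steps(c(tp, dp))
  seen <- character(0)
  keep <- list()
  for (s in all) {
    key <- step_key(s)
    if (key %in% seen) next
    seen <- c(seen, key)
    keep[[length(keep) + 1L]] <- s
  }
  keep[seq_len(min(k, length(keep)))]
}

#' Frozen bonds filter
#'
#' Removes every step that breaks a frozen bond; order is preserved.
#'
#' @param steps list of `rp_step`.
#' @param freeze character vector of frozen bond keys.
#' @return filtered list of `rp_step`.
#' @export
frozen_filter <- function(steps, freeze) {
  if (!length(freeze) || !length(steps)) return(steps)
  Filter(function(s) !violates_freeze(s, freeze), steps)
}

# ---------------------------------------------------------------------------
# stock

#' Build a stock of purchasable building blocks
#'
#' @param smiles character vector of building-block SMILES.
#' @return object of class `rp_stock`.
#' @export
stock <- function(smiles) {
  ids <- vapply(smiles, function(s) mol_identity(parse_smiles(s)), "",
                USE.NAMES = FALSE)
  set <- new.env(parent = emptyenv())
  for (i in ids) assign(i, TRUE, envir = set)
  structure(list(set = set, smiles = unique(ids)), class = "rp_stock")
}

#' Read a stock file (one SMILES per line, '#' comments)
#' @param path file path.
#' @return `rp_stock`.
#' @export
read_stock <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  stock(ln)
}

#' Write a stock to file
#' @param stk `rp_stock`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_stock <- function(stk, path) {
  writeLines(stk$smiles, path)
  invisible(path)
}

#' @export
print.rp_stock <- function(x, ...) {
  cat("<rp_stock> ", length(x$smiles), " building blocks\n", sep = "")
  invisible(x)
}

#' Is a molecule in stock?
#'
#' Membership uses the canonical identity token (maps stripped), so bond
#' constraints never affect stock lookup.
#'
#' @param mol `rp_mol` or SMILES string.
#' @param stk `rp_stock`.
#' @return logical.
#' @export
in_stock <- function(mol, stk) {
  id <- if (inherits(mol, "rp_mol")) mol_identity(mol)
        else mol_identity(parse_smiles(mol))
  !is.null(stk$set[[id]])
}
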