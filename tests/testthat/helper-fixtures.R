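# Shared in-code fixtures: a minimal amide world plus lazily-built
# generator fixtures reused across test files.

amide_template <- function(w = 1) {
  retro_template("amide", "[C:1](=[O:2])[N:3]>>[C:1](=[O:2])O.[N:3]", w)
}

# N-methylacetamide with the classic mapping; break the amide C-N bond
demo_target <- function() {
  parse_target("[CH3:10][C:1](=[O:2])[NH:3][CH3:11]",
               break_pairs = list(c(1, 3)))
}

demo_library <- function() {
  template_library(data.frame(
    name = c("amide", "ester"),
    retro_smarts = c("[C:1](=[O:2])[N:3]>>[C:1](=[O:2])O.[N:3]",
                     "[C:1](=[O:2])[O:3][C:4]>>[C:1](=[O:2])O.[O:3][C:4]"),
    prior_weight = c(3, 1), reaction_class = "acylation",
    stringsAsFactors = FALSE))
}

demo_stock <- function() stock(c("CC(=O)O", "CN", "CC(N)=O", "CCO"))

# fixtures are deterministic in the seed; memoize them per session
.fx_cache <- new.env(parent = emptyenv())
cached_fixture <- function(key, builder) {
  hit <- .fx_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- builder()
  assign(key, val, envir = .fx_cache)
  val
}

small_fixture <- function() {
  cached_fixture("small", function()
    generate_fixture(6, depth_range = 1:3, seed = 42))
}

hidden_fixture <- function(seed = 301) {
  cached_fixture(paste0("hidden", seed), function()
    generate_fixture(5, depth_range = 2:3, seed = seed, hidden = TRUE))
}

# hand-built route: acetamide-like target disconnected once
demo_route <- function(extra_steps = list()) {
  tgt <- demo_target()
  lib <- list(amide_template())
  class(lib) <- "rp_template_library"
  steps <- template_policy(tgt$mol, lib)
  route_from_steps(tgt$mol, c(steps[1], extra_steps), demo_stock())
}

# brute-force dominance oracle for Pareto ranks (maximization)
pareto_rank_oracle <- function(m) {
  n <- nrow(m)
  dominated_by <- function(i, pool) {
    any(vapply(pool, function(j) {
      all(m[j, ] >= m[i, ]) && any(m[j, ] > m[i, ])
    }, logical(1)))
  }
  rank <- integer(n)
  remaining <- seq_len(n)
  r <- 0L
  while (length(remaining)) {
    r <- r + 1L
    front <- remaining[!vapply(remaining, dominated_by, logical(1),
                               pool = remaining)]
    rank[front] <- r
    remaining <- setdiff(remaining, front)
  }
  rank
}

# independent python/rdkit canonicalization oracle on a SMILES vector;
# returns canonical strings (one per input)
rdkit_canonical <- function(smiles) {
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "for line in sys.stdin:",
    "    m = Chem.MolFromSmiles(line.strip())",
    "    print(Chem.MolToSmiles(m))", sep = "\n")
  res <- system2("python", c("-c", shQuote(script)),
                 input = smiles, stdout = TRUE)
  res
}
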