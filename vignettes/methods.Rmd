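---
title: "Prompt-guided retrosynthesis planning: models, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prompt-guided retrosynthesis planning: models, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroprompt)
```

## The problem

Multistep retrosynthesis tools decompose a target molecule into
purchasable building blocks by applying single-step retro reactions
recursively. Off-the-shelf planners optimize solvability and route length
but ignore the chemist's prior knowledge: in practice one often knows
which bond *should* be disconnected somewhere along the route (to reuse an
intermediate across a compound series, or to avoid an expensive starting
material) and which bonds *must* stay intact. `retroprompt` makes both
kinds of knowledge first-class inputs:

* **bonds to break** — soft constraints: the search and the route ranking
  are biased toward routes that disconnect them, early if possible, but
  predictions that fail to break them are never discarded, since other
  disconnections before or after may be necessary, and partial solutions
  are still useful to a chemist;
* **bonds to freeze** — hard constraints: a filter removes every
  single-step prediction that severs a frozen bond, so no route in the
  output can ever violate one.

Constraints are anchored on atom-map numbers (`[N:1]`, `[c:2]`), which
template application propagates from the product onto the reactants, so a
bond keeps its identity across every step of a route. A `!`-tag dialect
(`CC(=O)!N!C`) is accepted on input and normalized to map pairs.

## Scores

### State score

The default search objective favors solved, short routes:

$$s_\text{state} = 0.95\, f + 0.05\, g(L)$$

where $f$ is the fraction of leaf molecules found in stock and $g$ is a
decreasing logistic squash of the route length $L$ (number of reactions),
normalized so that $g(0) = 1$; a target that is already purchasable scores
exactly 1. The squash midpoint (4 reactions) and scale (1.2) are
configurable knobs; only the qualitative contract — monotone decreasing,
$g(0)=1$ — matters to the rest of the package.

### Broken bonds score

Given the prompted set $B$ of bonds to break, every bond $b$ broken by a
reaction at depth $d(r_b)$ (the first reaction has depth 0) earns a credit
$1 - d(r_b)/D_\max$; prompted bonds that never break incur one *joint*
penalty term corresponding to breaking at the maximum depth,
$1 - D_\max/D_\max = 0$. The sum is normalized by the number of productive
components: $|B_\text{broken}|$ when every prompted bond breaks,
$|B_\text{broken}| + 1$ otherwise. The score is exactly 1 when all
prompted bonds break in the first reaction and exactly 0 when none breaks,
and earlier breaking always scores higher.

```{r bb-endpoints}
B <- c("1-2", "3-4", "5-6")
broken_bonds_score(setNames(c(0L, 0L, 0L), B), B, d_max = 6)   # all, first
broken_bonds_score(setNames(integer(0), character(0)), B, 6)   # none
```

Two properties of this normalization deserve a note. Completing the final
unbroken bond can never lower the score (the penalty slot is replaced by a
non-negative credit), and breaking an additional bond in the first
reaction can never lower it either; but breaking an additional bond *very
deep* in the tree can, because a small credit enters an average that the
unbroken penalty already occupies. The score is a preference over routes,
not a count of satisfied constraints; `satisfies_constraints()` gives the
Boolean answer.

The depth/normalization pairing was fixed by calibration against the three
worked-example values this family of scores is known by (0.65, 0.86,
0.92, with $D_\max = 24$ in the worked-example configuration); the exact
fractions are $47/72$, $31/36$ and $11/12$:

```{r bb-calibration}
round(broken_bonds_score(setNames(c(0L, 1L), B[1:2]), B, 24), 4)      # 0.65
round(broken_bonds_score(setNames(c(2L, 4L, 4L), B), B, 24), 4)      # 0.86
round(broken_bonds_score(setNames(c(1L, 2L, 3L), B), B, 24), 4)      # 0.92
```

Under this normalization a route that breaks only two of three prompted
bonds is bounded by $2/3$, so the 0.86 example is necessarily a route that
breaks all three bonds at greater depth. In searches, $D_\max$ defaults to
the configured maximum search depth (not the realized tree depth), so
scores are comparable across all routes of one search.

An empty break set is a refused input, not a zero: a multi-objective
search silently configured without prompted bonds would otherwise optimize
a constant.

### Combined score

The route-ranking strategy orders routes by
$0.5\,s_\text{state} + 0.5\,s_\text{broken}$ — an equal-weight linear
combination applied after the search, leaving the search itself untouched.

## Search

Both search variants are Monte-Carlo tree search over *states* (multisets
of unsolved frontier molecules, each with its own transform depth).
Expansion applies the multi-expansion policy to the first frontier
molecule, then the frozen bonds filter; the reward of a node is the
immediate evaluation of its state (no rollout), accumulated as a running
mean, following the conventions of template-based MCTS planners. The
search runs to its iteration or time budget and never stops at the first
solution; every visited state is a candidate route at extraction time.

* **Single-objective MCTS** uses the state score and UCB1 selection
  (exploration constant 1.4).
* **MO-MCTS** rewards with the vector (state score, broken bonds score).
  Selection computes the per-objective mean plus a UCB exploration bonus
  for every child and draws uniformly — seeded — among the Pareto
  non-dominated children. The acquisition rule is a documented,
  swappable stand-in; dominance is non-strict under maximization, so
  exact ties share a front.

Front extraction peels non-dominated sets iteratively
(`pareto_fronts()`); the multi-objective strategies return the primary
front, padded from lower ranks up to the requested count.

### Expansion policies

The **template policy** applies every retro template in the library and
ranks the resulting steps by template prior weight, normalized over all
successful applications for the molecule, truncated at $k = 50$. It plays
the role of the ranked single-step model in production planners; template
matching itself is VF2 subgraph isomorphism (igraph) over element,
aromaticity and bond-order colors, with exact-hydrogen requirements
checked per embedding.

The **disconnection-aware policy** is a deterministic stand-in for a
prompt-based single-step model: each prompted bond present in the molecule
is handled separately, and only steps whose broken set contains that bond
are returned, up to a beam of 5 per bond. It therefore guarantees the
behavioral contract that matters downstream — tagged bonds *will* be
disconnected by the steps it proposes, and tags propagate through atom
maps — without trained weights.

`multi_expand()` concatenates the two policies' outputs with priors
normalized *per policy* (the equal-weighting reading), sorts by prior,
deduplicates identical reactant multisets keeping the higher-prior copy,
and truncates to 50. Ties break deterministically: template-policy steps
before disconnection-aware ones, then lexicographically by canonical
reactant SMILES. Because each policy's priors sum to one over its own
output, a policy proposing fewer steps concentrates more mass per step —
which reproduces the tendency of disconnection-aware predictions to rank
high in the combined list; a rescaling knob was considered and left out.

### Strategies

| name | expansion | search | extraction |
|------|-----------|--------|------------|
| `standard` | template | MCTS (state) | top-n by state |
| `route-ranking` | template | MCTS (state) | top-n by combined |
| `mo-search` | template | MO-MCTS | Pareto front |
| `da` | multi-expansion | MCTS (state) | top-n by state |
| `da-mo` | multi-expansion | MO-MCTS | Pareto front |

The frozen bonds filter is active in all five.

## Route similarity, dissimilarity, diversity

`route_similarity()` is the mean of a bond component (Jaccard overlap of
the two routes' target-atom disconnection sets) and an atom component
(best-match Jaccard agreement of the target-atom sets of the two routes'
leaves, summed in both directions and normalized by the *total* molecule
count of both routes). Only atoms identified in the final target
participate; molecules carrying none still count in the normalization.
This reproduces, deliberately, the documented quirk of this metric family:
a multi-step route compared with itself scores below 1, so the
self-dissimilarity of a route set is slightly above zero. The
implementation follows the stated contract (disconnection overlap + atom
grouping + whole-route normalization) and is an approximation, not a
re-derivation, of any particular published algorithm.

Dissimilarity to a reference set is $\gamma = 1 - \zeta_\max$
(mean-of-max similarity); within-set diversity is
$\kappa = 1 - \zeta_\min$ (mean-of-min).

## The synthetic benchmark

`generate_fixture()` builds the complete study world from a seed: a
six-family retro-template library (amide coupling, ester formation,
Suzuki coupling, aromatic substitution, reductive amination, ether
formation), a stock of ~60 building blocks, and targets forward-composed
from the stock through the template inverses — so every target carries a
planted reference route that is solved by construction. Atom provenance
is tracked through every composition, anchoring the planted bonds in the
final target's map space.

Constraints are extracted the way benchmark constraints are extracted
from real route collections: bonds to break come from the reactions with
the highest *convergent disconnection score*
$\mathrm{CDS} = 1 - (\max_i a_i - \min_i a_i)/\sum_i a_i$ over reactant
heavy-atom counts (single-reactant steps score 0) — a surrogate that
preserves the stated purpose, preferring disconnections into roughly
equal-sized reactants; its exact published algebra is not reproduced.
Bonds to freeze are sampled from the bonds unchanged along the whole
route, which guarantees at least one solved, satisfying route exists (the
reference); we freeze fewer bonds than we break (default: one freeze from
two or three breaks) so the freeze does not dominate the experiment.
Default break counts are sampled from {1, 2, 3} capped at the route
depth, mirroring realistic constraint-count distributions.

The `hidden = TRUE` variant plants the regime where constraint
satisfaction and shortness genuinely conflict: the deepest composition is
forced to be convergent (so CDS selects its bond as the prompt), later
steps attach small blocks, and the last intermediate *plus the pieces of
every depth-0 disconnection that avoids the prompted bond* are added to
the stock. Short solved routes that skip the prompted bond then outnumber
the extraction budget, and only searches that value the broken bonds
objective keep the satisfying (longer) routes in their output — the
mechanism behind the directional benchmark result that multi-objective
and combined strategies satisfy constraints for at least as many targets
as the standard search.

What the generator does *not* emulate: reaction feasibility beyond the
valence model (no yields, no selectivity, no protecting groups),
stereochemistry, reagent/catalyst context, and the scale of real template
libraries (thousands of templates, millions of stock compounds). Passing
benchmarks here demonstrates the *machinery* — constraint tracking,
filtering, scoring, search and evaluation — under controlled conditions,
not chemical accuracy on real syntheses.

## Numerical and design choices

* **Molecule layer.** A compact neutral organic SMILES dialect (B, C, N,
  O, P, S, halogens; aromatic c/n/o/s; no charges, isotopes or
  stereodescriptors) with valence-model hydrogens. Canonical ranks come
  from iterative invariant refinement with branching individualization on
  ties (lexicographically smallest output wins), so canonicalization is
  independent of input atom order; atom maps ride along without
  influencing ranks. Stock identity strips maps, so constraints never
  affect purchasability lookups.
* **Bond-order changes are not disconnections**: a frozen bond whose
  order changes but persists is not violated — constraints speak the
  language of disconnections. Flagged here because the opposite
  convention is defensible.
* **Unmapped atoms** never participate in constraint logic; map number 0
  is reserved.
* **Dominance convention**: maximization on every axis, non-strict ties
  share a rank.
* **Determinism**: all stochastic choices (MO tie-breaks, generator
  composition, freeze sampling) flow from explicit seeds; two runs with
  the same seed produce identical trees, routes and fixtures.
* **Problem sizes.** The shipped evaluations use fixtures of 5–50
  targets at depths 1–3, searches of 40–100 iterations with expansion
  width 50 and beam 5, and batch statistics over batches of 6–8 targets
  (the batch-size default is 128, matching bulk-evaluation practice;
  small studies scale it down). These sizes were chosen so a full
  evaluation runs on a laptop in minutes while still exercising every
  code path at realistic branching factors.

## Known limitations

* The toy template set cannot represent ring-forming/-breaking
  retro steps beyond what its six families cover; multi-product templates
  are supported by the engine but unused.
* The disconnection-aware policy is only as good as the template library:
  a prompted bond no template can break yields no disconnection-aware
  predictions (the template policy still runs).
* The MO acquisition rule (per-objective UCB + random non-dominated
  choice) is one member of a family; it is isolated behind
  `.select_child` precisely so it can be swapped.
* Route similarity is target-anchored: routes for different targets are
  incomparable by design.
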