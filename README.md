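# retroprompt

Human-guided multistep retrosynthesis planning via bond prompts, in R.

Retrosynthesis tools decompose a target molecule into purchasable
building blocks by recursive single-step retro reactions, but standard
planners optimize only solvability and route length. A chemist usually
knows more: which bond should be disconnected somewhere along the route
(**bonds to break** — e.g. to share an intermediate across a compound
series) and which bonds must survive every step (**bonds to freeze**).
`retroprompt` takes both as prompts, anchored on atom-map numbers
(`[N:1]`, `[c:2]`, or the `!`-tag shorthand `CC(=O)!N!C`):

* freeze constraints are **hard** — a filter discards every single-step
  prediction that severs a frozen bond, so no output route can violate
  one;
* break constraints are **soft** — they bias the search and the route
  ranking through a *broken bonds score*

  $$s(B) \;=\; \frac{\sum_{b \in B_\text{broken}} \bigl(1 - d(r_b)/D_\max\bigr)
  \;+\; \mathbb{1}[\text{partial}]\,\bigl(1 - D_\max/D_\max\bigr)}
  {\lvert B_\text{broken}\rvert + \mathbb{1}[\text{partial}]}$$

  which is 1 exactly when every prompted bond breaks in the first
  reaction ($d = 0$), 0 exactly when none breaks, and rewards breaking
  prompted bonds *early* in the tree.

Five strategies combine two expansion policies (a ranked template policy
and a disconnection-aware policy that handles each prompted bond
separately) with single-objective MCTS or multi-objective MCTS over
(state score, broken bonds score), where the extracted routes form the
Pareto front: `standard`, `route-ranking`, `mo-search`, `da`, `da-mo`.
Route similarity / dissimilarity (γ) / diversity (κ) metrics characterize
the output, and a seeded synthetic benchmark generator plants solved
reference routes with extractable constraints to evaluate the strategies.

## Worked example

Generate a two-step benchmark target (an ester of a biaryl alcohol,
planted with the ester C–O bond as the bond to break), then search with
the multi-objective strategy:

```r
library(retroprompt)

fx  <- generate_fixture(1, depth_range = 2, seed = 42)
tg  <- fx$targets[[1]]
tg
#> <rp_benchmark_target> Cc3ccc(C(=O)OCc1ccc(cc1)-c2ccc(C)cc2)cc3
#>   depth 2, recipe: ester_formation -> suzuki_coupling
#>   break {1-10}  freeze {}

cfg <- search_config(iteration_limit = 60, seed = 1)
res <- run_strategy("mo-search", tg, library = fx$library,
                    stk = fx$stock, config = cfg)
route_score_table(res$routes)
#> # A tibble: 5 × 6
#>   route solved n_reactions state broken_bonds combined
#>   <int> <lgl>        <int> <dbl>        <dbl>    <dbl>
#> 1     1 TRUE             2 0.994        1        0.997
#> 2     2 TRUE             2 0.994        0.833    0.913
#> 3     3 FALSE            2 0.677        1        0.838
#> 4     4 FALSE            2 0.677        0.833    0.755
#> 5     5 FALSE            1 0.523        1        0.761

satisfies_constraints(res$routes[[1]], tg$constraints)
#> [1] TRUE
```

Reading the table: the top route is solved (every leaf purchasable) in 2
reactions with state score 0.994, and its broken-bonds score of 1 means
the prompted bond `1-10` (the ester C–O) is disconnected in the very
first reaction; the second route breaks it one level deeper (score
0.833 = (1 − 1/6), with `D_max = 6`). The extracted set is the Pareto
front over the two scores, so solved-but-later-breaking and
unsolved-but-early-breaking routes both surface.

The same workflow is scriptable from a shell:

```sh
Rscript inst/cli/retroplan.R plan --target 'CC(=O)!N!C' \
    --library lib.json --stock stock.smi --strategy mo-search --out out/
Rscript inst/cli/retroplan.R benchmark generate --n 20 --seed 1 --out fx/
Rscript inst/cli/retroplan.R score --route route.json --break 1-3
```

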