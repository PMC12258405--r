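Package: retroprompt
Title: Human-Guided Multistep Retrosynthesis Planning via Bond Prompts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Prompt-constrained multistep retrosynthesis planning: users tag
    bonds to break and bonds to freeze on a target molecule, and the engine
    searches for synthesis routes with single- or multi-objective
    Monte-Carlo tree search over a mapped retro-template library.  Routes
    are scored with a depth-weighted broken-bonds score and a
    solvability/length state score; a frozen-bonds filter removes
    predictions that violate freeze constraints; route similarity,
    dissimilarity and diversity metrics characterize the output.  A
    synthetic benchmark generator plants solved reference routes with
    extractable bond constraints and drives strategy evaluation with batch
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    yaml,
    tibble,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
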