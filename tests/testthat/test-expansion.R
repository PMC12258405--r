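test_that("apply_template: single embedding, no match, dedup", {
  tpl <- amide_template()
  m <- parse_smiles("[CH3:10][C:1](=[O:2])[NH:3][CH3:11]")
  steps <- apply_template(tpl, m)
  expect_length(steps, 1L)
  expect_setequal(vapply(steps[[1]]$reactants, mol_identity, ""),
                  c("CC(=O)O", "CN"))
  expect_identical(steps[[1]]$broken, "1-3")
  # no match
  expect_length(apply_template(tpl, parse_smiles("CC")), 0L)
  # symmetric unmapped diamide: embeddings collapse to one reactant
  # multiset (oracle: canonicalize every embedding's reactants and count)
  dia <- parse_smiles("CNC(=O)CCC(=O)NC")
  steps2 <- apply_template(tpl, dia)
  keys <- vapply(steps2, retroprompt:::step_key, "")
  expect_identical(length(steps2), length(unique(keys)))
  expect_length(steps2, 1L)
  # mapped diamide: the two sites anchor different bonds and stay distinct
  dia_m <- parse_target("CNC(=O)CCC(=O)NC")$mol
  steps3 <- apply_template(tpl, dia_m)
  expect_length(steps3, 2L)
  expect_false(identical(steps3[[1]]$broken, steps3[[2]]$broken))
})

test_that("template_policy normalizes priors and truncates at k", {
  tgt <- demo_target()$mol
  one <- template_library(data.frame(
    name = "amide", retro_smarts =
      "[C:1](=[O:2])[N:3]>>[C:1](=[O:2])O.[N:3]",
    prior_weight = 5, reaction_class = ""))
  s1 <- template_policy(tgt, one)
  expect_length(s1, 1L)
  expect_equal(s1[[1]]$prior, 1.0)
  # two matching templates, weights 3:1 -> priors 0.75/0.25
  ester_amide <- parse_target("CCOC(=O)CCNC(C)=O")$mol
  lib <- demo_library()
  s2 <- template_policy(ester_amide, lib)
  pr <- vapply(s2, function(s) s$prior, 0)
  expect_equal(sum(pr), 1.0)
  expect_equal(sort(unique(round(pr, 6))), c(0.25, 0.75))
  expect_true(all(diff(pr) <= 0))
  # top-k equals the head of the full sort (oracle: full application list)
  full <- template_policy(ester_amide, lib, k = 100)
  expect_identical(vapply(template_policy(ester_amide, lib, k = 1),
                          retroprompt:::step_key, ""),
                   retroprompt:::step_key(full[[1]]))
})

test_that("disconnection_policy handles each prompted bond separately", {
  lib <- demo_library()
  tgt <- demo_target()
  s <- disconnection_policy(tgt$mol, tgt$constraints$`break`, lib, beam = 5)
  expect_length(s, 1L)
  expect_true("1-3" %in% s[[1]]$broken)
  expect_identical(s[[1]]$source_policy, "disconnection_aware")
  # policy gating: molecule without the prompted atoms
  other <- parse_target("CCOC(C)=O")$mol
  expect_length(disconnection_policy(other, "98-99", lib), 0L)
  # two prompted bonds: per-bond lists concatenated, every step breaks its
  # bond (oracle: filter the template policy by broken-set membership)
  dia <- parse_target("CNC(=O)CCC(=O)NC")$mol
  both <- apply_template(amide_template(), dia)
  keys <- sort(unique(unlist(lapply(both, function(x) x$broken))))
  s2 <- disconnection_policy(dia, keys, lib, beam = 5)
  expect_length(s2, 2L)
  for (st in s2) expect_true(any(keys %in% st$broken))
  expect_equal(sum(vapply(s2, function(x) x$prior, 0)), 1.0)
})

test_that("multi_expand combines, dedups and matches template_policy in
           standard mode", {
  lib <- demo_library()
  tgt <- demo_target()
  std <- multi_expand(tgt$mol, tgt$constraints, lib, mode = "standard")
  tp <- template_policy(tgt$mol, lib)
  expect_identical(vapply(std, retroprompt:::step_key, ""),
                   vapply(tp, retroprompt:::step_key, ""))
  da <- multi_expand(tgt$mol, tgt$constraints, lib,
                     mode = "disconnection_aware")
  # identical reactant multisets merged, higher-prior copy kept
  expect_identical(length(unique(vapply(da, retroprompt:::step_key, ""))),
                   length(da))
  pr <- vapply(da, function(s) s$prior, 0)
  expect_true(all(diff(pr) <= 0))
  expect_true(all(pr > 0 & pr <= 1))
})

test_that("frozen_filter removes exactly the violating steps in order", {
  lib <- demo_library()
  dia <- parse_target("CNC(=O)CCC(=O)NC")$mol
  steps <- template_policy(dia, lib)
  expect_identical(frozen_filter(steps, character(0)), steps)
  keys <- sort(unique(unlist(lapply(steps, function(s) s$broken))))
  expect_length(frozen_filter(steps, keys), 0L)
  # mixed: oracle = plain Filter over violates_freeze
  f <- keys[1]
  got <- frozen_filter(steps, f)
  want <- Filter(function(s) !violates_freeze(s, f), steps)
  expect_identical(vapply(got, retroprompt:::step_key, ""),
                   vapply(want, retroprompt:::step_key, ""))
})

test_that("stock lookup ignores atom maps and honors comments", {
  stk <- demo_stock()
  expect_true(in_stock("CC(=O)O", stk))
  expect_true(in_stock(parse_smiles("[CH3:7][C:5](=[O:6])O"), stk))
  expect_false(in_stock("c1ccccc1", stk))
  p <- tempfile(fileext = ".smi"); on.exit(unlink(p))
  writeLines(c("# building blocks", "CC(=O)O", "", "CN"), p)
  stk2 <- read_stock(p)
  expect_true(in_stock("CN", stk2))
  expect_length(stk2$smiles, 2L)
})
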