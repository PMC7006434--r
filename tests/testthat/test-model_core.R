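test_that("stoichiometric matrix assembly matches per-reaction maps", {
  # single glutamate -> glutamine conversion: column (-1, +1)
  p <- parse_reaction_formula("1 glu_L[e] -> 1 gln_L[e]")
  m <- metabolic_model(rbind(metabolite("glu_L[e]"), metabolite("gln_L[e]")),
                       list(reaction("Glu2Gln", p$stoichiometry)))
  S <- build_stoichiometric_matrix(m)
  expect_equal(dim(S), c(2L, 1L))
  expect_equal(S["glu_L[e]", "Glu2Gln"], -1)
  expect_equal(S["gln_L[e]", "Glu2Gln"], 1)

  # empty model: 0 x 0
  empty <- metabolic_model(metabolite("x[c]")[0, ], list())
  expect_equal(dim(build_stoichiometric_matrix(empty)), c(0L, 0L))

  # 6-reaction toy: entry-by-entry independent assembly
  toy <- chain_model()
  toy$reactions <- c(toy$reactions, parallel_model()$reactions["P1"],
                     cycle_model()$reactions[c("F1", "F2")])
  toy$metabolites <- rbind(toy$metabolites, metabolite("b[c]"),
                           metabolite("x[c]"), metabolite("y[c]"))
  toy <- metabolic_model(toy$metabolites, toy$reactions)
  S <- as.matrix(build_stoichiometric_matrix(toy))
  expected <- matrix(0, nrow(toy$metabolites), length(toy$reactions),
                     dimnames = dimnames(S))
  for (r in toy$reactions)
    for (met in names(r$stoichiometry))
      expected[met, r$id] <- r$stoichiometry[[met]]
  expect_identical(S, expected)
})

test_that("matrix round-trip reproduces every reaction's stoichiometry", {
  model <- generate_toy_astrocyte(toy_params(include_tibolone = TRUE,
                                             include_estradiol_stub = TRUE))
  S <- as.matrix(build_stoichiometric_matrix(model))
  for (r in model$reactions) {
    col <- S[, r$id]
    back <- col[col != 0]
    expect_equal(back[sort(names(back))],
                 r$stoichiometry[sort(names(r$stoichiometry))])
  }
})

test_that("metabolite id parsing normalizes both dialects and rejects junk", {
  p <- parse_met_id(c("glu_L[e]", "glu_L_e", "a3SOtibolone[e]"))
  expect_equal(p$id, c("glu_L[e]", "glu_L[e]", "a3SOtibolone[e]"))
  expect_equal(p$compartment, c("e", "e", "e"))
  # trailing _L is not a compartment code
  expect_error(parse_met_id("glu_L"), "cannot parse")
  expect_error(parse_met_id("glu[q]"), "cannot parse")
})

test_that("reaction classification partitions the toy model", {
  model <- generate_toy_astrocyte()
  # printed examples
  tib <- tibolone_reactions()
  expect_equal(classify_reaction(tib[[1]]), "exchange")     # Tibolone[e] <=>
  tr <- reaction("t", c("glu_L[e]" = -1, "glu_L[c]" = 1))
  expect_equal(classify_reaction(tr), "transport")
  ic <- reaction("i", c("glc_D[c]" = -1, "lac_L[c]" = 2))
  expect_equal(classify_reaction(ic), "intracellular")
  degenerate <- structure(list(id = "z", stoichiometry = numeric(0)),
                          class = "gf_reaction")
  expect_error(classify_reaction(degenerate), "empty stoichiometry")

  kinds <- vapply(model$reactions, function(r) r$kind, character(1))
  expect_true(all(kinds %in% c("exchange", "transport", "intracellular",
                               "pseudo")))
  expect_equal(sum(table(kinds)), length(model$reactions))
  expect_equal(unname(table(kinds)["exchange"]), 14L)
  expect_equal(unname(table(kinds)["transport"]), 13L)
})

test_that("validation reports balance, orphans and syntax findings", {
  mets <- rbind(metabolite("glc[c]", formula = "C6H12O6"),
                metabolite("lac[c]", formula = "C3H6O3"),
                metabolite("x[c]"))
  ok <- metabolic_model(mets, list(
    reaction("FERM", c("glc[c]" = -1, "lac[c]" = 2), reversible = TRUE),
    reaction("EX_glc", c("glc[c]" = -1), reversible = TRUE),
    reaction("EX_lac", c("lac[c]" = -1), reversible = TRUE)))
  expect_true(validate_model(ok)$valid)

  # carbon imbalance: 1 glc -> 1 lac
  bad <- metabolic_model(mets, list(
    reaction("FERM", c("glc[c]" = -1, "lac[c]" = 1), reversible = TRUE),
    reaction("EX_glc", c("glc[c]" = -1), reversible = TRUE),
    reaction("EX_lac", c("lac[c]" = -1), reversible = TRUE)))
  v <- validate_model(bad)
  expect_false(v$valid)
  expect_true("C" %in% v$balance$element)

  # metabolite consumed by one irreversible reaction, produced by none
  orp <- metabolic_model(mets, list(
    reaction("USE_X", c("x[c]" = -1, "lac[c]" = 1)),
    reaction("EX_lac", c("lac[c]" = -1), reversible = TRUE)))
  v2 <- validate_model(orp)
  expect_true("x[c]" %in% v2$orphans$metabolite)
  expect_equal(v2$orphans$problem[v2$orphans$metabolite == "x[c]"],
               "consumed-only")

  # bound inversion is a syntax finding (bypassing the constructor check)
  inv <- ok
  inv$reactions[["FERM"]]$lb <- 10
  inv$reactions[["FERM"]]$ub <- -10
  expect_true("FERM" %in% validate_model(inv)$syntax$item)
})

test_that("mutation fuzzer: every seeded single-coefficient imbalance is flagged", {
  mets <- rbind(metabolite("a[c]", formula = "C2H4O2"),
                metabolite("b[c]", formula = "C1H2O1"),
                metabolite("d[c]", formula = "C3H6O3"))
  base <- list(
    reaction("R1", c("a[c]" = -1, "b[c]" = 2), reversible = TRUE),
    reaction("R2", c("a[c]" = -1, "b[c]" = -1, "d[c]" = 1), reversible = TRUE))
  model <- metabolic_model(mets, base)
  expect_equal(nrow(validate_model(model)$balance), 0L)
  set.seed(11)
  for (i in 1:25) {
    mut <- model
    rid <- sample(names(mut$reactions), 1)
    met <- sample(names(mut$reactions[[rid]]$stoichiometry), 1)
    mut$reactions[[rid]]$stoichiometry[met] <-
      mut$reactions[[rid]]$stoichiometry[met] + sample(c(-2, -1, 1, 2), 1)
    if (mut$reactions[[rid]]$stoichiometry[met] == 0)
      mut$reactions[[rid]]$stoichiometry[met] <- 0.5
    v <- validate_model(mut)
    expect_true(rid %in% v$balance$reaction,
                label = paste("mutation", i, "on", rid, "flagged"))
  }
})

test_that("model invariants are enforced at construction", {
  expect_error(reaction("r", c("a[c]" = 0)), "zero stoichiometric")
  expect_error(reaction("r", c("a[c]" = -1), lb = 5, ub = 1), "lower_bound")
  expect_error(reaction("r", c("a[c]" = -1), reversible = FALSE, lb = -2),
               "irreversible")
  expect_error(
    metabolic_model(metabolite("a[c]"),
                    list(reaction("r", c("zz[c]" = -1)))),
    "undeclared metabolite")
  expect_error(
    metabolic_model(metabolite("a[c]"),
                    list(reaction("r", c("a[c]" = -1))), objective_id = "nope"),
    "objective_id")
})
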