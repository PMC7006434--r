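lp_parts <- function(model) {
  list(S = as.matrix(build_stoichiometric_matrix(model)),
       lb = vapply(model$reactions, function(r) r$lb, numeric(1)),
       ub = vapply(model$reactions, function(r) r$ub, numeric(1)),
       rxns = reaction_ids(model))
}

test_that("solve_fba handles bottlenecks, yields and infeasibility", {
  expect_equal(solve_fba(chain_model(cap = 5), "E_out")$objective_value, 5)

  # toy fermentation: glucose uptake fixed at 1, oxidative route disabled,
  # maximal lactate export is the 2:1 fermentative yield
  m <- generate_toy_astrocyte()
  m <- set_bounds(m, "EX_glc_D_e", lb = -1, ub = -1)
  m <- set_bounds(m, "OXIDG", lb = 0, ub = 0)
  expect_equal(solve_fba(m, "EX_lac_L_e")$objective_value, 2, tolerance = 1e-9)

  # forced flux with no substrate producer
  bad <- chain_model()
  bad <- set_bounds(bad, "E_in", lb = 0, ub = 0)     # no uptake
  bad <- set_bounds(bad, "E_out", lb = 1, ub = 1)    # but forced export
  expect_equal(solve_fba(bad, "E_out")$status, "infeasible")
})

test_that("optimal solutions satisfy mass balance and bounds", {
  models <- list(chain_model(), parallel_model(), cycle_model(), lexi_model(),
                 generate_toy_astrocyte())
  for (m in models) {
    p <- lp_parts(m)
    for (oid in reaction_ids(m)[c(1, length(p$rxns))]) {
      sol <- solve_fba(m, oid)
      if (sol$status != "optimal") next
      v <- sol$fluxes
      expect_lte(max(abs(p$S %*% v)), 1e-9 * max(1, max(abs(v))))
      expect_true(all(v >= p$lb - 1e-9 & v <= p$ub + 1e-9))
    }
  }
})

test_that("solver agrees with vertex enumeration on all n<=6 fixtures", {
  fixtures <- list(chain_model(), parallel_model(), cycle_model(),
                   lexi_model())
  for (m in fixtures) {
    p <- lp_parts(m)
    for (k in seq_along(p$rxns)) {
      cvec <- as.numeric(seq_along(p$rxns) == k)
      mine <- solve_fba(m, p$rxns[k])
      oracle <- vertex_optimum(p$S, p$lb, p$ub, cvec)
      expect_equal(mine$status, oracle$status)
      if (mine$status == "optimal")
        expect_equal(mine$objective_value, oracle$objective, tolerance = 1e-8,
                     label = paste(class(m)[1], p$rxns[k]))
    }
  }
  # randomized n<=6 bounded LPs (b = 0, bounds straddling zero)
  set.seed(20)
  for (i in 1:40) {
    n <- sample(3:6, 1); mrows <- sample(1:3, 1)
    A <- matrix(sample(c(-2, -1, 0, 1, 2), mrows * n, replace = TRUE),
                mrows, n)
    lb <- sample(c(-10, -4, 0), n, replace = TRUE)
    ub <- sample(c(3, 8), n, replace = TRUE)
    cvec <- sample(-2:2, n, replace = TRUE)
    mine <- gliaflux:::lp_solve(A, rep(0, mrows), cvec, lb, ub)
    oracle <- vertex_optimum(A, lb, ub, cvec)
    expect_equal(mine$status, oracle$status, label = paste("case", i))
    if (mine$status == "optimal")
      expect_equal(mine$objective, oracle$objective, tolerance = 1e-8,
                   label = paste("case", i))
  }
})

test_that("lexicographic FBA stages behave as specified", {
  m <- chain_model(cap = 5)
  single <- solve_lexicographic(m, "E_out")
  expect_equal(single$objective_value, solve_fba(m, "E_out")$objective_value)

  # two orthogonal objectives on disjoint subnetworks reach their solo optima
  dis <- metabolic_model(
    rbind(metabolite("a[c]"), metabolite("b[c]")),
    list(reaction("EA_in", c("a[c]" = -1), reversible = TRUE, lb = -2, ub = 0),
         reaction("EA_out", c("a[c]" = -1)),
         reaction("EB_in", c("b[c]" = -1), reversible = TRUE, lb = -7, ub = 0),
         reaction("EB_out", c("b[c]" = -1))))
  lex <- solve_lexicographic(dis, c("EA_out", "EB_out"))
  expect_equal(unname(lex$stage_values), c(2, 7), tolerance = 1e-6)

  # knockout lowers stage-1 optimum and raises the stage-2 value;
  # checked against the brute-force vertex oracle
  m <- lexi_model()
  p <- lp_parts(m)
  c1 <- as.numeric(p$rxns == "O1"); c2 <- as.numeric(p$rxns == "O2")
  base <- solve_lexicographic(m, c("O1", "O2"))
  base_oracle <- vertex_lexicographic(p$S, p$lb, p$ub, c1, c2)
  expect_equal(unname(base$stage_values),
               c(base_oracle$stage1, base_oracle$stage2), tolerance = 1e-4)
  ko <- knockout(m, "RP")
  pk <- lp_parts(ko)
  after <- solve_lexicographic(ko, c("O1", "O2"))
  after_oracle <- vertex_lexicographic(pk$S, pk$lb, pk$ub, c1, c2)
  expect_equal(unname(after$stage_values),
               c(after_oracle$stage1, after_oracle$stage2), tolerance = 1e-4)
  expect_lt(after$stage_values[1], base$stage_values[1])  # stage 1 falls
  expect_gt(after$stage_values[2], base$stage_values[2])  # stage 2 rises

  # infeasible stage reports its index
  bad <- set_bounds(m, "E_s", lb = 1, ub = 1)
  r <- solve_lexicographic(bad, c("O1", "O2"))
  expect_equal(r$status, "infeasible")
  expect_equal(attr(r, "stage"), 1L)
})

test_that("canonical fluxes are parsimonious and deterministic", {
  # equivalent parallel routes: split determined by the minimal-total-flux
  # criterion, identical across repeated calls
  m <- parallel_model(cap = 4)
  a <- canonical_fluxes(m, "E_out")
  b <- canonical_fluxes(m, "E_out")
  expect_identical(a$fluxes, b$fluxes)
  expect_equal(a$objective_value, 4)
  expect_equal(unname(a$fluxes["P1"] + a$fluxes["P2"]), 4, tolerance = 1e-6)

  # loop-free network: canonical fluxes equal the unique optimum
  ch <- chain_model(cap = 5)
  expect_equal(unname(canonical_fluxes(ch, "E_out")$fluxes),
               unname(solve_fba(ch, "E_out")$fluxes), tolerance = 1e-6)

  # internal cycle carries zero flux in the canonical solution: verified by
  # brute force over active sets (any optimum has F1 - F2 = 3; the minimal
  # total-flux choice is F2 = 0)
  cy <- cycle_model(cap = 3)
  v <- canonical_fluxes(cy, "E_out")$fluxes
  expect_equal(unname(v[["F1"]]), 3, tolerance = 1e-6)
  expect_equal(unname(v[["F2"]]), 0, tolerance = 1e-6)
})

test_that("flux variability matches structure and the vertex oracle", {
  fva <- flux_variability(chain_model(cap = 5))
  expect_true(all(abs(abs(fva$vmin) - 5) < 1e-8))
  expect_true(all(abs(abs(fva$vmax) - 5) < 1e-8))

  # dead-end branch pinned to (0, 0)
  m <- random_blocked_model(1)
  fva <- flux_variability(m, "EX_c", fraction = 0, reactions = "DEAD")
  expect_equal(c(fva$vmin, fva$vmax), c(0, 0), tolerance = 1e-9)

  # parallel routes at fraction 0: ranges equal vertex-enumeration extrema
  pm <- parallel_model(cap = 4)
  p <- lp_parts(pm)
  fva <- flux_variability(pm, fraction = 0)
  V <- enumerate_vertices(p$S, p$lb, p$ub)
  for (k in seq_along(p$rxns)) {
    expect_equal(fva$vmin[k], min(V[, k]), tolerance = 1e-8, label = p$rxns[k])
    expect_equal(fva$vmax[k], max(V[, k]), tolerance = 1e-8, label = p$rxns[k])
  }
})

test_that("blocked-reaction detection equals the reachability+LP oracle", {
  expect_equal(find_blocked_reactions(generate_toy_astrocyte()), character(0))

  for (seed in 1:6) {
    m <- random_blocked_model(seed)
    mine <- sort(find_blocked_reactions(m))
    oracle <- sort(oracle_blocked(m))
    expect_identical(mine, oracle, label = paste("seed", seed))
    # structural check: reactions needing non-producible metabolites are blocked
    producible <- producible_closure(m)
    for (r in m$reactions) {
      if (r$kind == "exchange" || r$reversible) next
      needs <- names(r$stoichiometry)[r$stoichiometry < 0]
      if (!all(needs %in% producible))
        expect_true(r$id %in% mine, label = paste("seed", seed, r$id))
    }
  }
})

test_that("knockouts zero the reaction and never raise a single objective", {
  m <- generate_toy_astrocyte()
  base <- solve_fba(m, "BIOMASS")$objective_value

  expect_equal(solve_fba(knockout(m, "BIOMASS"), "BIOMASS")$objective_value, 0)
  mid <- knockout(chain_model(), "At")
  expect_equal(solve_fba(mid, "E_out")$objective_value, 0)
  expect_error(knockout(m, "NOT_A_REACTION"), "unknown reaction")

  # monotonicity: feasible-set shrinkage over every toy reaction
  for (id in reaction_ids(m)) {
    ko <- solve_fba(knockout(m, id), "BIOMASS")
    val <- if (ko$status == "optimal") ko$objective_value else 0
    expect_lte(val, base + 1e-9, label = id)
  }

  # knocking out a zero-flux-in-optimum reaction keeps the optimum
  v <- canonical_fluxes(m, "BIOMASS")$fluxes
  zero_id <- names(v)[abs(v) < 1e-9][1]
  expect_equal(solve_fba(knockout(m, zero_id), "BIOMASS")$objective_value,
               base, tolerance = 1e-6)
})

test_that("solver agrees with scipy/HiGHS on the toy astrocyte model", {
  m <- generate_toy_astrocyte(toy_params(include_tibolone = TRUE,
                                         include_estradiol_stub = TRUE))
  p <- lp_parts(m)
  objs <- c("BIOMASS", unname(toy_objectives()))
  probs <- lapply(objs, function(o) list(
    A = p$S, b = rep(0, nrow(p$S)), c = as.numeric(p$rxns == o),
    lb = p$lb, ub = p$ub, maximize = TRUE))
  res <- scipy_lp_batch(probs)
  for (k in seq_along(objs)) {
    mine <- solve_fba(m, objs[k])
    expect_equal(mine$status, res[[k]]$status, label = objs[k])
    expect_equal(mine$objective_value, res[[k]]$objective, tolerance = 1e-7,
                 label = objs[k])
  }
})
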