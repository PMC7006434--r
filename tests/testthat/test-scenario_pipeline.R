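toy_three_scenarios <- function(params = toy_params(), ic50_mean = 0.25) {
  healthy <- generate_toy_astrocyte(params)
  inflamed <- build_scenario(healthy, scenario_spec(
    "inflammatory",
    forced_bounds = list(EX_hdca_e = c(-ic50_mean, -ic50_mean))))
  treated <- build_scenario(inflamed, scenario_spec(
    "treatment",
    added_reactions = c(tibolone_reactions(),
                        estradiol_stub_reactions(params)),
    forced_bounds = list(T1 = c(-params$tibolone_cap, 1000))))
  list(healthy = healthy, inflamed = inflamed, treated = treated)
}

test_that("scenario construction sets bounds and counts as specified", {
  sc <- toy_three_scenarios()
  # healthy: palmitate uptake free up to the medium cap
  expect_equal(unname(get_bounds(sc$healthy, "EX_hdca_e")), c(-1, 1000))
  # inflammatory: palmitate exchange fixed at -IC50_mean
  expect_equal(unname(get_bounds(sc$inflamed, "EX_hdca_e")), c(-0.25, -0.25))
  # treatment adds the ten tibolone reactions plus the five-reaction stub
  expect_equal(length(sc$treated$reactions),
               length(sc$inflamed$reactions) + 10 + 5)
  expect_error(build_scenario(sc$healthy, scenario_spec("inflammatory",
    forced_bounds = list(EX_nope = c(-1, -1)))), "unknown reaction")
  expect_error(scenario_spec("inflammatory"), "palmitate")
  expect_error(scenario_spec("treatment"), "tibolone")
})

test_that("robustness curves match the engineered linear decline", {
  m <- generate_toy_astrocyte()              # u0 = 0.5, lactate z0 = 2
  cv <- robustness_curve(m, "EX_hdca_e", "EX_lac_L_e", n = 101)
  expect_equal(nrow(cv$grid), 101L)
  feas <- cv$grid$feasible
  expect_equal(cv$grid$objective[feas],
               2 * (1 - cv$grid$uptake[feas] / 0.5), tolerance = 1e-6)
  # beyond the route capacity the trailing points are infeasible-flagged zeros
  expect_true(any(!feas))
  expect_true(all(cv$grid$objective[!feas] == 0))
  expect_true(all(which(!feas) > max(which(feas))))

  # a control with no network effect gives a constant curve: two disjoint
  # subnetworks, control in one, objective in the other
  dis <- metabolic_model(
    rbind(metabolite("a[c]"), metabolite("b[c]")),
    list(reaction("EA_in", c("a[c]" = -1), reversible = TRUE, lb = -2, ub = 0),
         reaction("EA_out", c("a[c]" = -1)),
         reaction("EB_in", c("b[c]" = -1), reversible = TRUE, lb = -7, ub = 0),
         reaction("EB_out", c("b[c]" = -1))))
  cv2 <- robustness_curve(dis, "EA_in", "EB_out", n = 21)
  expect_true(all(cv2$grid$feasible))
  expect_equal(diff(range(cv2$grid$objective)), 0, tolerance = 1e-8)
  expect_error(robustness_curve(m, "FERM", "EX_lac_L_e", n = 10),
               "not an exchange")
})

test_that("robustness curves are concave on their feasible prefix", {
  m <- generate_toy_astrocyte()
  for (oid in unname(toy_objectives())) {
    cv <- robustness_curve(m, "EX_hdca_e", oid, n = 201)
    z <- cv$grid$objective[cv$grid$feasible]
    if (length(z) >= 3) {
      d2 <- diff(z, differences = 2)
      expect_lte(max(d2), 1e-6, label = oid)
    }
  }
})

test_that("IC50: half-max crossing, interpolation, undefined cases", {
  # synthetic straight line z(u) = 1 - u on [0, 1] crosses half-max at 0.5
  line <- structure(list(
    control_id = "c", objective_id = "o",
    grid = data.frame(uptake = seq(0, 1, length.out = 101),
                      objective = 1 - seq(0, 1, length.out = 101),
                      feasible = TRUE)), class = "gf_robustness")
  expect_equal(ic50(line), 0.5, tolerance = 1e-9)

  flat <- line
  flat$grid$objective <- 1
  expect_error(ic50(flat), "undefined IC50")

  # toy objectives: IC50 equals the analytic u0/2 within grid resolution
  m <- generate_toy_astrocyte()            # u0 = 0.5
  res <- mean_ic50(m, "EX_hdca_e", unname(toy_objectives()), n = 1000)
  spacing <- 1 / 999
  for (oid in names(res$values))
    expect_lt(abs(res$values[[oid]] - 0.25), 2 * spacing)
  expect_lt(abs(res$mean - 0.25), 2 * spacing)
  expect_equal(res$sd, 0, tolerance = 1e-6)
  expect_equal(res$undefined, character(0))

  # mean/sd arithmetic on unequal synthetic curves
  c1 <- line; c2 <- line
  c2$grid$objective <- pmax(1 - 2 * c2$grid$uptake, 0)   # IC50 = 0.25
  vals <- c(ic50(c1), ic50(c2))
  expect_equal(mean(vals), 0.375)
})

test_that("IC50 is stable under grid refinement", {
  m <- generate_toy_astrocyte()
  v1 <- ic50(robustness_curve(m, "EX_hdca_e", "DM_atp_c", n = 1000))
  v2 <- ic50(robustness_curve(m, "EX_hdca_e", "DM_atp_c", n = 4000))
  expect_lte(abs(v1 - v2), 2 / 999)
})

test_that("fold changes implement the zero-branch rule and threshold", {
  # printed worked example: (0.39 -> 1.28) gives 2.28
  expect_equal(fold_change_value(0.39, 1.28), 2.28, tolerance = 0.005)
  # zero-reference branch returns the alternative flux
  expect_equal(fold_change_value(0, 0.7), 0.7)
  expect_equal(fold_change_value(0, 0), 0)
  expect_equal(fold_change_value(-0.26, 2.44), (2.44 + 0.26) / 0.26,
               tolerance = 1e-9)

  a <- c(R1 = 1, R2 = 0.5, R3 = 0)
  b <- c(R1 = 1, R2 = 2.0, R3 = -3, R4 = 9)      # R4 not shared: dropped
  fc <- fold_changes(a, b, threshold = 2)
  expect_equal(fc$reaction_id, c("R2", "R3"))    # sorted by |fold change|
  expect_equal(fc$fold_change, c(3, -3))
  expect_equal(nrow(attr(fc, "all")), 3L)

  # identical distributions: empty at any positive threshold
  expect_equal(nrow(fold_changes(a, a, threshold = 0.1)), 0L)
})

test_that("knockout classification finds the engineered reaction classes", {
  sc <- toy_three_scenarios()
  kc <- classify_knockouts(sc$healthy, sc$inflamed, sc$treated,
                           objective_id = "EX_gln_L_e")
  lab <- stats::setNames(kc$label, kc$reaction_id)

  # freeing the shared capacity pool helps the stage-2 objective
  expect_equal(unname(lab["CYSt"]), "pro_inflammatory")
  expect_equal(unname(lab["EX_cys_L_e"]), "pro_inflammatory")
  # oxygen path: >= 2-fold change between scenarios, knockout kills the
  # (palmitate-forced) objective
  expect_equal(unname(lab["O2t"]), "anti_inflammatory")
  expect_equal(unname(lab["EX_o2_e"]), "anti_inflammatory")
  # sole entry point of the treatment effect
  expect_equal(unname(lab["T1"]), "treatment_essential")
  expect_equal(unname(lab["ESTREL"]), "treatment_essential")
  # parallel tibolone conversions are individually dispensable
  expect_equal(unname(lab["T2"]), "neutral")
  expect_equal(unname(lab["T9"]), "neutral")
  expect_equal(unname(lab["FERM"]), "neutral")

  # labels are mutually exclusive and cover all candidates
  expect_equal(anyDuplicated(kc$reaction_id), 0L)
  expect_true(all(kc$label %in% c("pro_inflammatory", "anti_inflammatory",
                                  "treatment_essential", "neutral")))
})

test_that("knockout classification is invariant to reaction ordering", {
  sc <- toy_three_scenarios()
  perm <- function(m, seed) {
    set.seed(seed)
    ord <- sample(seq_along(m$reactions))
    metabolic_model(m$metabolites, m$reactions[ord],
                    objective_id = m$objective_id)
  }
  kc1 <- classify_knockouts(sc$healthy, sc$inflamed, sc$treated, "EX_gln_L_e")
  kc2 <- classify_knockouts(perm(sc$healthy, 4), perm(sc$inflamed, 5),
                            perm(sc$treated, 6), "EX_gln_L_e")
  expect_identical(kc1[order(kc1$reaction_id), c("reaction_id", "label")],
                   kc2[order(kc2$reaction_id), c("reaction_id", "label")])
})

test_that("subsystem activity tallies activated/inactivated percentages", {
  subs <- c(R1 = "glycolysis", R2 = "glycolysis", R3 = "glycolysis",
            R4 = "glycolysis", R5 = "tca")
  ref <- c(R1 = 0, R2 = 1, R3 = 2, R4 = 0.5, R5 = 0)
  alt <- c(R1 = 1, R2 = 1, R3 = 2, R4 = 0.5, R5 = 0)
  sa <- subsystem_activity(ref, alt, subs)
  g <- sa[sa$subsystem == "glycolysis", ]
  expect_equal(g$pct_activated, 25)        # 1 of 4 newly active
  expect_equal(g$pct_inactivated, 0)
  expect_equal(sa[sa$subsystem == "tca", ]$pct_activated, 0)

  # identical fluxes: zero everywhere
  sa0 <- subsystem_activity(ref, ref, subs)
  expect_true(all(sa0$pct_activated == 0 & sa0$pct_inactivated == 0))

  # untagged reactions group under "unassigned"
  sa1 <- subsystem_activity(c(R9 = 0), c(R9 = 1),
                            c(R9 = NA_character_))
  expect_equal(sa1$subsystem, "unassigned")
  expect_equal(sa1$pct_activated, 100)

  # hand count on the toy inflammation comparison
  sc <- toy_three_scenarios()
  hf <- canonical_fluxes(sc$healthy)
  inf <- canonical_fluxes(sc$inflamed)
  sa2 <- subsystem_activity(hf, inf, model_subsystems(sc$healthy))
  fat <- sa2[sa2$subsystem == "Fatty acid oxidation", ]
  # all 3 palmitate reactions (exchange, transport, beta-oxidation) activate
  expect_equal(fat$n_reactions, 3L)
  expect_equal(fat$pct_activated, 100)
})

test_that("pipeline runs end to end, honors grid size, and is deterministic", {
  out1 <- withr::local_tempdir()
  cfg <- pipeline_config(grid_n = 40, outdir = out1, seed = 7)
  res <- run_pipeline(cfg)
  files <- list.files(out1)
  expect_true(all(c("healthy_fluxes.tsv", "inflammatory_fluxes.tsv",
                    "treatment_fluxes.tsv", "knockout_classification.tsv",
                    "foldchanges_healthy_vs_inflammatory.tsv",
                    "foldchanges_inflammatory_vs_treatment.tsv",
                    "subsystem_activity.tsv", "summary.json",
                    "run_log.txt") %in% files))
  rob <- utils::read.delim(file.path(out1, "robustness_EX_lac_L_e.tsv"))
  expect_equal(nrow(rob), 40L)

  # byte-identical outputs under the same config and seed
  out2 <- withr::local_tempdir()
  run_pipeline(pipeline_config(grid_n = 40, outdir = out2, seed = 7))
  for (f in files)
    expect_identical(readLines(file.path(out2, f)),
                     readLines(file.path(out1, f)), label = f)

  # a failing stage names itself
  bad <- pipeline_config(model = "/nonexistent/file.xml",
                         outdir = withr::local_tempdir())
  expect_error(run_pipeline(bad), "stage 'model'")
})
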