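# Synthetic astrocyte-like toy network.
#
# The network is engineered so that every pipeline stage has a closed-form
# ground truth:
#   * glucose fermentation yields `lactate_yield` lactate per glucose and the
#     oxidative route yields `atp_yield_ox` ATP per glucose (the classical 36,
#     matching the objective-table stoichiometry rather than modern 30-32
#     estimates);
#   * every objective route consumes a shared finite mitochondrial
#     oxidative-capacity token (`ctrf`, supply `capacity_pool` per hour), and
#     palmitate beta-oxidation drains that pool at rate capacity_pool /
#     inhibition_u0 per unit uptake, so each objective declines linearly to 0
#     at forced uptake u0 and has IC50 exactly u0 / 2;
#   * the estradiol-effect stub regenerates part of the pool from estradiol,
#     so tibolone treatment measurably shifts fluxes and knocking out the
#     tibolone exchange abolishes the effect.

#' Parameters of the synthetic toy astrocyte network
#'
#' @param glucose_cap,glutamate_cap,glycine_cap,cysteine_cap,palmitate_cap
#'   uptake caps (mmol/gDW/h) for the corresponding exchange reactions.
#' @param o2_cap,nh4_cap,h2o_cap uptake caps for small-molecule exchanges.
#' @param capacity_pool supply rate of the shared mitochondrial
#'   oxidative-capacity token; every objective route is sized to consume the
#'   whole pool at its unconstrained optimum.
#' @param atp_yield_ox ATP per glucose through the oxidative route
#'   (default 36).
#' @param lactate_yield lactate per glucose through fermentation (default 2).
#' @param inhibition_u0 forced palmitate uptake at which every objective
#'   reaches zero (must lie in (0, 1]); IC50 of each objective is u0/2.
#' @param tibolone_cap tibolone uptake cap in the treatment scenario.
#' @param relief_per_estradiol capacity-token units regenerated per estradiol
#'   processed by the stub relief reaction.
#' @param include_tibolone,include_estradiol_stub append the tibolone
#'   reaction set / the estradiol-effect stub set to the generated model.
#' @param seed integer seed (used by companion generators).
#' @return object of class \code{"gf_toy_params"}.
#' @export
toy_params <- function(glucose_cap = 1, glutamate_cap = 1, glycine_cap = 2,
                       cysteine_cap = 1, palmitate_cap = 1, o2_cap = 25,
                       nh4_cap = 5, h2o_cap = 10, capacity_pool = 1,
                       atp_yield_ox = 36L, lactate_yield = 2L,
                       inhibition_u0 = 0.5, tibolone_cap = 2.5,
                       relief_per_estradiol = 0.5,
                       include_tibolone = FALSE,
                       include_estradiol_stub = FALSE, seed = 1L) {
  stopifnot(atp_yield_ox == as.integer(atp_yield_ox), atp_yield_ox > 0,
            lactate_yield == as.integer(lactate_yield), lactate_yield > 0,
            inhibition_u0 > 0, inhibition_u0 <= 1,
            glucose_cap > 0, capacity_pool > 0)
  structure(list(glucose_cap = glucose_cap, glutamate_cap = glutamate_cap,
                 glycine_cap = glycine_cap, cysteine_cap = cysteine_cap,
                 palmitate_cap = palmitate_cap, o2_cap = o2_cap,
                 nh4_cap = nh4_cap, h2o_cap = h2o_cap,
                 capacity_pool = capacity_pool,
                 atp_yield_ox = as.integer(atp_yield_ox),
                 lactate_yield = as.integer(lactate_yield),
                 inhibition_u0 = inhibition_u0, tibolone_cap = tibolone_cap,
                 relief_per_estradiol = relief_per_estradiol,
                 include_tibolone = include_tibolone,
                 include_estradiol_stub = include_estradiol_stub,
                 seed = as.integer(seed)),
            class = "gf_toy_params")
}

#' Default growth-medium definition for the toy network
#'
#' A DMEM-like medium restricted to the exchanges present in the toy:
#' glucose, glutamate, glycine, cysteine, palmitate, oxygen, ammonia, water
#' and the capacity token as inputs; the gliotransmitters and end products
#' (glutamine, D-serine, reduced glutathione, lactate, glucose, glutamate,
#' CO2, water, ammonia) as outputs.
#'
#' @param params a \code{gf_toy_params}.
#' @return a \code{gf_medium}.
#' @export
default_medium <- function(params = toy_params()) {
  medium(
    uptake = c(EX_glc_D_e = params$glucose_cap,
               EX_glu_L_e = params$glutamate_cap,
               EX_gly_e = params$glycine_cap,
               EX_cys_L_e = params$cysteine_cap,
               EX_hdca_e = params$palmitate_cap,
               EX_o2_e = params$o2_cap,
               EX_nh4_c = params$nh4_cap,
               EX_h2o_e = params$h2o_cap,
               EX_ctrf_e = params$capacity_pool),
    outputs = c("EX_lac_L_e", "EX_gln_L_e", "EX_ser_D_e", "EX_gthrd_e",
                "EX_glc_D_e", "EX_glu_L_e", "EX_co2_e", "EX_h2o_e",
                "EX_nh4_c"))
}

#' Objective-function map of the toy network
#'
#' Maps the five objective ids of the evaluation table (glutamate-glutamine
#' cycle, glycine to D-serine, lactate from glucose, ATP from glucose,
#' cysteine to reduced glutathione) to the toy reactions whose flux realizes
#' each conversion.
#'
#' @return named character vector: objective id -> toy reaction id.
#' @export
toy_objectives <- function() {
  c(Glu2Gln = "EX_gln_L_e", Gly2SerD = "EX_ser_D_e", Glc2Lac = "EX_lac_L_e",
    Glc2ATP = "DM_atp_c", Cys2GTHRD = "EX_gthrd_e")
}

toy_metabolites <- function() {
  rbind(
    metabolite("glc_D[e]", "D-glucose", "C6H12O6"),
    metabolite("glc_D[c]", "D-glucose", "C6H12O6"),
    metabolite("glu_L[e]", "L-glutamate", "C5H9NO4"),
    metabolite("glu_L[c]", "L-glutamate", "C5H9NO4"),
    metabolite("gly[e]", "glycine", "C2H5NO2"),
    metabolite("gly[c]", "glycine", "C2H5NO2"),
    metabolite("cys_L[e]", "L-cysteine", "C3H7NO2S"),
    metabolite("cys_L[c]", "L-cysteine", "C3H7NO2S"),
    metabolite("hdca[e]", "palmitate", "C16H32O2"),
    metabolite("hdca[m]", "palmitate", "C16H32O2"),
    metabolite("lac_L[e]", "L-lactate", "C3H6O3"),
    metabolite("lac_L[c]", "L-lactate", "C3H6O3"),
    metabolite("gln_L[e]", "L-glutamine", "C5H10N2O3"),
    metabolite("gln_L[c]", "L-glutamine", "C5H10N2O3"),
    metabolite("ser_D[e]", "D-serine", "C3H7NO3"),
    metabolite("ser_D[c]", "D-serine", "C3H7NO3"),
    metabolite("gthrd[e]", "reduced glutathione", "C10H17N3O6S"),
    metabolite("gthrd[c]", "reduced glutathione", "C10H17N3O6S"),
    metabolite("o2[e]", "oxygen", "O2"),
    metabolite("o2[c]", "oxygen", "O2"),
    metabolite("co2[e]", "carbon dioxide", "CO2"),
    metabolite("co2[c]", "carbon dioxide", "CO2"),
    metabolite("h2o[e]", "water", "H2O"),
    metabolite("h2o[c]", "water", "H2O"),
    metabolite("nh4[c]", "ammonia", "NH3"),
    # energy/capacity tokens: Q and P are bookkeeping elements for the
    # adenylate moiety; the capacity token deliberately carries no formula
    metabolite("atp[c]", "ATP (energy token)", "QP3"),
    metabolite("adp[c]", "ADP (energy token)", "QP2"),
    metabolite("pi[c]", "phosphate (energy token)", "P"),
    metabolite("ctrf[e]", "mitochondrial oxidative capacity token", NA),
    metabolite("ctrf[m]", "mitochondrial oxidative capacity token", NA))
}

#' Generate the synthetic toy astrocyte model
#'
#' Produces a 35-reaction compartmentalized network (extracellular, cytosol,
#' mitochondrion) covering glucose fermentation to lactate, full glucose
#' oxidation to ATP, glutamine synthesis from glutamate, D-serine synthesis
#' from glycine, glutathione synthesis from cysteine/glutamate/glycine,
#' palmitate beta-oxidation, a biomass pseudo-reaction, and the shared
#' capacity-token pool that couples palmitate uptake to every objective.
#' The default medium is already applied to the exchange bounds. With the
#' corresponding flags, the ten-reaction tibolone set and the five-reaction
#' estradiol-effect stub are appended.
#'
#' @param params a \code{gf_toy_params}.
#' @return a \code{gf_model} with objective \code{"BIOMASS"}.
#' @export
generate_toy_astrocyte <- function(params = toy_params()) {
  stopifnot(inherits(params, "gf_toy_params"))
  C <- params$capacity_pool
  Y <- params$atp_yield_ox
  L <- params$lactate_yield
  u0 <- params$inhibition_u0

  ex <- function(id, met, subsystem = "Exchange")
    reaction(id, stats::setNames(-1, met), reversible = TRUE,
             subsystem = subsystem)
  tr <- function(id, from, to, gene = NULL, subsystem = "Transport")
    reaction(id, stats::setNames(c(-1, 1), c(from, to)), reversible = TRUE,
             gpr = gene, subsystem = subsystem)

  rxns <- list(
    # exchanges (bounds shaped by the medium below)
    ex("EX_glc_D_e", "glc_D[e]"),
    ex("EX_glu_L_e", "glu_L[e]"),
    ex("EX_gly_e", "gly[e]"),
    ex("EX_cys_L_e", "cys_L[e]"),
    ex("EX_hdca_e", "hdca[e]", "Fatty acid oxidation"),
    ex("EX_lac_L_e", "lac_L[e]"),
    ex("EX_gln_L_e", "gln_L[e]"),
    ex("EX_ser_D_e", "ser_D[e]"),
    ex("EX_gthrd_e", "gthrd[e]"),
    ex("EX_o2_e", "o2[e]"),
    ex("EX_co2_e", "co2[e]"),
    ex("EX_h2o_e", "h2o[e]"),
    ex("EX_nh4_c", "nh4[c]"),
    ex("EX_ctrf_e", "ctrf[e]"),
    # reversible transports
    tr("GLCt", "glc_D[e]", "glc_D[c]", "SLC2A1"),
    tr("GLUt", "glu_L[e]", "glu_L[c]", "SLC1A2 or SLC1A3",
       "Glutamate-glutamine cycle"),
    tr("GLYt", "gly[e]", "gly[c]", "SLC6A9", "Serine and glycine metabolism"),
    tr("CYSt", "cys_L[e]", "cys_L[c]", "SLC7A11", "Glutathione metabolism"),
    tr("HDCAt", "hdca[e]", "hdca[m]", "CD36", "Fatty acid oxidation"),
    tr("LACt", "lac_L[c]", "lac_L[e]", "SLC16A1", "Glycolysis and fermentation"),
    tr("GLNt", "gln_L[c]", "gln_L[e]", "SLC38A3", "Glutamate-glutamine cycle"),
    tr("SERDt", "ser_D[c]", "ser_D[e]", "SLC1A4", "Serine and glycine metabolism"),
    tr("GTHRDt", "gthrd[c]", "gthrd[e]", "ABCC1", "Glutathione metabolism"),
    tr("O2t", "o2[e]", "o2[c]"),
    tr("CO2t", "co2[e]", "co2[c]"),
    tr("H2Ot", "h2o[e]", "h2o[c]", "AQP9"),
    tr("CTRFt", "ctrf[e]", "ctrf[m]", "SLC25A20"),
    # internal chemistry
    reaction("FERM",
             c("glc_D[c]" = -1, "ctrf[m]" = -C / params$glucose_cap,
               "lac_L[c]" = L),
             gpr = "GAPDH and PKM and LDHA",
             name = "glucose fermentation to lactate (lumped)",
             subsystem = "Glycolysis and fermentation"),
    reaction("OXIDG",
             c("glc_D[c]" = -1, "o2[c]" = -6, "adp[c]" = -Y, "pi[c]" = -Y,
               "co2[c]" = 6, "h2o[c]" = 6, "atp[c]" = Y),
             gpr = "NDUFS1 and SDHA and COX4I1 and ATP5F1A",
             name = "glucose oxidation to ATP (lumped)",
             subsystem = "Oxidative phosphorylation"),
    reaction("GLYSER",
             c("gly[c]" = -2, "o2[c]" = -0.5,
               "ctrf[m]" = -C / (params$glycine_cap / 2),
               "ser_D[c]" = 1, "co2[c]" = 1, "nh4[c]" = 1),
             gpr = "SHMT1 and GLDC and AMT",
             name = "glycine to D-serine (lumped SHMT/GCS)",
             subsystem = "Serine and glycine metabolism"),
    reaction("GLNS",
             c("glu_L[c]" = -1, "nh4[c]" = -1, "atp[c]" = -1,
               "ctrf[m]" = -C / params$glutamate_cap,
               "gln_L[c]" = 1, "adp[c]" = 1, "pi[c]" = 1, "h2o[c]" = 1),
             gpr = "GLUL", name = "glutamine synthetase",
             subsystem = "Glutamate-glutamine cycle"),
    reaction("GTHS",
             c("cys_L[c]" = -1, "glu_L[c]" = -1, "gly[c]" = -1,
               "atp[c]" = -2, "ctrf[m]" = -C / params$cysteine_cap,
               "gthrd[c]" = 1, "h2o[c]" = 2, "adp[c]" = 2, "pi[c]" = 2),
             gpr = "GCLC and GSS", name = "glutathione synthesis (lumped)",
             subsystem = "Glutathione metabolism"),
    reaction("BETAOX",
             c("hdca[m]" = -1, "o2[c]" = -23, "ctrf[m]" = -C / u0,
               "co2[c]" = 16, "h2o[c]" = 16),
             gpr = "CPT1A and ACADVL and HADHA",
             name = "palmitate beta-oxidation (lumped)",
             subsystem = "Fatty acid oxidation"),
    reaction("DM_atp_c",
             c("atp[c]" = -1, "ctrf[m]" = -C / (Y * params$glucose_cap),
               "adp[c]" = 1, "pi[c]" = 1),
             name = "ATP demand", subsystem = "Oxidative phosphorylation"),
    reaction("BIOMASS",
             c("atp[c]" = -2, "glu_L[c]" = -0.2, "gly[c]" = -0.2,
               "cys_L[c]" = -0.05, "ctrf[m]" = -C / 2,
               "adp[c]" = 2, "pi[c]" = 2),
             name = "biomass (growth/maintenance pseudo-reaction)",
             subsystem = "Growth", kind = "pseudo"))

  model <- metabolic_model(toy_metabolites(), rxns, objective_id = "BIOMASS")
  model <- apply_medium(model, default_medium(params))

  if (params$include_tibolone)
    model <- append_reactions(model, tibolone_reactions())
  if (params$include_estradiol_stub)
    model <- append_reactions(model, estradiol_stub_reactions(params))

  check <- solve_fba(model, "BIOMASS")
  if (check$status != "optimal" || check$objective_value <= 1e-9)
    stop("toy generation error: healthy model infeasible for biomass ",
         "with the given parameters")
  model
}

# append reactions (and any new metabolites they reference) to a model
append_reactions <- function(model, rxns) {
  new_mets <- setdiff(unlist(lapply(rxns, function(r) names(r$stoichiometry))),
                      metabolite_ids(model))
  mets <- model$metabolites
  steroid_names <- c(
    "Tibolone[e]" = "tibolone", "a3OHtibolone[e]" = "3-alpha-hydroxytibolone",
    "b3OHtibolone[e]" = "3-beta-hydroxytibolone",
    "d4tibolone[e]" = "delta-4 tibolone isomer",
    "a3SOtibolone[e]" = "sulfated 3-alpha-hydroxytibolone",
    "estradiol[c]" = "estradiol", "prgstrn[c]" = "progesterone",
    "tststerone[c]" = "testosterone", "dstrdl[c]" = "deactivated estradiol",
    "dstrdl[e]" = "deactivated estradiol")
  for (m in new_mets)
    mets <- rbind(mets, metabolite(
      m, name = if (m %in% names(steroid_names)) steroid_names[[m]] else m))
  metabolic_model(mets, c(model$reactions, rxns),
                  objective_id = model$objective_id)
}

#' The ten tibolone reactions of the treatment scenario
#'
#' Exactly the printed reaction set recreating tibolone metabolism: the
#' tibolone exchange (T1), interconversion to the 3-alpha/3-beta hydroxy
#' metabolites (T2, T3), delta-4 isomer formation (T4, T5), the estradiol
#' receptor agonist conversions (T6, T7), progesterone/androgen receptor
#' activation by the delta-4 isomer (T8), sulfation to the inactive blood
#' form and its sink (T9, T10). The steroid metabolites carry no elemental
#' formulas (the printed stoichiometries are receptor-level conversions, not
#' balanced chemistry), so mass-balance validation skips them.
#'
#' @return list of ten \code{gf_reaction}s (T1..T10).
#' @export
tibolone_reactions <- function() {
  tbl <- list(
    c("T1", "Tibolone[e] <=>", "Tibolone exchange reaction", ""),
    c("T2", "Tibolone[e] <=> a3OHtibolone[e]",
      "3a-hydroxytibolone interconversion", "ADH4 or ADH5 or ADH7"),
    c("T3", "Tibolone[e] <=> b3OHtibolone[e]",
      "3b-hydroxytibolone interconversion", "ADH4 or ADH5 or ADH7"),
    c("T4", "Tibolone[e] -> d4tibolone[e]", "D4-tibolone isomer formation", ""),
    c("T5", "b3OHtibolone[e] -> d4tibolone[e]",
      "D4-tibolone isomer formation from 3b-hydroxytibolone", ""),
    c("T6", "a3OHtibolone[e] -> estradiol[c]",
      "estradiol receptor agonist action of 3a-hydroxytibolone", ""),
    c("T7", "b3OHtibolone[e] -> estradiol[c]",
      "estradiol receptor agonist action of 3b-hydroxytibolone", ""),
    c("T8", "d4tibolone[e] -> prgstrn[c] + tststerone[c]",
      "progesterone and androgen receptor activation by the D4 isomer", ""),
    c("T9", "a3OHtibolone[e] <=> a3SOtibolone[e]",
      "3a-hydroxytibolone conversion to sulfated inactive compound", ""),
    c("T10", "a3SOtibolone[e] ->", "tibolone inactive form in blood", ""))
  lapply(tbl, function(row) {
    p <- parse_reaction_formula(row[2])
    reaction(row[1], p$stoichiometry, reversible = p$reversible,
             name = row[3], gpr = if (nzchar(row[4])) row[4] else NULL,
             subsystem = "Steroid metabolism")
  })
}

#' The estradiol-effect stub reaction set
#'
#' A deliberately fictional five-reaction stand-in for the estradiol-derived
#' reaction catalog of the treatment scenario (the real set is hundreds of
#' database reactions and out of desk scope): a relief reaction regenerating
#' part of the mitochondrial capacity pool per estradiol processed, export of
#' the deactivated steroid, and sinks for the progesterone/testosterone
#' receptor tokens.
#'
#' @param params a \code{gf_toy_params} (sets the relief stoichiometry).
#' @return list of five \code{gf_reaction}s.
#' @export
estradiol_stub_reactions <- function(params = toy_params()) {
  list(
    reaction("ESTREL",
             c("estradiol[c]" = -1, "ctrf[m]" = params$relief_per_estradiol,
               "dstrdl[c]" = 1),
             gpr = "CYP27A1",
             name = "estradiol-mediated relief of oxidative capacity (stub)",
             subsystem = "Steroid metabolism"),
    reaction("DSTRDLt", c("dstrdl[c]" = -1, "dstrdl[e]" = 1),
             reversible = TRUE, gpr = "ABCD3",
             name = "deactivated estradiol export (stub)",
             subsystem = "Steroid metabolism"),
    reaction("EX_dstrdl_e", c("dstrdl[e]" = -1), reversible = FALSE,
             name = "deactivated estradiol sink (stub)",
             subsystem = "Steroid metabolism"),
    reaction("DM_prgstrn_c", c("prgstrn[c]" = -1), reversible = FALSE,
             name = "progesterone receptor token sink (stub)",
             subsystem = "Steroid metabolism"),
    reaction("DM_tststerone_c", c("tststerone[c]" = -1), reversible = FALSE,
             name = "testosterone receptor token sink (stub)",
             subsystem = "Steroid metabolism"))
}

#' Generate a synthetic expression profile over the model's genes
#'
#' One value per distinct gene appearing in any GPR, drawn log-normally
#' (meanlog \code{mu}, sdlog \code{sigma}); a stand-in for mean expression
#' values of a tissue expression study. Deterministic per seed.
#'
#' @param model a \code{gf_model} with GPR-bearing reactions.
#' @param seed integer seed.
#' @param mu,sigma log-normal parameters (defaults 2.0, 0.5).
#' @return named numeric vector gene -> expression.
#' @export
generate_expression_profile <- function(model, seed = 1L, mu = 2.0,
                                        sigma = 0.5) {
  genes <- sort(unique(unlist(lapply(model$reactions,
                                     function(r) gpr_genes(r$gpr)))))
  if (length(genes) == 0) stop("model has no GPR-bearing reactions")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stats::setNames(stats::rlnorm(length(genes), meanlog = mu, sdlog = sigma),
                  genes)
}
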