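# End-to-end pipeline: constrain -> gap-fill -> prune blocked -> healthy FBA
# -> robustness/IC50 -> inflammatory -> treatment -> fold changes -> knockout
# classification -> reports.

#' Pipeline configuration
#'
#' @param model \code{"synthetic"} (generate the toy network) or the path to
#'   an SBML file.
#' @param toy a \code{gf_toy_params} used when \code{model = "synthetic"}.
#' @param expression \code{"synthetic"} (generate a profile over the model's
#'   genes) or the path of an expression TSV.
#' @param medium \code{NULL} (toy default medium), a \code{gf_medium}, or the
#'   path of a medium TSV.
#' @param objectives named character vector of objective reaction ids
#'   (default: the toy objective map).
#' @param classification_objective stage-2 objective used for knockout
#'   classification (default: the glutamate-glutamine objective).
#' @param control_id control exchange for the robustness analysis (default:
#'   the palmitate exchange).
#' @param grid_n,u_lo,u_hi robustness grid (default 1000 points on [0, 1]).
#' @param threshold fold-change reporting threshold (default 2).
#' @param eps relative tolerance for knockout classification.
#' @param bound_cap expression-scaling flux cap (default 1000).
#' @param seed integer seed for the synthetic expression profile.
#' @param outdir output directory for reports.
#' @return configuration list of class \code{"gf_config"}.
#' @export
pipeline_config <- function(model = "synthetic", toy = toy_params(),
                            expression = "synthetic", medium = NULL,
                            objectives = toy_objectives(),
                            classification_objective = "Glu2Gln",
                            control_id = "EX_hdca_e",
                            grid_n = 1000, u_lo = 0, u_hi = 1,
                            threshold = 2, eps = 1e-6, bound_cap = 1000,
                            seed = 1L, outdir = tempfile("gliaflux_run_")) {
  structure(list(model = model, toy = toy, expression = expression,
                 medium = medium, objectives = objectives,
                 classification_objective = classification_objective,
                 control_id = control_id, grid_n = grid_n, u_lo = u_lo,
                 u_hi = u_hi, threshold = threshold, eps = eps,
                 bound_cap = bound_cap, seed = as.integer(seed),
                 outdir = outdir),
            class = "gf_config")
}

#' Run the full three-scenario pipeline
#'
#' Executes: model construction, expression constraining, gap filling of
#' reactions without correlated expression, blocked-reaction pruning, medium
#' application, healthy-scenario FBA, per-objective robustness and IC50,
#' inflammatory scenario (palmitate forced to the mean IC50), treatment
#' scenario (tibolone set + estradiol stub), fold-change comparisons,
#' knockout classification and subsystem-activity summaries. All reports are
#' TSV/JSON with deterministic ordering and formatting; identical
#' configuration and seed give byte-identical outputs.
#'
#' @param config a \code{gf_config} from [pipeline_config()].
#' @return (invisibly) a list with the scenario models, flux distributions,
#'   IC50 results, fold-change records, knockout classification, subsystem
#'   summary and the output directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "gf_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- model source ---------------------------------------------------------
  base <- stage("model", {
    if (identical(config$model, "synthetic")) {
      say("model: synthetic toy astrocyte (seed ", config$toy$seed, ")")
      generate_toy_astrocyte(config$toy)
    } else {
      say("model: SBML ", config$model)
      read_sbml(config$model)
    }
  })
  say("model size: ", nrow(base$metabolites), " metabolites, ",
      length(base$reactions), " reactions")

  # --- expression constraining + gap fill ----------------------------------
  profile <- stage("expression", {
    if (identical(config$expression, "synthetic")) {
      say("expression: synthetic log-normal profile (seed ", config$seed, ")")
      generate_expression_profile(base, seed = config$seed)
    } else {
      say("expression: ", config$expression)
      read_expression_table(config$expression)
    }
  })

  constrained <- stage("constrain", {
    # reactions whose GPR genes are entirely absent from the profile have no
    # correlated expression: they form the gap-filling candidate pool
    uncorr <- vapply(base$reactions, function(r) {
      g <- gpr_genes(r$gpr)
      length(g) > 0 && !any(g %in% names(profile))
    }, logical(1))
    pool <- base$reactions[uncorr]
    trimmed <- if (any(uncorr)) {
      say("constrain: ", sum(uncorr),
          " reaction(s) without correlated expression removed for gap filling")
      metabolic_model(base$metabolites, base$reactions[!uncorr],
                      objective_id = base$objective_id)
    } else base
    m <- apply_expression_bounds(trimmed, profile, bound_cap = config$bound_cap)
    gf <- gap_fill(m, pool, objective_id = m$objective_id)
    say("gap fill: added [", paste(gf$added, collapse = ", "),
        "], objective feasible: ", gf$feasible)
    gf$model
  })

  healthy <- stage("medium+prune", {
    med <- if (is.null(config$medium)) {
      if (!identical(config$model, "synthetic"))
        stop("a medium file is required for SBML model sources")
      default_medium(config$toy)
    } else if (inherits(config$medium, "gf_medium")) config$medium
    else read_medium(config$medium)
    m <- apply_medium(constrained, med)
    blocked <- find_blocked_reactions(m)
    say("blocked reactions removed: [", paste(blocked, collapse = ", "), "]")
    if (length(blocked) > 0) {
      keep <- setdiff(reaction_ids(m), blocked)
      m <- metabolic_model(m$metabolites, m$reactions[keep],
                           objective_id = m$objective_id)
    }
    m
  })

  objective_ids <- vapply(config$objectives,
                          function(o) resolve_reaction_id(healthy, o),
                          character(1))

  # --- healthy scenario -----------------------------------------------------
  healthy_flux <- stage("healthy FBA", canonical_fluxes(healthy))
  say("healthy biomass: ", fmt_num(healthy_flux$objective_value))
  write_flux_report(healthy_flux, file.path(config$outdir, "healthy_fluxes.tsv"))

  # --- robustness / IC50 ----------------------------------------------------
  ic <- stage("robustness", mean_ic50(
    healthy, config$control_id, objective_ids,
    n = config$grid_n, u_lo = config$u_lo, u_hi = config$u_hi))
  say("IC50 per objective: ",
      paste(names(ic$values), fmt_num(ic$values), sep = "=", collapse = ", "))
  say("IC50 mean: ", fmt_num(ic$mean), " sd: ", fmt_num(ic$sd))
  for (oid in names(ic$curves)) {
    g <- ic$curves[[oid]]$grid
    g$objective <- fmt_num(g$objective)
    g$uptake <- fmt_num(g$uptake)
    utils::write.table(g, file.path(config$outdir,
                                    paste0("robustness_", oid, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- inflammatory scenario ------------------------------------------------
  inflamed <- stage("inflammatory", build_scenario(healthy, scenario_spec(
    "inflammatory",
    forced_bounds = stats::setNames(
      list(c(-ic$mean, -ic$mean)), config$control_id))))
  inflamed_flux <- canonical_fluxes(inflamed)
  say("inflamed biomass: ", fmt_num(inflamed_flux$objective_value))
  write_flux_report(inflamed_flux,
                    file.path(config$outdir, "inflammatory_fluxes.tsv"))

  fc_hi <- fold_changes(healthy_flux, inflamed_flux,
                        threshold = config$threshold)
  write_foldchange_report(
    fc_hi, file.path(config$outdir, "foldchanges_healthy_vs_inflammatory.tsv"))
  say("fold-change records healthy->inflamed (threshold ", config$threshold,
      "): ", nrow(fc_hi))

  # --- treatment scenario ---------------------------------------------------
  treated <- stage("treatment", build_scenario(inflamed, scenario_spec(
    "treatment",
    added_reactions = c(tibolone_reactions(),
                        estradiol_stub_reactions(config$toy)),
    forced_bounds = list(T1 = c(-config$toy$tibolone_cap, 1000)))))
  treated_flux <- canonical_fluxes(treated)
  say("treated biomass: ", fmt_num(treated_flux$objective_value))
  write_flux_report(treated_flux,
                    file.path(config$outdir, "treatment_fluxes.tsv"))

  fc_it <- fold_changes(inflamed_flux, treated_flux,
                        threshold = config$threshold)
  write_foldchange_report(
    fc_it, file.path(config$outdir, "foldchanges_inflammatory_vs_treatment.tsv"))
  say("fold-change records inflamed->treated (threshold ", config$threshold,
      "): ", nrow(fc_it))

  # --- knockout classification ---------------------------------------------
  class_obj <- resolve_reaction_id(
    inflamed,
    if (config$classification_objective %in% names(objective_ids))
      objective_ids[[config$classification_objective]]
    else config$classification_objective)
  kc <- stage("knockouts", classify_knockouts(
    healthy, inflamed, treated, objective_id = class_obj,
    eps = config$eps, fc_threshold = config$threshold))
  counts <- table(kc$label)
  say("knockout classification: ",
      paste(names(counts), counts, sep = "=", collapse = ", "))
  kc_out <- kc
  for (col in c("biomass_before", "biomass_after", "objective_before",
                "objective_after", "relative_change"))
    kc_out[[col]] <- fmt_num(kc_out[[col]])
  utils::write.table(kc_out,
                     file.path(config$outdir, "knockout_classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- subsystem activity ---------------------------------------------------
  sa <- subsystem_activity(healthy_flux, inflamed_flux,
                           model_subsystems(healthy))
  sa_out <- sa
  sa_out$pct_activated <- fmt_num(sa_out$pct_activated)
  sa_out$pct_inactivated <- fmt_num(sa_out$pct_inactivated)
  utils::write.table(sa_out,
                     file.path(config$outdir, "subsystem_activity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    model = if (identical(config$model, "synthetic")) "synthetic" else config$model,
    n_metabolites = nrow(healthy$metabolites),
    n_reactions_healthy = length(healthy$reactions),
    n_reactions_treated = length(treated$reactions),
    biomass = list(healthy = healthy_flux$objective_value,
                   inflamed = inflamed_flux$objective_value,
                   treated = treated_flux$objective_value),
    ic50 = list(mean = ic$mean, sd = ic$sd, values = as.list(ic$values),
                undefined = ic$undefined),
    fold_change_counts = list(healthy_vs_inflammatory = nrow(fc_hi),
                              inflammatory_vs_treatment = nrow(fc_it)),
    knockout_labels = as.list(table(kc$label)),
    parameters = list(grid_n = config$grid_n, u_lo = config$u_lo,
                      u_hi = config$u_hi, threshold = config$threshold,
                      eps = config$eps, seed = config$seed))
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))

  invisible(list(healthy = healthy, inflamed = inflamed, treated = treated,
                 healthy_flux = healthy_flux, inflamed_flux = inflamed_flux,
                 treated_flux = treated_flux, ic50 = ic,
                 fold_changes_healthy_inflamed = fc_hi,
                 fold_changes_inflamed_treated = fc_it,
                 knockouts = kc, subsystems = sa, outdir = config$outdir))
}
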