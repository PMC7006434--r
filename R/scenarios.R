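# The three-scenario experiment: scenario construction, robustness / IC50,
# fold changes with the 2-fold threshold, knockout classification, and
# subsystem-activity summaries.

#' Scenario specification
#'
#' @param name one of \code{"healthy"}, \code{"inflammatory"},
#'   \code{"treatment"}.
#' @param forced_bounds named list of \code{c(lb, ub)} pairs applied after
#'   medium and additions (the inflammatory scenario forces the palmitate
#'   exchange to the mean IC50 uptake here).
#' @param added_reactions list of \code{gf_reaction}s appended to the model
#'   (the treatment scenario adds the tibolone set and the estradiol stub).
#' @param medium optional \code{gf_medium} applied first.
#' @param objectives character vector of objective reaction ids evaluated
#'   for this scenario.
#' @return object of class \code{"gf_scenario_spec"}.
#' @export
scenario_spec <- function(name = c("healthy", "inflammatory", "treatment"),
                          forced_bounds = list(), added_reactions = list(),
                          medium = NULL, objectives = character(0)) {
  name <- match.arg(name)
  if (name == "inflammatory" && length(forced_bounds) == 0)
    stop("inflammatory scenario must force the palmitate exchange bounds")
  if (name == "treatment" && length(added_reactions) == 0)
    stop("treatment scenario must include the tibolone reaction set")
  structure(list(name = name, forced_bounds = forced_bounds,
                 added_reactions = added_reactions, medium = medium,
                 objectives = objectives),
            class = "gf_scenario_spec")
}

#' Build a scenario model from a base model and a specification
#'
#' Healthy: the medium-constrained base (palmitate uptake left free to the
#' optimizer). Inflammatory: healthy with the palmitate exchange fixed at
#' the mean IC50 uptake (lb = ub = -IC50). Treatment: inflammatory plus the
#' tibolone reaction set and the configured estradiol-effect stub.
#'
#' @param base a \code{gf_model}.
#' @param spec a \code{gf_scenario_spec}.
#' @return a \code{gf_model}.
#' @export
build_scenario <- function(base, spec) {
  stopifnot(inherits(spec, "gf_scenario_spec"))
  model <- base
  if (!is.null(spec$medium)) model <- apply_medium(model, spec$medium)
  if (length(spec$added_reactions) > 0)
    model <- append_reactions(model, spec$added_reactions)
  for (id in names(spec$forced_bounds)) {
    b <- spec$forced_bounds[[id]]
    model <- set_bounds(model, id, lb = b[[1]], ub = b[[2]])
  }
  model
}

#' Robustness analysis of an objective against a forced uptake
#'
#' For each of \code{n} grid points u in \code{[u_lo, u_hi]}, the control
#' exchange is fixed at uptake u (lb = ub = -u) and the objective is
#' maximized. Infeasible points are recorded as objective 0 with
#' \code{feasible = FALSE} (biological shutdown).
#'
#' @param model a \code{gf_model}.
#' @param control_id exchange reaction used as control (e.g. the palmitate
#'   exchange).
#' @param objective_id objective reaction id.
#' @param n grid size (default 1000).
#' @param u_lo,u_hi uptake range (default 0 to 1 mmol/gDW/h).
#' @return object of class \code{"gf_robustness"}: list with
#'   \code{control_id}, \code{objective_id} and data.frame \code{grid}
#'   (columns uptake, objective, feasible).
#' @export
robustness_curve <- function(model, control_id, objective_id, n = 1000,
                             u_lo = 0, u_hi = 1) {
  control_id <- resolve_reaction_id(model, control_id)
  if (model$reactions[[control_id]]$kind != "exchange")
    stop("control '", control_id, "' is not an exchange reaction")
  objective_id <- resolve_reaction_id(model, objective_id)
  stopifnot(n >= 2, u_hi > u_lo)
  p <- model_lp_parts(model)
  cvec <- as.numeric(p$rxns == objective_id)
  ci <- match(control_id, p$rxns)
  us <- seq(u_lo, u_hi, length.out = n)
  obj <- numeric(n); feas <- logical(n)
  for (k in seq_len(n)) {
    lb <- p$lb; ub <- p$ub
    lb[ci] <- ub[ci] <- -us[k]
    sol <- lp_solve(p$S, rep(0, nrow(p$S)), cvec, lb, ub, maximize = TRUE)
    feas[k] <- sol$status == "optimal"
    obj[k] <- if (feas[k]) sol$objective else 0
  }
  structure(list(control_id = control_id, objective_id = objective_id,
                 grid = data.frame(uptake = us, objective = obj,
                                   feasible = feas)),
            class = "gf_robustness")
}

#' Half-maximal inhibitory uptake (IC50) of a robustness curve
#'
#' The reference is the maximum objective value on the grid; the IC50 is the
#' smallest uptake at which the objective first falls to half that maximum,
#' linearly interpolated between the bracketing grid points.
#'
#' @param curve a \code{gf_robustness}.
#' @return numeric uptake value.
#' @export
ic50 <- function(curve) {
  stopifnot(inherits(curve, "gf_robustness"))
  g <- curve$grid
  if (sum(g$feasible) < 2)
    stop("robustness curve has fewer than 2 feasible points")
  z_max <- max(g$objective[g$feasible])
  target <- z_max / 2
  below <- which(g$objective <= target + 1e-12)
  if (length(below) == 0)
    stop("undefined IC50: objective never falls to half-maximum for '",
         curve$objective_id, "'")
  i <- below[1]
  if (i == 1) return(g$uptake[1])
  z1 <- g$objective[i - 1]; z2 <- g$objective[i]
  g$uptake[i - 1] + (z1 - target) / (z1 - z2) * (g$uptake[i] - g$uptake[i - 1])
}

#' Mean IC50 over a set of objective functions
#'
#' Runs one robustness curve per objective and averages the per-objective
#' IC50 values; objectives whose curve never reaches half-maximum are
#' excluded and reported.
#'
#' @param model a \code{gf_model}.
#' @param control_id control exchange reaction id.
#' @param objective_ids character vector of objective reaction ids (>= 1).
#' @param n,u_lo,u_hi grid parameters passed to [robustness_curve()].
#' @return list with \code{mean}, \code{sd} (sample standard deviation),
#'   \code{values} (named per-objective IC50s), \code{undefined} (ids
#'   excluded), \code{curves} (the robustness curves).
#' @export
mean_ic50 <- function(model, control_id, objective_ids, n = 1000,
                      u_lo = 0, u_hi = 1) {
  stopifnot(length(objective_ids) >= 1)
  vals <- numeric(0); undef <- character(0)
  curves <- list()
  for (oid in objective_ids) {
    cv <- robustness_curve(model, control_id, oid, n = n,
                           u_lo = u_lo, u_hi = u_hi)
    curves[[oid]] <- cv
    v <- tryCatch(ic50(cv), error = function(e) NA_real_)
    if (is.na(v)) undef <- c(undef, oid) else vals[oid] <- v
  }
  if (length(vals) == 0)
    stop("IC50 undefined for every objective")
  list(mean = mean(vals), sd = if (length(vals) > 1) stats::sd(vals) else 0,
       values = vals, undefined = undef, curves = curves)
}

#' Fold change between two flux values
#'
#' \code{(alt - ref) / |ref|} when the reference flux is nonzero (within
#' 1e-9), otherwise the alternative flux itself (the zero-reference branch
#' of the flux-differences rule).
#'
#' @param ref,alt numeric vectors of reference / alternative fluxes.
#' @return numeric vector of fold changes.
#' @export
fold_change_value <- function(ref, alt) {
  ifelse(abs(ref) > 1e-9, (alt - ref) / abs(ref),
         ifelse(abs(alt) > 1e-9, alt, 0))
}

#' Per-reaction fold changes between two scenarios
#'
#' Both inputs should be canonical (parsimonious) flux distributions over
#' the same reaction universe; the intersection of reaction ids is used.
#' The returned records are filtered to \code{|fold_change| >= threshold}
#' and sorted by decreasing magnitude; the unfiltered list is attached as
#' attribute \code{"all"}.
#'
#' @param fluxes_ref,fluxes_alt \code{gf_flux} objects (or named vectors).
#' @param threshold reporting threshold (default 2-fold).
#' @return data.frame with columns \code{reaction_id}, \code{flux_ref},
#'   \code{flux_alt}, \code{fold_change}.
#' @export
fold_changes <- function(fluxes_ref, fluxes_alt, threshold = 2) {
  vr <- if (inherits(fluxes_ref, "gf_flux")) fluxes_ref$fluxes else fluxes_ref
  va <- if (inherits(fluxes_alt, "gf_flux")) fluxes_alt$fluxes else fluxes_alt
  ids <- sort(intersect(names(vr), names(va)))
  fc <- fold_change_value(unname(vr[ids]), unname(va[ids]))
  all_rec <- data.frame(reaction_id = ids, flux_ref = unname(vr[ids]),
                        flux_alt = unname(va[ids]), fold_change = fc,
                        stringsAsFactors = FALSE)
  keep <- all_rec[abs(all_rec$fold_change) >= threshold, , drop = FALSE]
  keep <- keep[order(-abs(keep$fold_change), keep$reaction_id), , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "all") <- all_rec
  keep
}

#' Knockout-based classification of reactions
#'
#' Every candidate reaction of the inflamed model (except the two objective
#' constructs themselves) is knocked out and re-evaluated under the
#' lexicographic objective (biomass first, then \code{objective_id}):
#' \itemize{
#'   \item \emph{pro_inflammatory}: the stage-2 objective value increases
#'     (a knockout can free the shared resource pool for the objective);
#'   \item \emph{anti_inflammatory}: the reaction changed at least
#'     \code{fc_threshold}-fold between the healthy and inflamed scenarios
#'     and its knockout decreases the lexicographic objective;
#'   \item \emph{treatment_essential}: for reactions of the
#'     tibolone/estradiol set, knocking them out in the treated model
#'     returns the lexicographic objective tuple to the inflamed tuple
#'     within \code{eps} (the treatment effect is abolished);
#'   \item \emph{neutral}: none of the above.
#' }
#' Infeasible knockout models are scored as objective 0 and classified by
#' the same rules.
#'
#' @param healthy,inflamed,treated \code{gf_model}s sharing a reaction
#'   universe (the treated model adds the tibolone/estradiol reactions).
#' @param objective_id the stage-2 objective reaction id.
#' @param eps relative tolerance for "increase"/"decrease"/"abolished".
#' @param fc_threshold fold-change gate for the anti-inflammatory rule.
#' @param treatment_set candidate ids for the treatment-essential rule;
#'   default: reactions present in \code{treated} but not \code{inflamed}.
#' @return data.frame with columns \code{reaction_id}, \code{label},
#'   \code{biomass_before}, \code{biomass_after}, \code{objective_before},
#'   \code{objective_after}, \code{relative_change}.
#' @export
classify_knockouts <- function(healthy, inflamed, treated,
                               objective_id, eps = 1e-6, fc_threshold = 2,
                               treatment_set = NULL) {
  biomass_id <- inflamed$objective_id
  objective_id <- resolve_reaction_id(inflamed, objective_id)
  objs <- c(biomass_id, objective_id)

  lex_tuple <- function(model, ids = objs) {
    sol <- solve_lexicographic(model, ids)
    if (sol$status != "optimal") return(c(0, 0))
    unname(sol$stage_values)
  }
  base_inf <- lex_tuple(inflamed)
  base_tre <- lex_tuple(treated)
  tolv <- function(x) eps * pmax(1, abs(x))

  fc_all <- attr(fold_changes(canonical_fluxes(healthy, biomass_id),
                              canonical_fluxes(inflamed, biomass_id),
                              threshold = fc_threshold), "all")
  fc_by_id <- stats::setNames(fc_all$fold_change, fc_all$reaction_id)

  if (is.null(treatment_set))
    treatment_set <- setdiff(reaction_ids(treated), reaction_ids(inflamed))
  treatment_effect <- any(abs(base_tre - base_inf) > tolv(base_inf))

  rows <- list()
  candidates <- setdiff(reaction_ids(inflamed), objs)
  for (r in candidates) {
    after <- lex_tuple(knockout(inflamed, r))
    label <- "neutral"
    if (after[2] > base_inf[2] + tolv(base_inf[2])) {
      label <- "pro_inflammatory"
    } else {
      fc <- if (r %in% names(fc_by_id)) fc_by_id[[r]] else 0
      decreased <- after[1] < base_inf[1] - tolv(base_inf[1]) ||
        (abs(after[1] - base_inf[1]) <= tolv(base_inf[1]) &&
           after[2] < base_inf[2] - tolv(base_inf[2]))
      if (abs(fc) >= fc_threshold && decreased) label <- "anti_inflammatory"
    }
    rows[[r]] <- data.frame(
      reaction_id = r, label = label,
      biomass_before = base_inf[1], biomass_after = after[1],
      objective_before = base_inf[2], objective_after = after[2],
      stringsAsFactors = FALSE)
  }
  for (r in intersect(treatment_set, reaction_ids(treated))) {
    after <- lex_tuple(knockout(treated, r))
    abolished <- treatment_effect &&
      all(abs(after - base_inf) <= tolv(base_inf))
    rows[[r]] <- data.frame(
      reaction_id = r,
      label = if (abolished) "treatment_essential" else "neutral",
      biomass_before = base_tre[1], biomass_after = after[1],
      objective_before = base_tre[2], objective_after = after[2],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[sort(names(rows))])
  denom <- ifelse(abs(out$objective_before) > eps, abs(out$objective_before), 1)
  out$relative_change <- (out$objective_after - out$objective_before) / denom
  rownames(out) <- NULL
  out
}

#' Subsystem activation/inactivation summary between two scenarios
#'
#' Per subsystem: the percentage of member reactions that are newly active
#' in the alternative scenario (|flux| <= tol in the reference, > tol in the
#' alternative) and, symmetrically, newly inactive. Reactions without a
#' subsystem tag are grouped under \code{"unassigned"}.
#'
#' @param fluxes_ref,fluxes_alt \code{gf_flux} objects or named vectors.
#' @param subsystems named character vector reaction id -> subsystem tag
#'   (see [model_subsystems()]).
#' @param tol activity threshold on |flux| (default 1e-6).
#' @return data.frame with columns \code{subsystem}, \code{n_reactions},
#'   \code{pct_activated}, \code{pct_inactivated}.
#' @export
subsystem_activity <- function(fluxes_ref, fluxes_alt, subsystems,
                               tol = 1e-6) {
  vr <- if (inherits(fluxes_ref, "gf_flux")) fluxes_ref$fluxes else fluxes_ref
  va <- if (inherits(fluxes_alt, "gf_flux")) fluxes_alt$fluxes else fluxes_alt
  ids <- intersect(names(vr), names(va))
  tags <- subsystems[ids]
  tags[is.na(tags)] <- "unassigned"
  act <- abs(vr[ids]) <= tol & abs(va[ids]) > tol
  inact <- abs(vr[ids]) > tol & abs(va[ids]) <= tol
  agg <- function(x) tapply(x, tags, function(z) 100 * mean(z))
  out <- data.frame(subsystem = sort(unique(tags)), stringsAsFactors = FALSE)
  out$n_reactions <- as.integer(table(tags)[out$subsystem])
  out$pct_activated <- as.numeric(agg(act)[out$subsystem])
  out$pct_inactivated <- as.numeric(agg(inact)[out$subsystem])
  rownames(out) <- NULL
  out
}

#' Subsystem tags of a model
#' @param model a \code{gf_model}.
#' @return named character vector reaction id -> subsystem (NA when untagged).
#' @export
model_subsystems <- function(model) {
  vapply(model$reactions, function(r) r$subsystem, character(1))
}
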