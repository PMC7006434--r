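# Tissue-specific constraining: GPR expression evaluation, expression-
# proportional bounds, additionCost gap filling, medium application.

#' Evaluate a GPR rule against an expression profile
#'
#' Leaves take the gene's expression value (0 when the gene is missing from
#' the profile — an absent transcript implies no capacity). AND nodes take
#' the minimum of their children (an enzyme complex is limited by its
#' scarcest subunit); OR nodes take the sum (isoenzymes add capacity). An
#' empty GPR returns \code{NA}, the "no gene association" sentinel.
#'
#' @param gpr a GPR tree from [parse_gpr()] (or a rule string, or
#'   \code{NULL}).
#' @param profile named numeric vector of mean expression values.
#' @return numeric score, or \code{NA} for no association.
#' @examples
#' evaluate_gpr("GLUL", c(GLUL = 7)) # 7
#' evaluate_gpr("A and B", c(A = 3, B = 5)) # 3
#' evaluate_gpr("A or B", c(A = 3, B = 5)) # 8
#' @export
evaluate_gpr <- function(gpr, profile) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) return(NA_real_)
  rec <- function(node) {
    if (node$type == "leaf") {
      if (node$gene %in% names(profile)) return(unname(profile[[node$gene]]))
      return(0)
    }
    vals <- vapply(node$children, rec, numeric(1))
    if (node$type == "and") min(vals) else sum(vals)
  }
  rec(gpr)
}

#' Constrain reaction bounds proportionally to gene expression
#'
#' For each reaction with a GPR score s, the upper bound becomes
#' \code{bound_cap * s / s_max} (s_max: the maximum score over the model) and
#' the lower bound becomes the negative of that for reversible reactions, 0
#' otherwise. Reactions without gene association keep their prior bounds;
#' exchange reactions are never touched. The scaling is invariant to uniform
#' rescaling of the profile.
#'
#' @param model a \code{gf_model}.
#' @param profile named numeric expression vector (nonempty).
#' @param bound_cap flux bound given to the highest-scoring reaction
#'   (default 1000 mmol/gDW/h).
#' @return modified copy of the model.
#' @export
apply_expression_bounds <- function(model, profile, bound_cap = 1000) {
  stopifnot(length(profile) > 0)
  scores <- vapply(model$reactions, function(r) evaluate_gpr(r$gpr, profile),
                   numeric(1))
  scorable <- !is.na(scores) &
    vapply(model$reactions, function(r) r$kind != "exchange", logical(1))
  if (!any(scorable)) return(model)
  s_max <- max(scores[scorable])
  if (s_max <= 0)
    stop("degenerate expression profile: all GPR scores are zero")
  for (id in reaction_ids(model)[scorable]) {
    s <- scores[[id]]
    ub <- bound_cap * s / s_max
    model$reactions[[id]]$ub <- ub
    model$reactions[[id]]$lb <- if (model$reactions[[id]]$reversible) -ub else 0
  }
  model
}

#' Addition cost of a candidate reaction
#'
#' The fraction of the candidate's metabolites that are absent from the
#' model, in \code{[0, 1]}. Used to rank gap-filling candidates: cheap
#' reactions reuse the model's existing metabolite pool.
#'
#' @param candidate a \code{gf_reaction} with at least one metabolite.
#' @param model a \code{gf_model}.
#' @return numeric in \code{[0, 1]}.
#' @export
addition_cost <- function(candidate, model) {
  mets <- names(candidate$stoichiometry)
  stopifnot(length(mets) >= 1)
  mean(!(mets %in% metabolite_ids(model)))
}

#' Fill gaps from a reference reaction set
#'
#' Iteratively re-enables reactions from a reference pool (reactions with no
#' correlated gene expression, in the tissue-model workflow) until the
#' objective becomes feasible: each round, if the objective optimum exceeds
#' 1e-9 the search stops; otherwise every not-yet-added reference reaction
#' with [addition_cost()] at or below the threshold is added (costs are
#' re-evaluated every round as added reactions contribute metabolites).
#'
#' @param model a \code{gf_model}.
#' @param reference list of candidate \code{gf_reaction}s, disjoint from the
#'   model's reaction ids.
#' @param objective_id objective whose feasibility drives the search.
#' @param cost_threshold maximum addition cost per round (default 0.25).
#' @param max_rounds round cap (default 100).
#' @return object of class \code{"gf_gapfill"}: list with \code{model} (the
#'   augmented model), \code{added} (ids in addition order), \code{costs}
#'   (cost at time of addition), \code{feasible} (logical).
#' @export
gap_fill <- function(model, reference, objective_id = model$objective_id,
                     cost_threshold = 0.25, max_rounds = 100L) {
  ref_ids <- vapply(reference, function(r) r$id, character(1))
  if (any(ref_ids %in% reaction_ids(model)))
    stop("reference set overlaps model reactions: ",
         paste(intersect(ref_ids, reaction_ids(model)), collapse = ", "))
  names(reference) <- ref_ids
  added <- character(0); costs <- numeric(0)
  feasible <- FALSE
  for (round in seq_len(max_rounds)) {
    sol <- solve_fba(model, objective_id)
    if (sol$status == "optimal" && sol$objective_value > 1e-9) {
      feasible <- TRUE
      break
    }
    pool <- setdiff(ref_ids, added)
    if (length(pool) == 0) break
    cc <- vapply(reference[pool], addition_cost, numeric(1), model = model)
    take <- pool[cc <= cost_threshold]
    if (length(take) == 0) break
    new_mets <- setdiff(unlist(lapply(reference[take],
                                      function(r) names(r$stoichiometry))),
                        metabolite_ids(model))
    mets <- model$metabolites
    for (m in new_mets) mets <- rbind(mets, metabolite(m))
    model <- metabolic_model(mets, c(model$reactions, reference[take]),
                             objective_id = model$objective_id)
    added <- c(added, take)
    costs <- c(costs, unname(cc[take]))
  }
  if (!feasible) {   # final re-check (pool may have emptied on the last add)
    sol <- solve_fba(model, objective_id)
    feasible <- sol$status == "optimal" && sol$objective_value > 1e-9
  }
  structure(list(model = model, added = added, costs = costs,
                 feasible = feasible), class = "gf_gapfill")
}

#' Apply a medium definition to a model
#'
#' Uptake uses the standard COBRA sign convention: a negative flux on an
#' exchange reaction imports the metabolite, so medium caps become lower
#' bounds. Listed inputs get \code{lower_bound = -max_uptake}; exchange
#' reactions not listed as inputs get \code{lower_bound = 0}; allowed
#' outputs keep a positive upper bound; exchanges that are neither input nor
#' output are closed to \code{(0, 0)}.
#'
#' @param model a \code{gf_model}.
#' @param medium a \code{gf_medium} from [medium()] or [read_medium()].
#' @return modified copy of the model.
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(medium, "gf_medium"))
  resolve_ex <- function(id) {
    rid <- resolve_reaction_id(model, id)
    if (model$reactions[[rid]]$kind != "exchange")
      stop("medium id '", id, "' resolves to non-exchange reaction '", rid, "'")
    rid
  }
  inputs <- stats::setNames(unname(medium$uptake),
                            vapply(names(medium$uptake), resolve_ex, character(1)))
  outputs <- vapply(medium$outputs, resolve_ex, character(1))
  for (id in reaction_ids(model)) {
    if (model$reactions[[id]]$kind != "exchange") next
    is_in <- id %in% names(inputs)
    is_out <- id %in% outputs
    model$reactions[[id]]$lb <- if (is_in) -inputs[[id]] else 0
    if (is_out) {
      if (model$reactions[[id]]$ub <= 0) model$reactions[[id]]$ub <- 1000
    } else if (!is_in) {
      model$reactions[[id]]$ub <- 0
    }
  }
  model
}
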