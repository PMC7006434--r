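# Linear-programming layer: FBA, lexicographic FBA, parsimonious
# canonicalization, flux variability, blocked reactions, knockouts.

model_lp_parts <- function(model) {
  S <- as.matrix(build_stoichiometric_matrix(model))
  lb <- vapply(model$reactions, function(r) r$lb, numeric(1))
  ub <- vapply(model$reactions, function(r) r$ub, numeric(1))
  list(S = S, lb = lb, ub = ub, rxns = reaction_ids(model))
}

new_flux <- function(status, objective_value, fluxes, objective_id,
                     stage_values = NULL) {
  structure(list(status = status, objective_value = objective_value,
                 fluxes = fluxes, objective_id = objective_id,
                 stage_values = stage_values),
            class = "gf_flux")
}

#' @export
print.gf_flux <- function(x, ...) {
  cat("gf_flux:", x$status, " objective(", x$objective_id, ") =",
      format(x$objective_value, digits = 8), "\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Solves \code{max / min c'v} subject to \code{S v = 0} and
#' \code{lb <= v <= ub}, where \code{c} selects the objective reaction.
#' Infeasibility and unboundedness are reported faithfully via the
#' \code{status} field, never as a silent zero.
#'
#' @param model a \code{gf_model}.
#' @param objective_id objective reaction id; defaults to the model's.
#' @param direction \code{"max"} (default) or \code{"min"}.
#' @return a \code{gf_flux}: list with \code{status}, \code{objective_value},
#'   \code{fluxes} (named vector v of length n), \code{objective_id}.
#' @export
solve_fba <- function(model, objective_id = model$objective_id,
                      direction = c("max", "min")) {
  direction <- match.arg(direction)
  if (is.null(objective_id)) stop("no objective_id given and model has none")
  objective_id <- resolve_reaction_id(model, objective_id)
  p <- model_lp_parts(model)
  cvec <- as.numeric(p$rxns == objective_id)
  sol <- lp_solve(p$S, rep(0, nrow(p$S)), cvec, p$lb, p$ub,
                  maximize = direction == "max")
  fl <- if (sol$status == "optimal") stats::setNames(sol$x, p$rxns)
        else stats::setNames(rep(NA_real_, length(p$rxns)), p$rxns)
  new_flux(sol$status, sol$objective, fl, objective_id)
}

#' Lexicographic (staged) flux balance analysis
#'
#' Stage k maximizes objective k subject to all previous stage optima being
#' held within a relative tolerance (default 1e-6). Used for knockout
#' screening with biomass as the first objective: in a single LP a knockout
#' can never increase the optimum, while the second-stage value can rise when
#' the first-stage optimum falls.
#'
#' @param model a \code{gf_model}.
#' @param objectives ordered character vector of reaction ids (>= 1).
#' @param tolerances per-stage relative slack on fixed optima (recycled).
#' @return a \code{gf_flux} whose \code{stage_values} holds each stage's
#'   optimum; \code{objective_value} is the last stage's. On infeasibility
#'   the failing stage index is attached as attribute \code{"stage"}.
#' @export
solve_lexicographic <- function(model, objectives, tolerances = 1e-6) {
  stopifnot(length(objectives) >= 1)
  objectives <- vapply(objectives, function(o) resolve_reaction_id(model, o),
                       character(1))
  tolerances <- rep_len(tolerances, length(objectives))
  p <- model_lp_parts(model)
  n <- length(p$rxns)
  A <- p$S; b <- rep(0, nrow(A))
  lb <- p$lb; ub <- p$ub
  stage_values <- numeric(0)
  sol <- NULL
  for (k in seq_along(objectives)) {
    cvec <- c(as.numeric(p$rxns == objectives[k]), rep(0, length(lb) - n))
    sol <- lp_solve(A, b, cvec, lb, ub, maximize = TRUE)
    if (sol$status != "optimal") {
      fl <- stats::setNames(rep(NA_real_, n), p$rxns)
      out <- new_flux(sol$status, NA_real_, fl, objectives[k], stage_values)
      attr(out, "stage") <- k
      return(out)
    }
    zk <- sol$objective
    stage_values <- c(stage_values, zk)
    if (k < length(objectives)) {
      # fix stage-k optimum: c_k' v - s_k = z_k - delta, slack s_k >= 0
      delta <- tolerances[k] * max(1, abs(zk))
      A <- rbind(cbind(A, 0), c(cvec, rep(0, ncol(A) - length(cvec)), -1))
      b <- c(b, zk - delta)
      lb <- c(lb, 0); ub <- c(ub, Inf)
    }
  }
  names(stage_values) <- objectives
  fl <- stats::setNames(sol$x[seq_len(n)], p$rxns)
  new_flux("optimal", unname(stage_values[length(stage_values)]), fl,
           objectives[length(objectives)], stage_values)
}

#' Canonical (parsimonious) flux distribution
#'
#' Among the optima of the objective, minimizes the total absolute flux
#' (pFBA). Alternate optima make raw FBA vectors arbitrary; the parsimonious
#' solution computed with a fixed variable order and deterministic pivoting
#' is reproducible across runs and is the vector used for all cross-scenario
#' flux comparisons.
#'
#' @param model a \code{gf_model}.
#' @param objective_id objective reaction id; defaults to the model's.
#' @return a \code{gf_flux}; \code{objective_value} is the stage-1 optimum.
#' @export
canonical_fluxes <- function(model, objective_id = model$objective_id) {
  objective_id <- resolve_reaction_id(model, objective_id)
  p <- model_lp_parts(model)
  n <- length(p$rxns)
  cvec <- as.numeric(p$rxns == objective_id)
  s1 <- lp_solve(p$S, rep(0, nrow(p$S)), cvec, p$lb, p$ub, maximize = TRUE)
  if (s1$status != "optimal")
    return(new_flux(s1$status, s1$objective,
                    stats::setNames(rep(NA_real_, n), p$rxns), objective_id))
  z <- s1$objective
  delta <- 1e-9 * max(1, abs(z))
  # split v = vp - vn, vp, vn >= 0; minimize sum(vp + vn)
  # subject to S(vp - vn) = 0 and c'(vp - vn) - s = z - delta
  A2 <- rbind(cbind(p$S, -p$S, 0), c(cvec, -cvec, -1))
  b2 <- c(rep(0, nrow(p$S)), z - delta)
  lb2 <- c(pmax(p$lb, 0), pmax(-p$ub, 0), 0)
  ub2 <- c(pmax(p$ub, 0), pmax(-p$lb, 0), Inf)
  c2 <- c(rep(1, 2 * n), 0)
  s2 <- lp_solve(A2, b2, c2, lb2, ub2, maximize = FALSE)
  if (s2$status != "optimal")
    stop("parsimonious stage failed with status ", s2$status)
  v <- s2$x[seq_len(n)] - s2$x[n + seq_len(n)]
  new_flux("optimal", z, stats::setNames(v, p$rxns), objective_id)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the objective retaining
#' at least \code{fraction} of its optimum. With \code{fraction <= 0} the
#' objective constraint is dropped and the raw flux polytope is scanned.
#'
#' @param model a \code{gf_model}.
#' @param objective_id objective reaction id; defaults to the model's.
#' @param fraction fraction of the optimal objective to retain (default 1).
#' @param reactions reaction ids to scan (default: all).
#' @return data.frame with columns \code{reaction_id}, \code{vmin},
#'   \code{vmax}.
#' @export
flux_variability <- function(model, objective_id = model$objective_id,
                             fraction = 1.0, reactions = reaction_ids(model)) {
  p <- model_lp_parts(model)
  n <- length(p$rxns)
  A <- p$S; b <- rep(0, nrow(A)); lb <- p$lb; ub <- p$ub
  if (fraction > 0) {
    objective_id <- resolve_reaction_id(model, objective_id)
    cvec <- as.numeric(p$rxns == objective_id)
    s1 <- lp_solve(A, b, cvec, lb, ub, maximize = TRUE)
    if (s1$status != "optimal")
      stop("model is ", s1$status, "; flux variability undefined")
    # c'v - s = fraction * z, slack s >= 0 enforces c'v >= fraction * z
    A <- rbind(cbind(A, 0), c(cvec, -1))
    b <- c(b, fraction * s1$objective)
    lb <- c(lb, 0); ub <- c(ub, Inf)
  }
  reactions <- vapply(reactions, function(r) resolve_reaction_id(model, r),
                      character(1))
  idx <- match(reactions, p$rxns)
  vmin <- vmax <- numeric(length(idx))
  for (k in seq_along(idx)) {
    cvec <- rep(0, ncol(A)); cvec[idx[k]] <- 1
    lo <- lp_solve(A, b, cvec, lb, ub, maximize = FALSE)
    hi <- lp_solve(A, b, cvec, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("flux variability LP failed for ", reactions[k])
    vmin[k] <- lo$objective; vmax[k] <- hi$objective
  }
  data.frame(reaction_id = unname(reactions), vmin = vmin, vmax = vmax,
             stringsAsFactors = FALSE)
}

#' Find blocked reactions
#'
#' A reaction is blocked when it can carry no flux under any feasible steady
#' state with every exchange reaction fully opened (bounds set to
#' \code{(-1000, 1000)}): both its minimum and maximum flux magnitudes fall
#' below 1e-9.
#'
#' @param model a \code{gf_model}.
#' @return character vector of blocked reaction ids (possibly empty).
#' @export
find_blocked_reactions <- function(model) {
  open <- model
  for (id in reaction_ids(open)) {
    if (open$reactions[[id]]$kind == "exchange") {
      open$reactions[[id]]$lb <- -1000
      open$reactions[[id]]$ub <- 1000
    }
  }
  fva <- flux_variability(open, fraction = 0)
  fva$reaction_id[abs(fva$vmin) <= 1e-9 & abs(fva$vmax) <= 1e-9]
}

#' Remove blocked reactions from a model
#'
#' Convenience pruning step used by the pipeline after gap filling.
#'
#' @param model a \code{gf_model}.
#' @return model without the reactions flagged by [find_blocked_reactions()].
#' @export
prune_blocked_reactions <- function(model) {
  blocked <- find_blocked_reactions(model)
  if (length(blocked) == 0) return(model)
  keep <- setdiff(reaction_ids(model), blocked)
  metabolic_model(model$metabolites, model$reactions[keep],
                  objective_id = model$objective_id)
}

#' Knock out a reaction
#'
#' Returns a copy of the model with the reaction's bounds fixed to
#' \code{(0, 0)}; the original model is untouched.
#'
#' @param model a \code{gf_model}.
#' @param reaction_id reaction to disable.
#' @return modified copy of the model.
#' @export
knockout <- function(model, reaction_id) {
  reaction_id <- resolve_reaction_id(model, reaction_id)
  model$reactions[[reaction_id]]$lb <- 0
  model$reactions[[reaction_id]]$ub <- 0
  model
}
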