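# Domain types for compartmentalized metabolic networks.
#
# A model is an ordered collection of metabolites and reactions plus an
# objective reaction id; the stoichiometric matrix S (m x n, metabolites x
# reactions) is assembled on demand from the per-reaction stoichiometry maps.

GF_COMPARTMENTS <- c("c", "m", "e", "g", "r", "l", "n", "x")

#' Parse a metabolite identifier into base and compartment
#'
#' Accepts both the bracket dialect \code{"glu_L[e]"} and the suffix dialect
#' \code{"glu_L_e"}; identifiers are normalized to bracket form internally.
#'
#' @param id character vector of metabolite ids.
#' @return data.frame with columns \code{id} (normalized), \code{base},
#'   \code{compartment}.
#' @examples
#' parse_met_id(c("glu_L[e]", "glu_L_e"))
#' @export
parse_met_id <- function(id) {
  stopifnot(is.character(id))
  base <- character(length(id)); comp <- character(length(id))
  bracket <- grepl("^(.+)\\[([a-z])\\]$", id)
  base[bracket] <- sub("^(.+)\\[([a-z])\\]$", "\\1", id[bracket])
  comp[bracket] <- sub("^(.+)\\[([a-z])\\]$", "\\2", id[bracket])
  suffix <- !bracket & grepl("^(.+)_([a-z])$", id)
  # only treat the trailing token as a compartment if it is a known code
  sufcomp <- sub("^(.+)_([a-z])$", "\\2", id[suffix])
  keep <- sufcomp %in% GF_COMPARTMENTS
  idx <- which(suffix)[keep]
  base[idx] <- sub("^(.+)_([a-z])$", "\\1", id[idx])
  comp[idx] <- sub("^(.+)_([a-z])$", "\\2", id[idx])
  bad <- base == "" | !(comp %in% GF_COMPARTMENTS)
  if (any(bad))
    stop("cannot parse metabolite id(s): ", paste(id[bad], collapse = ", "),
         " (expected 'base[compartment]' with compartment in {",
         paste(GF_COMPARTMENTS, collapse = ","), "})")
  data.frame(id = paste0(base, "[", comp, "]"), base = base,
             compartment = comp, stringsAsFactors = FALSE)
}

#' Create a metabolite
#'
#' @param id metabolite id in \code{"base[compartment]"} or
#'   \code{"base_compartment"} form.
#' @param name human-readable name.
#' @param formula optional elemental formula (e.g. \code{"C6H12O6"});
#'   \code{NA} means unannotated and exempts the metabolite from mass balance
#'   checking.
#' @param charge optional integer charge.
#' @return a one-row data.frame usable with [metabolic_model()].
#' @export
metabolite <- function(id, name = id, formula = NA_character_,
                       charge = NA_integer_) {
  p <- parse_met_id(id)
  data.frame(id = p$id, name = name, compartment = p$compartment,
             formula = as.character(formula), charge = as.integer(charge),
             stringsAsFactors = FALSE)
}

#' Create a reaction
#'
#' Stoichiometry follows the usual convention: negative coefficients are
#' consumed, positive produced. Reversibility and bounds are linked: a
#' reversible reaction defaults to bounds \code{(-1000, 1000)}, an
#' irreversible one to \code{(0, 1000)} (fluxes in mmol/gDW/h).
#'
#' @param id reaction id.
#' @param stoichiometry named numeric vector, metabolite id -> coefficient;
#'   all coefficients must be nonzero.
#' @param reversible logical.
#' @param lb,ub flux bounds; defaults derived from \code{reversible}.
#' @param name,subsystem optional annotation.
#' @param gpr gene-protein-reaction rule: a string such as
#'   \code{"(A and B) or C"}, a tree from [parse_gpr()], or \code{NULL}.
#' @param kind one of \code{"exchange"}, \code{"transport"},
#'   \code{"intracellular"}, \code{"pseudo"}, or \code{NA} to classify
#'   structurally when the model is assembled.
#' @return an object of class \code{"gf_reaction"}.
#' @export
reaction <- function(id, stoichiometry, reversible = FALSE,
                     lb = if (reversible) -1000 else 0, ub = 1000,
                     name = id, gpr = NULL, subsystem = NA_character_,
                     kind = NA_character_) {
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  if (any(stoichiometry == 0))
    stop("reaction '", id, "': zero stoichiometric coefficient for ",
         paste(names(stoichiometry)[stoichiometry == 0], collapse = ", "))
  if (anyDuplicated(names(stoichiometry)))
    stop("reaction '", id, "': duplicate metabolite in stoichiometry")
  if (lb > ub) stop("reaction '", id, "': lower_bound > upper_bound")
  if (!reversible && lb < 0)
    stop("reaction '", id, "': irreversible reaction with negative lower bound")
  nm <- parse_met_id(names(stoichiometry))$id
  names(stoichiometry) <- nm
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  structure(list(id = id, name = name, stoichiometry = stoichiometry,
                 reversible = isTRUE(reversible), lb = lb, ub = ub,
                 gpr = gpr, subsystem = subsystem, kind = kind),
            class = "gf_reaction")
}

#' Assemble a metabolic model
#'
#' @param metabolites data.frame as produced by row-binding [metabolite()]
#'   calls (columns id, name, compartment, formula, charge).
#' @param reactions list of [reaction()] objects.
#' @param objective_id id of the objective reaction (must exist).
#' @return an object of class \code{"gf_model"}.
#' @export
metabolic_model <- function(metabolites, reactions, objective_id = NULL) {
  stopifnot(is.data.frame(metabolites), is.list(reactions))
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  rids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  names(reactions) <- rids
  for (r in reactions) {
    missing <- setdiff(names(r$stoichiometry), metabolites$id)
    if (length(missing) > 0)
      stop("reaction '", r$id, "' references undeclared metabolite(s): ",
           paste(missing, collapse = ", "))
  }
  if (!is.null(objective_id) && !(objective_id %in% rids))
    stop("objective_id '", objective_id, "' is not a reaction in the model")
  model <- structure(list(metabolites = metabolites, reactions = reactions,
                          objective_id = objective_id),
                     class = "gf_model")
  # classify reactions lacking an explicit kind
  for (i in seq_along(model$reactions)) {
    if (is.na(model$reactions[[i]]$kind))
      model$reactions[[i]]$kind <- classify_reaction(model$reactions[[i]], model)
  }
  model
}

#' @export
print.gf_model <- function(x, ...) {
  kinds <- table(vapply(x$reactions, function(r) r$kind, character(1)))
  cat("gf_model:", nrow(x$metabolites), "metabolites,",
      length(x$reactions), "reactions\n")
  cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$objective_id)) cat("  objective:", x$objective_id, "\n")
  invisible(x)
}

#' Reaction and metabolite ids of a model
#' @param model a \code{gf_model}.
#' @return character vector.
#' @export
reaction_ids <- function(model) names(model$reactions)

#' @rdname reaction_ids
#' @export
metabolite_ids <- function(model) model$metabolites$id

#' Build the stoichiometric matrix S
#'
#' Returns the sparse m x n matrix whose column j holds reaction j's
#' stoichiometry over the model's metabolites (m metabolites, n reactions).
#' All-zero rows are permitted for declared-but-unused metabolites.
#'
#' @param model a \code{gf_model}.
#' @return a \code{dgCMatrix} with dimnames (metabolite ids, reaction ids).
#' @export
build_stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- reaction_ids(model)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(model$reactions)) {
    s <- model$reactions[[j]]$stoichiometry
    rows <- match(names(s), mets)
    if (anyNA(rows))
      stop("reaction '", rxns[j], "' references undeclared metabolite(s): ",
           paste(names(s)[is.na(rows)], collapse = ", "))
    ii <- c(ii, rows); jj <- c(jj, rep(j, length(s))); xx <- c(xx, unname(s))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), length(rxns)),
                       dimnames = list(mets, rxns))
}

#' Classify a reaction by structure
#'
#' Exchange: exactly one metabolite (boundary reaction). Transport: at least
#' two compartments and some base metabolite present in more than one
#' compartment. Otherwise intracellular. The \code{"pseudo"} kind is reserved
#' for objective constructs (biomass, demands) and is only assigned
#' explicitly, never inferred.
#'
#' @param rxn a \code{gf_reaction}.
#' @param model the owning \code{gf_model} (used only for error context).
#' @return one of \code{"exchange"}, \code{"transport"},
#'   \code{"intracellular"}.
#' @export
classify_reaction <- function(rxn, model = NULL) {
  s <- rxn$stoichiometry
  if (length(s) == 0) stop("reaction '", rxn$id, "' has empty stoichiometry")
  if (length(s) == 1) return("exchange")
  p <- parse_met_id(names(s))
  if (length(unique(p$compartment)) >= 2 &&
      anyDuplicated(p$base) > 0) return("transport")
  "intracellular"
}

# parse "C6H12O6" -> named count vector; returns NULL on empty/unparsable
parse_formula <- function(f) {
  if (is.na(f) || !nzchar(f)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f)[[1]]
  toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f))[[1]]
  if (length(toks) == 0 || sum(nchar(toks)) != nchar(f)) return(NULL)
  el <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
  ct <- sub("^[A-Z][a-z]?", "", toks)
  ct <- ifelse(ct == "", 1, as.numeric(ct))
  tapply(ct, el, sum)
}

#' Validate a model (syntax, mass-charge balance, orphan metabolites)
#'
#' Produces a minval-style validation report with three sections: (a) syntax
#' findings (unparsable metabolite ids, bound inversions), (b) elemental /
#' charge imbalances for reactions whose participants all carry formulas
#' (exchange and pseudo reactions are exempt; metabolites without formulas
#' cause the reaction to be skipped, not failed), and (c) orphan metabolites,
#' i.e. metabolites that are produced-only or consumed-only across all
#' non-exchange reactions (a reversible reaction counts as both producer and
#' consumer of every participant).
#'
#' @param model a \code{gf_model}.
#' @return an object of class \code{"gf_validation"}: list with data.frames
#'   \code{syntax}, \code{balance}, \code{orphans} and logical \code{valid}
#'   (TRUE when all three are empty).
#' @export
validate_model <- function(model) {
  syntax <- data.frame(item = character(0), problem = character(0))
  for (r in model$reactions) {
    if (r$lb > r$ub)
      syntax <- rbind(syntax, data.frame(item = r$id, problem = "lower_bound > upper_bound"))
    ok <- tryCatch({ parse_met_id(names(r$stoichiometry)); TRUE },
                   error = function(e) FALSE)
    if (!ok)
      syntax <- rbind(syntax, data.frame(item = r$id, problem = "unparsable metabolite id"))
  }

  balance <- data.frame(reaction = character(0), element = character(0),
                        imbalance = numeric(0))
  formulas <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  charges <- stats::setNames(model$metabolites$charge, model$metabolites$id)
  for (r in model$reactions) {
    if (r$kind %in% c("exchange", "pseudo")) next
    fl <- formulas[names(r$stoichiometry)]
    if (any(is.na(fl)) || any(!nzchar(fl))) next    # incompletely annotated
    counts <- list()
    for (k in seq_along(r$stoichiometry)) {
      el <- parse_formula(fl[k])
      if (is.null(el)) { counts <- NULL; break }
      counts[[k]] <- el * r$stoichiometry[k]
    }
    if (is.null(counts)) next
    all_el <- unique(unlist(lapply(counts, names)))
    net <- vapply(all_el, function(e)
      sum(vapply(counts, function(ct) if (e %in% names(ct)) ct[[e]] else 0,
                 numeric(1))), numeric(1))
    off <- abs(net) > 1e-6
    if (any(off))
      balance <- rbind(balance, data.frame(reaction = r$id,
                                           element = all_el[off],
                                           imbalance = unname(net[off])))
    ch <- charges[names(r$stoichiometry)]
    if (!any(is.na(ch))) {
      q <- sum(ch * r$stoichiometry)
      if (abs(q) > 1e-6)
        balance <- rbind(balance, data.frame(reaction = r$id,
                                             element = "charge", imbalance = q))
    }
  }

  produced <- character(0); consumed <- character(0)
  for (r in model$reactions) {
    if (r$kind == "exchange") next
    s <- r$stoichiometry
    produced <- c(produced, names(s)[s > 0], if (r$reversible) names(s)[s < 0])
    consumed <- c(consumed, names(s)[s < 0], if (r$reversible) names(s)[s > 0])
  }
  used <- unique(c(produced, consumed))
  orphan_ids <- used[!(used %in% produced) | !(used %in% consumed)]
  orphans <- data.frame(
    metabolite = orphan_ids,
    problem = ifelse(orphan_ids %in% produced, "produced-only", "consumed-only"))

  structure(list(syntax = syntax, balance = balance, orphans = orphans,
                 valid = nrow(syntax) == 0 && nrow(balance) == 0 &&
                   nrow(orphans) == 0),
            class = "gf_validation")
}

#' @export
print.gf_validation <- function(x, ...) {
  cat("gf_validation:", if (x$valid) "no findings\n" else "findings present\n")
  if (nrow(x$syntax)) { cat("syntax:\n"); print(x$syntax) }
  if (nrow(x$balance)) { cat("balance:\n"); print(x$balance) }
  if (nrow(x$orphans)) { cat("orphans:\n"); print(x$orphans) }
  invisible(x)
}

# --- small internal helpers shared across modules ---

# resolve a possibly-aliased reaction id ("EXhdca(e)" / "EX_hdca(e)" /
# "EX_hdca_e") against the model's reaction ids
resolve_reaction_id <- function(model, id) {
  rids <- reaction_ids(model)
  if (id %in% rids) return(id)
  norm <- function(x) gsub("[^A-Za-z0-9]", "", gsub("\\(([a-z])\\)$", "_\\1", x))
  hit <- which(norm(rids) == norm(id))
  if (length(hit) == 1) return(rids[hit])
  stop("unknown reaction id: '", id, "'")
}

#' Set or read flux bounds of a reaction
#'
#' Reaction ids may use any accepted alias dialect (e.g. \code{"EXhdca(e)"}
#' for \code{"EX_hdca_e"}).
#'
#' @param model a \code{gf_model}.
#' @param id reaction id.
#' @param lb,ub new bounds (either may be omitted).
#' @return \code{set_bounds}: the modified model copy; \code{get_bounds}: a
#'   named numeric vector \code{c(lb, ub)}.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  id <- resolve_reaction_id(model, id)
  if (!is.null(lb)) model$reactions[[id]]$lb <- lb
  if (!is.null(ub)) model$reactions[[id]]$ub <- ub
  model
}

#' @rdname set_bounds
#' @export
get_bounds <- function(model, id) {
  id <- resolve_reaction_id(model, id)
  r <- model$reactions[[id]]
  c(lb = r$lb, ub = r$ub)
}
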