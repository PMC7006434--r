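# TSV readers and writers: reaction tables (ID / formula / description),
# expression profiles, medium definitions, and deterministic result reports.

#' Read a reaction table (TSV with columns ID, formula, description)
#'
#' The formula column uses the reaction-formula dialect of
#' [parse_reaction_formula()]. Optional columns \code{gpr} and
#' \code{subsystem} are honored when present.
#'
#' @param path TSV file with a header line.
#' @return list of \code{gf_reaction} objects.
#' @export
read_reaction_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("id", "formula") %in% names(df)))
    stop("reaction table needs columns 'ID' and 'formula': ", path)
  lapply(seq_len(nrow(df)), function(i) {
    p <- parse_reaction_formula(df$formula[i])
    reaction(id = df$id[i], stoichiometry = p$stoichiometry,
             reversible = p$reversible,
             name = if ("description" %in% names(df)) df$description[i] else df$id[i],
             gpr = if ("gpr" %in% names(df)) df$gpr[i] else NULL,
             subsystem = if ("subsystem" %in% names(df)) df$subsystem[i]
                         else NA_character_)
  })
}

#' Read a gene-expression table
#'
#' Expects a TSV with header and columns \code{gene}, \code{value} (mean
#' expression, arbitrary non-negative units).
#'
#' @param path TSV file.
#' @return named numeric vector (an expression profile).
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("gene", "value") %in% names(df)))
    stop("expression table needs columns 'gene' and 'value': ", path)
  if (nrow(df) == 0) stop("expression table has no genes: ", path)
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup) > 0)
    stop("duplicate gene row(s) in expression table: ",
         paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(df$value) | df$value < 0)
  if (length(bad) > 0)
    stop("negative or non-finite expression at row ", bad[1],
         " (gene '", df$gene[bad[1]], "')")
  stats::setNames(df$value, df$gene)
}

#' Create a medium definition
#'
#' @param uptake named numeric vector: exchange reaction id -> maximum uptake
#'   rate (mmol/gDW/h, non-negative).
#' @param outputs character vector of exchange reaction ids allowed to carry
#'   positive (secretion) flux.
#' @return object of class \code{"gf_medium"}.
#' @export
medium <- function(uptake, outputs = character(0)) {
  stopifnot(is.numeric(uptake), !is.null(names(uptake)))
  if (any(uptake < 0)) stop("uptake rates must be >= 0")
  structure(list(uptake = uptake, outputs = outputs), class = "gf_medium")
}

#' Read a medium definition table
#'
#' Expects a TSV with header and columns \code{exchange_id},
#' \code{max_uptake}, \code{is_output} (0/1 or TRUE/FALSE). A row may define
#' an input (max_uptake > 0), an output, or both.
#'
#' @param path TSV file.
#' @return object of class \code{"gf_medium"}.
#' @export
read_medium <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("exchange_id", "max_uptake", "is_output")
  if (!all(need %in% names(df)))
    stop("medium table needs columns ", paste(need, collapse = ", "), ": ", path)
  bad <- which(!is.finite(df$max_uptake) | df$max_uptake < 0)
  if (length(bad) > 0)
    stop("negative or non-finite max_uptake at row ", bad[1],
         " ('", df$exchange_id[bad[1]], "')")
  up <- df$max_uptake[df$max_uptake > 0]
  names(up) <- df$exchange_id[df$max_uptake > 0]
  medium(uptake = up,
         outputs = df$exchange_id[as.logical(df$is_output)])
}

# deterministic 6-significant-digit formatting used by all report writers
fmt_num <- function(x) trimws(formatC(signif(x, 6), format = "g", digits = 6))

#' Write a per-reaction flux report
#'
#' TSV with deterministic ordering (by reaction id) and fixed 6-significant-
#' digit formatting. Fluxes with magnitude below 1e-9 are reported as 0 (the
#' solver state itself is never clamped).
#'
#' @param fluxes a \code{gf_flux} (from [solve_fba()] and friends) or a named
#'   numeric vector.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_flux_report <- function(fluxes, path) {
  v <- if (inherits(fluxes, "gf_flux")) fluxes$fluxes else fluxes
  v[abs(v) < 1e-9] <- 0
  ord <- order(names(v))
  df <- data.frame(reaction_id = names(v)[ord], flux = fmt_num(unname(v)[ord]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fold-change report
#'
#' @param records data.frame from [fold_changes()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_foldchange_report <- function(records, path) {
  df <- records
  for (col in c("flux_ref", "flux_alt", "fold_change"))
    df[[col]] <- fmt_num(df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
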