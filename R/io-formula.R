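# Reaction-formula dialect of the tissue-model reaction tables:
#   "1 glu_L[e] -> 1 gln_L[e]"        irreversible
#   "Tibolone[e] <=>"                 reversible one-sided exchange
# Unicode arrows (→, ↔) and ASCII arrows ("->", "<=>") are both
# accepted on input; output is always ASCII.

#' Parse a reaction formula string
#'
#' Coefficients default to 1 when omitted; left-hand side metabolites get
#' negative coefficients, right-hand side positive. One-sided formulas yield
#' single-metabolite exchange stoichiometry.
#'
#' @param text a nonempty formula string.
#' @return list with \code{stoichiometry} (named numeric) and
#'   \code{reversible} (logical).
#' @examples
#' parse_reaction_formula("1 glc_D[e] -> 2 lac_L[e]")
#' parse_reaction_formula("Tibolone[e] <=>")
#' @export
parse_reaction_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  txt <- trimws(text)
  if (!nzchar(txt)) stop("empty reaction formula")
  txt <- gsub("→", "->", txt)
  txt <- gsub("↔", "<=>", txt)
  reversible <- grepl("<=>", txt, fixed = TRUE)
  arrow <- if (reversible) "<=>" else "->"
  if (!grepl(arrow, txt, fixed = TRUE))
    stop("no reaction arrow ('->' or '<=>') in formula: '", text, "'")
  sides <- strsplit(txt, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1) sides <- c(sides, "")
  if (length(sides) != 2)
    stop("more than one arrow in formula: '", text, "'")

  parse_side <- function(side, sign, side_name) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      if (!nzchar(tm))
        stop("malformed term on ", side_name, " side of '", text, "'")
      parts <- strsplit(tm, "[ \t]+")[[1]]
      if (length(parts) == 1) { coef <- 1; met <- parts[1] }
      else if (length(parts) == 2) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        met <- parts[2]
        if (is.na(coef))
          stop("malformed coefficient '", parts[1], "' in '", text, "'")
      } else stop("malformed term '", tm, "' in '", text, "'")
      if (!is.na(suppressWarnings(as.numeric(met))))
        stop("malformed term '", tm, "' in '", text, "': metabolite missing")
      if (coef == 0)
        stop("zero coefficient for '", met, "' in '", text, "'")
      met <- parse_met_id(met)$id
      if (met %in% names(out))
        stop("duplicate metabolite '", met, "' on ", side_name,
             " side of '", text, "'")
      out[met] <- sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1, "left")
  rhs <- parse_side(sides[2], +1, "right")
  if (length(lhs) == 0 && length(rhs) == 0)
    stop("formula has no metabolites: '", text, "'")
  st <- lhs
  for (met in names(rhs)) {
    if (met %in% names(st)) st[met] <- st[met] + rhs[met] else st[met] <- rhs[met]
  }
  if (any(abs(st) < 1e-12))
    stop("net-zero stoichiometry for '",
         paste(names(st)[abs(st) < 1e-12], collapse = ", "),
         "' in '", text, "'")
  list(stoichiometry = st, reversible = reversible)
}

#' Print a stoichiometry map as a formula string (inverse of the parser)
#'
#' @param stoichiometry named numeric vector (negative = consumed).
#' @param reversible logical; selects \code{"<=>"} vs \code{"->"}.
#' @return ASCII formula string.
#' @export
format_reaction_formula <- function(stoichiometry, reversible = FALSE) {
  fmt_side <- function(s) {
    if (length(s) == 0) return("")
    paste(paste(format(abs(unname(s)), trim = TRUE, scientific = FALSE),
                names(s)), collapse = " + ")
  }
  lhs <- fmt_side(stoichiometry[stoichiometry < 0])
  rhs <- fmt_side(stoichiometry[stoichiometry > 0])
  arrow <- if (reversible) "<=>" else "->"
  trimws(paste(lhs, arrow, rhs))
}

# ---- GPR boolean trees -----------------------------------------------------

#' Parse a gene-protein-reaction rule string into a boolean tree
#'
#' Grammar: gene identifiers combined with \code{and} / \code{or}
#' (case-insensitive) and parentheses. \code{NULL}, \code{""} or \code{NA}
#' yield \code{NULL} (no gene association).
#'
#' @param text rule string, e.g. \code{"(A and B) or C"}.
#' @return a tree of nested lists: \code{list(type = "leaf", gene = ...)} or
#'   \code{list(type = "and"/"or", children = list(...))}; \code{NULL} for no
#'   association.
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text) || !nzchar(trimws(text)))
    return(NULL)
  toks <- regmatches(text, gregexpr("\\(|\\)|[^\\s()]+", text, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_or <- function() {
    node <- parse_and()
    kids <- list(node)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance(); kids[[length(kids) + 1L]] <- parse_and()
    }
    if (length(kids) == 1) kids[[1]] else list(type = "or", children = kids)
  }
  parse_and <- function() {
    node <- parse_atom()
    kids <- list(node)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance(); kids[[length(kids) + 1L]] <- parse_atom()
    }
    if (length(kids) == 1) kids[[1]] else list(type = "and", children = kids)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of GPR rule: '", text, "'")
    if (t == "(") {
      advance()
      node <- parse_or()
      if (is.na(peek()) || peek() != ")")
        stop("unbalanced parentheses in GPR rule: '", text, "'")
      advance()
      return(node)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("unexpected token '", t, "' in GPR rule: '", text, "'")
    advance()
    list(type = "leaf", gene = t)
  }
  tree <- parse_or()
  if (pos <= length(toks))
    stop("trailing tokens in GPR rule: '", text, "'")
  tree
}

#' Render a GPR tree back to a rule string
#' @param gpr tree from [parse_gpr()] (or \code{NULL}).
#' @return character string (\code{""} for no association).
#' @export
format_gpr <- function(gpr) {
  if (is.null(gpr)) return("")
  rec <- function(node, parent_op = NULL) {
    if (node$type == "leaf") return(node$gene)
    inner <- vapply(node$children, rec, character(1), parent_op = node$type)
    s <- paste(inner, collapse = paste0(" ", node$type, " "))
    if (!is.null(parent_op) && parent_op != node$type) paste0("(", s, ")") else s
  }
  rec(gpr)
}

# gene symbols appearing in a GPR tree
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (gpr$type == "leaf") return(gpr$gene)
  unique(unlist(lapply(gpr$children, gpr_genes)))
}
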