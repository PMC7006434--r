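# SBML Level 3 subset: core stoichiometry + fbc-style bounds, gene-product
# associations and the active objective. Kinetic laws and other constructs
# FBA does not need are skipped (with a warning on read). Subsystem tags and
# the pseudo-reaction kind travel in a small custom namespace so that a
# write -> read round trip reproduces the model exactly.

SBML_NS  <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS   <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
GF_NS    <- "http://gliaflux.invalid/sbml"

sbml_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Write a model as SBML (Level 3 subset)
#'
#' @param model a \code{gf_model}.
#' @param path output file.
#' @return invisibly, the path.
#' @seealso [read_sbml()]
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS, "xmlns:gf" = GF_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "gliaflux_model",
                             "fbc:strict" = "false")

  comps <- sort(unique(model$metabolites$compartment))
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cc in comps)
    xml2::xml_add_child(lc, "compartment", id = cc, constant = "true")

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    p <- parse_met_id(mt$id)
    sp <- xml2::xml_add_child(
      ls, "species",
      id = paste0("M_", sbml_sid(p$base), "_", p$compartment),
      name = mt$name, compartment = p$compartment,
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false", "gf:base" = p$base)
    if (!is.na(mt$formula)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", mt$formula)
    if (!is.na(mt$charge)) xml2::xml_set_attr(sp, "fbc:charge", as.character(mt$charge))
  }

  # flux-bound parameters (deduplicated by value)
  bkey <- function(v) sprintf("%.17g", v)
  bvals <- sort(unique(unlist(lapply(model$reactions, function(r) c(r$lb, r$ub)))))
  bids <- stats::setNames(paste0("bnd_", seq_along(bvals)),
                          vapply(bvals, bkey, character(1)))
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (k in seq_along(bvals))
    xml2::xml_add_child(lp, "parameter", id = bids[[k]],
                        value = bkey(bvals[k]), constant = "true")

  genes <- sort(unique(unlist(lapply(model$reactions, function(r) gpr_genes(r$gpr)))))
  if (length(genes) > 0) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes)
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sbml_sid(g)),
                          "fbc:label" = g)
  }

  add_gpr <- function(parent, node) {
    if (node$type == "leaf") {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = paste0("G_", sbml_sid(node$gene)))
    } else {
      el <- xml2::xml_add_child(parent, paste0("fbc:", node$type))
      for (ch in node$children) add_gpr(el, ch)
    }
  }

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(
      lr, "reaction", id = paste0("R_", sbml_sid(r$id)), name = r$name,
      reversible = tolower(as.character(r$reversible)), fast = "false",
      "fbc:lowerFluxBound" = bids[[bkey(r$lb)]],
      "fbc:upperFluxBound" = bids[[bkey(r$ub)]],
      "gf:id" = r$id, "gf:kind" = r$kind)
    if (!is.na(r$subsystem)) xml2::xml_set_attr(rn, "gf:subsystem", r$subsystem)
    reac <- r$stoichiometry[r$stoichiometry < 0]
    prod <- r$stoichiometry[r$stoichiometry > 0]
    if (length(reac) > 0) {
      el <- xml2::xml_add_child(rn, "listOfReactants")
      for (met in names(reac)) {
        p <- parse_met_id(met)
        xml2::xml_add_child(el, "speciesReference",
                            species = paste0("M_", sbml_sid(p$base), "_", p$compartment),
                            stoichiometry = sprintf("%.17g", abs(reac[[met]])),
                            constant = "true")
      }
    }
    if (length(prod) > 0) {
      el <- xml2::xml_add_child(rn, "listOfProducts")
      for (met in names(prod)) {
        p <- parse_met_id(met)
        xml2::xml_add_child(el, "speciesReference",
                            species = paste0("M_", sbml_sid(p$base), "_", p$compartment),
                            stoichiometry = sprintf("%.17g", prod[[met]]),
                            constant = "true")
      }
    }
    if (!is.null(r$gpr)) {
      ga <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      add_gpr(ga, r$gpr)
    }
  }

  if (!is.null(model$objective_id)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", sbml_sid(model$objective_id)),
                        "fbc:coefficient" = "1")
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a model from SBML (Level 3 subset)
#'
#' Species, compartments, reactions, flux bounds, gene-product associations
#' and the active objective are restored; unsupported constructs (e.g.
#' kinetic laws) produce a warning and are skipped. Reactions without
#' explicit bounds receive defaults: \code{(-1000, 1000)} when reversible,
#' \code{(0, 1000)} otherwise.
#'
#' @param path SBML file.
#' @return a \code{gf_model}.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  nsmap <- xml2::xml_ns(doc)
  pfx_of <- function(uri, fallback) {
    hit <- names(nsmap)[nsmap == uri]
    if (length(hit) >= 1) hit[1] else fallback
  }
  core <- pfx_of(SBML_NS, "d1")
  fbc <- pfx_of(FBC_NS, "fbc")
  gf <- pfx_of(GF_NS, NA_character_)
  q <- function(name) paste0(core, ":", name)         # core-namespace xpath
  a_fbc <- function(node, name) xml2::xml_attr(node, paste0(fbc, ":", name),
                                               ns = nsmap)
  a_gf <- function(node, name) {
    if (is.na(gf)) return(NA_character_)
    xml2::xml_attr(node, paste0(gf, ":", name), ns = nsmap)
  }

  mdl <- xml2::xml_find_first(doc, paste0(".//", q("model")), nsmap)
  if (is.na(xml2::xml_name(mdl))) stop("no <model> element in ", path)

  params <- xml2::xml_find_all(
    mdl, paste0("./", q("listOfParameters"), "/", q("parameter")), nsmap)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  gps <- xml2::xml_find_all(
    mdl, paste0("./", fbc, ":listOfGeneProducts/", fbc, ":geneProduct"), nsmap)
  glabels <- stats::setNames(
    vapply(gps, function(g) {
      lb <- a_fbc(g, "label")
      if (is.na(lb)) a_fbc(g, "id") else lb
    }, character(1)),
    vapply(gps, function(g) a_fbc(g, "id"), character(1)))

  species <- xml2::xml_find_all(
    mdl, paste0("./", q("listOfSpecies"), "/", q("species")), nsmap)
  met_df <- NULL
  sid2met <- character(0)
  for (sp in species) {
    sid <- xml2::xml_attr(sp, "id")
    comp <- xml2::xml_attr(sp, "compartment")
    base <- a_gf(sp, "base")
    if (is.na(base)) {
      base <- sub("^M_", "", sid)
      base <- sub(paste0("_", comp, "$"), "", base)
    }
    mid <- paste0(base, "[", comp, "]")
    sid2met[sid] <- mid
    ch <- a_fbc(sp, "charge")
    nm <- xml2::xml_attr(sp, "name")
    met_df <- rbind(met_df, metabolite(
      mid, name = if (is.na(nm)) mid else nm,
      formula = a_fbc(sp, "chemicalFormula"),
      charge = if (is.na(ch)) NA_integer_ else as.integer(ch)))
  }
  if (is.null(met_df))
    met_df <- metabolite("x[c]")[0, ]

  read_gpr_node <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- a_fbc(node, "geneProduct")
      gene <- if (gid %in% names(glabels)) glabels[[gid]] else sub("^G_", "", gid)
      return(list(type = "leaf", gene = gene))
    }
    if (nm %in% c("and", "or")) {
      kids <- lapply(xml2::xml_children(node), read_gpr_node)
      return(list(type = nm, children = kids))
    }
    stop("unsupported GPR element <", nm, ">")
  }

  rxn_nodes <- xml2::xml_find_all(
    mdl, paste0("./", q("listOfReactions"), "/", q("reaction")), nsmap)
  skipped <- character(0)
  rxns <- list()
  for (rn in rxn_nodes) {
    if (length(xml2::xml_find_all(rn, paste0("./", q("kineticLaw")), nsmap)) > 0)
      skipped <- c(skipped, "kineticLaw")
    gfid <- a_gf(rn, "id")
    if (is.na(gfid)) gfid <- sub("^R_", "", xml2::xml_attr(rn, "id"))
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(
      rn, paste0("./", q("listOfReactants"), "/", q("speciesReference")), nsmap)) {
      mid <- sid2met[[xml2::xml_attr(sr, "species")]]
      st[mid] <- -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(
      rn, paste0("./", q("listOfProducts"), "/", q("speciesReference")), nsmap)) {
      mid <- sid2met[[xml2::xml_attr(sr, "species")]]
      co <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      st[mid] <- if (mid %in% names(st)) st[[mid]] + co else co
    }
    lbp <- a_fbc(rn, "lowerFluxBound"); ubp <- a_fbc(rn, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(pvals)) pvals[[lbp]]
          else if (rev) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(pvals)) pvals[[ubp]] else 1000
    ga <- xml2::xml_find_first(
      rn, paste0("./", fbc, ":geneProductAssociation"), nsmap)
    gpr <- if (!is.na(xml2::xml_name(ga))) read_gpr_node(xml2::xml_child(ga)) else NULL
    nm <- xml2::xml_attr(rn, "name")
    kd <- a_gf(rn, "kind")
    rxns[[length(rxns) + 1L]] <- reaction(
      id = gfid, stoichiometry = st, reversible = rev, lb = lb, ub = ub,
      name = if (is.na(nm)) gfid else nm, gpr = gpr,
      subsystem = a_gf(rn, "subsystem"),
      kind = if (is.na(kd)) NA_character_ else kd)
  }
  if (length(skipped) > 0)
    warning("skipped unsupported SBML construct(s): ",
            paste(unique(skipped), collapse = ", "))

  obj <- xml2::xml_find_first(
    mdl, paste0("./", fbc, ":listOfObjectives/", fbc, ":objective/",
                fbc, ":listOfFluxObjectives/", fbc, ":fluxObjective"), nsmap)
  objective_id <- NULL
  if (!is.na(xml2::xml_name(obj))) {
    oref <- sub("^R_", "", a_fbc(obj, "reaction"))
    rids <- vapply(rxns, function(r) r$id, character(1))
    if (oref %in% rids) objective_id <- oref
  }
  metabolic_model(met_df, rxns, objective_id = objective_id)
}
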