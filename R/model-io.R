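## Reading and writing stoichiometric models.
##
## Primary format: a JSON schema
##   {"metabolites":[{"id", "formula"?}],
##    "reactions":[{"id","stoichiometry":{met: coef},
##                  "lower_bound","upper_bound","gpr"}],
##    "objective", "atp_maintenance", "gam"?}
## Unbounded sides are serialized as JSON null. A minimal SBML Level 3
## (+ FBC-style gene associations) subset is supported for interchange; only
## documents written by this package are guaranteed to round-trip.

#' Read a metabolic model from JSON or SBML
#'
#' @param path File path.
#' @param format `"json"` or `"sbml"`; guessed from the file extension by
#'   default.
#' @return A validated [MetabolicModel-class].
#' @seealso [writeMetabolicModel()]
#' @export
readMetabolicModel <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (!file.exists(path)) inputError("no such file: ", path)
  if (format == "json") readModelJSON(path) else readModelSBML(path)
}

#' Write a metabolic model to JSON or SBML
#'
#' @param model A [MetabolicModel-class].
#' @inheritParams readMetabolicModel
#' @return `path`, invisibly.
#' @export
writeMetabolicModel <- function(model, path,
                                format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (format == "json") writeModelJSON(model, path)
  else writeModelSBML(model, path)
  invisible(path)
}

.boundToJSON <- function(x) if (is.infinite(x)) NULL else x
.boundFromJSON <- function(x, side) {
  if (is.null(x)) (if (side == "lower") -Inf else Inf) else as.numeric(x)
}

readModelJSON <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$reactions) || is.null(doc$objective) ||
      is.null(doc$atp_maintenance))
    inputError("model JSON lacks required fields")
  mets <- NULL
  if (!is.null(doc$metabolites)) {
    ids <- vapply(doc$metabolites, function(m) as.character(m$id), "")
    forms <- vapply(doc$metabolites, function(m) {
      if (is.null(m$formula)) "" else as.character(m$formula)
    }, "")
    mets <- stats::setNames(forms, ids)
  }
  rxns <- lapply(doc$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    list(stoichiometry = st,
         lower_bound = .boundFromJSON(r$lower_bound, "lower"),
         upper_bound = .boundFromJSON(r$upper_bound, "upper"),
         gpr = if (is.null(r$gpr)) "" else as.character(r$gpr))
  })
  names(rxns) <- vapply(doc$reactions, function(r) as.character(r$id), "")
  if (anyDuplicated(names(rxns))) inputError("duplicate reaction ids in JSON")
  MetabolicModel(rxns, metabolites = mets,
                 genes = if (is.null(doc$genes)) NULL else unlist(doc$genes),
                 objective = doc$objective,
                 atp_maintenance = doc$atp_maintenance,
                 gam = if (is.null(doc$gam)) 0 else as.numeric(doc$gam))
}

writeModelJSON <- function(model, path) {
  S <- stoichiometry(model)
  lb <- lowerBounds(model); ub <- upperBounds(model)
  gpr <- gprRules(model)
  rxns <- lapply(reactionIds(model), function(r) {
    col <- stats::setNames(as.numeric(S[, r]), rownames(S))
    st <- col[col != 0]
    out <- list(id = r, stoichiometry = as.list(st),
                lower_bound = .boundToJSON(lb[[r]]),
                upper_bound = .boundToJSON(ub[[r]]))
    if (nzchar(gpr[[r]])) out$gpr <- gpr[[r]]
    out
  })
  mets <- lapply(metaboliteIds(model), function(m) {
    f <- model@metFormula[[m]]
    if (nzchar(f)) list(id = m, formula = f) else list(id = m)
  })
  doc <- list(metabolites = mets, reactions = rxns,
              genes = as.list(geneIds(model)),
              objective = objectiveReaction(model),
              atp_maintenance = maintenanceReaction(model),
              gam = model@gamATP)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

## ---- SBML (minimal Level 3 subset with fbc-style annotations) ------------

.sbmlBound <- function(x, side) {
  if (is.infinite(x)) (if (side == "lower") "-INF" else "INF")
  else format(x, digits = 17)
}

writeModelSBML <- function(model, path) {
  S <- stoichiometry(model)
  lb <- lowerBounds(model); ub <- upperBounds(model)
  gpr <- gprRules(model)
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
    level = "3", version = "1", "fbc:required" = "false"
  )
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             "fbc:strict" = "false")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", constant = "true")
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in metaboliteIds(model)) {
    sp <- xml2::xml_add_child(los, "species", id = m, compartment = "c",
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    f <- model@metFormula[[m]]
    if (nzchar(f)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", f)
  }
  logp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in geneIds(model)) {
    xml2::xml_add_child(logp, "fbc:geneProduct", "fbc:id" = g,
                        "fbc:label" = g)
  }
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in reactionIds(model)) {
    rx <- xml2::xml_add_child(lor, "reaction", id = r, reversible =
                                tolower(as.character(lb[[r]] < 0)),
                              fast = "false",
                              "fbc:lowerFluxBound" = .sbmlBound(lb[[r]], "lower"),
                              "fbc:upperFluxBound" = .sbmlBound(ub[[r]], "upper"))
    if (nzchar(gpr[[r]]))
      xml2::xml_set_attr(rx, "fbc:geneAssociation", gpr[[r]])
    col <- stats::setNames(as.numeric(S[, r]), rownames(S))
    sub <- col[col < 0]; prod <- col[col > 0]
    if (length(sub)) {
      lo <- xml2::xml_add_child(rx, "listOfReactants")
      for (m in names(sub))
        xml2::xml_add_child(lo, "speciesReference", species = m,
                            stoichiometry = format(-sub[[m]], digits = 17),
                            constant = "true")
    }
    if (length(prod)) {
      lo <- xml2::xml_add_child(rx, "listOfProducts")
      for (m in names(prod))
        xml2::xml_add_child(lo, "speciesReference", species = m,
                            stoichiometry = format(prod[[m]], digits = 17),
                            constant = "true")
    }
  }
  objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lof <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lof, "fbc:fluxObjective",
                      "fbc:reaction" = objectiveReaction(model),
                      "fbc:coefficient" = "1")
  xml2::xml_add_child(mdl, "annotation",
                      atpMaintenance = maintenanceReaction(model),
                      gamATP = format(model@gamATP, digits = 17))
  xml2::write_xml(doc, path)
}

.parseSbmlBound <- function(x, side) {
  if (is.na(x) || x %in% c("INF", "-INF"))
    return(if (!is.na(x) && x == "-INF") -Inf
           else if (!is.na(x) && x == "INF") Inf
           else if (side == "lower") -Inf else Inf)
  as.numeric(x)
}

readModelSBML <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)  # work positionally; fbc attrs keep their prefix
  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  met_ids <- xml2::xml_attr(species, "id")
  forms <- xml2::xml_attr(species, "chemicalFormula")
  forms[is.na(forms)] <- ""
  gps <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  genes <- xml2::xml_attr(gps, "id")
  rxnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rxnodes)) inputError("SBML parse error: no reactions")
  rxns <- lapply(rxnodes, function(rx) {
    refs <- function(which, sign) {
      nodes <- xml2::xml_find_all(rx, paste0("./", which, "/speciesReference"))
      stats::setNames(
        sign * as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
        xml2::xml_attr(nodes, "species")
      )
    }
    st <- c(refs("listOfReactants", -1), refs("listOfProducts", 1))
    gpr <- xml2::xml_attr(rx, "geneAssociation")
    list(stoichiometry = st,
         lower_bound = .parseSbmlBound(xml2::xml_attr(rx, "lowerFluxBound"),
                                       "lower"),
         upper_bound = .parseSbmlBound(xml2::xml_attr(rx, "upperFluxBound"),
                                       "upper"),
         gpr = if (is.na(gpr)) "" else gpr)
  })
  names(rxns) <- xml2::xml_attr(rxnodes, "id")
  obj <- xml2::xml_attr(
    xml2::xml_find_first(
      doc, ".//*[local-name()='listOfObjectives']//*[local-name()='fluxObjective']"),
    "reaction")
  ann <- xml2::xml_find_first(doc, ".//model/annotation")
  atpm <- xml2::xml_attr(ann, "atpMaintenance")
  gam <- xml2::xml_attr(ann, "gamATP")
  if (is.na(obj) || is.na(atpm))
    inputError("SBML lacks objective or maintenance annotation")
  MetabolicModel(rxns,
                 metabolites = stats::setNames(forms, met_ids),
                 genes = if (length(genes)) genes else NULL,
                 objective = obj, atp_maintenance = atpm,
                 gam = if (is.na(gam)) 0 else as.numeric(gam))
}
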