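## Constructor, accessors and show methods for MetabolicModel and friends.

#' Construct a MetabolicModel
#'
#' @param reactions Named list: one element per reaction, each a list with
#'   `stoichiometry` (named numeric, metabolite -> coefficient), `lower_bound`,
#'   `upper_bound` and optional `gpr` (default "" = spontaneous).
#' @param metabolites Optional named character vector mapping metabolite ids to
#'   elemental formulas ("" when unknown); metabolites appearing only in
#'   stoichiometries are allowed and get an empty formula.
#' @param genes Optional character vector of gene ids; defaults to the union of
#'   genes referenced by the GPR rules.
#' @param objective Reaction id of the biomass/objective reaction.
#' @param atp_maintenance Reaction id of the ATP maintenance reaction.
#' @param gam GAM ATP coefficient (mmol/gDCW) already embedded in the biomass
#'   reaction, if any (see [setMaintenance()]).
#' @return A validated [MetabolicModel-class] object.
#' @examples
#' m <- MetabolicModel(
#'   reactions = list(
#'     EX_a = list(stoichiometry = c(a = -1), lower_bound = -10, upper_bound = 0),
#'     GROW = list(stoichiometry = c(a = -1, atp = 1), lower_bound = 0,
#'                 upper_bound = 1000),
#'     ATPM = list(stoichiometry = c(atp = -1), lower_bound = 0,
#'                 upper_bound = 1000)
#'   ),
#'   objective = "GROW", atp_maintenance = "ATPM"
#' )
#' @export
MetabolicModel <- function(reactions, metabolites = NULL, genes = NULL,
                           objective, atp_maintenance, gam = 0) {
  if (anyDuplicated(names(reactions)))
    inputError("duplicate reaction ids")
  rxn_ids <- names(reactions)
  mets_used <- unique(unlist(lapply(reactions,
                                    function(r) names(r$stoichiometry))))
  if (!is.null(metabolites)) {
    declared <- names(metabolites)
    if (anyDuplicated(declared)) inputError("duplicate metabolite ids")
    unknown <- setdiff(mets_used, declared)
    if (length(unknown))
      inputError("stoichiometry references undeclared metabolite(s): ",
                 paste(unknown, collapse = ", "))
    met_ids <- declared
    formulas <- as.character(metabolites)
  } else {
    met_ids <- mets_used
    formulas <- rep("", length(met_ids))
  }
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(reactions)) {
    st <- reactions[[k]]$stoichiometry
    if (is.null(st) || !length(st))
      inputError("reaction '", rxn_ids[[k]], "' has empty stoichiometry")
    i <- c(i, match(names(st), met_ids))
    j <- c(j, rep(k, length(st)))
    x <- c(x, as.numeric(st))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(met_ids), length(reactions)),
                            dimnames = list(met_ids, rxn_ids))
  num <- function(field, default = NULL) {
    vapply(reactions, function(r) {
      v <- r[[field]]
      if (is.null(v)) {
        if (is.null(default)) inputError("missing ", field)
        v <- default
      }
      as.numeric(v)
    }, numeric(1))
  }
  lb <- stats::setNames(num("lower_bound"), rxn_ids)
  ub <- stats::setNames(num("upper_bound"), rxn_ids)
  bad <- lb > ub
  if (any(bad))
    inputError("lower bound exceeds upper bound for: ",
               paste(rxn_ids[bad], collapse = ", "))
  gpr <- stats::setNames(vapply(reactions, function(r) {
    g <- r$gpr
    if (is.null(g) || is.na(g)) "" else as.character(g)
  }, character(1)), rxn_ids)
  gpr_genes <- unique(unlist(lapply(gpr, gprGenes)))
  if (is.null(genes)) genes <- gpr_genes
  methods::new("MetabolicModel",
    stoichiometry = S,
    lowerBounds = lb, upperBounds = ub, gpr = gpr,
    genes = as.character(genes),
    metFormula = stats::setNames(formulas, met_ids),
    objectiveReaction = objective,
    maintenanceReaction = atp_maintenance,
    gamATP = as.numeric(gam)
  )
}

#' @rdname MetabolicModel
#' @param object,x A `MetabolicModel`.
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))
#' @rdname MetabolicModel
#' @export
setMethod("reactionIds", "MetabolicModel",
          function(x) colnames(x@stoichiometry))

#' @rdname MetabolicModel
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))
#' @rdname MetabolicModel
#' @export
setMethod("metaboliteIds", "MetabolicModel",
          function(x) rownames(x@stoichiometry))

#' @rdname MetabolicModel
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname MetabolicModel
#' @export
setMethod("geneIds", "MetabolicModel", function(x) x@genes)

#' @rdname MetabolicModel
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))
#' @rdname MetabolicModel
#' @export
setMethod("stoichiometry", "MetabolicModel", function(x) x@stoichiometry)

#' @rdname MetabolicModel
#' @export
setGeneric("lowerBounds", function(x) standardGeneric("lowerBounds"))
#' @rdname MetabolicModel
#' @export
setMethod("lowerBounds", "MetabolicModel", function(x) x@lowerBounds)

#' @rdname MetabolicModel
#' @export
setGeneric("upperBounds", function(x) standardGeneric("upperBounds"))
#' @rdname MetabolicModel
#' @export
setMethod("upperBounds", "MetabolicModel", function(x) x@upperBounds)

#' @rdname MetabolicModel
#' @export
setGeneric("gprRules", function(x) standardGeneric("gprRules"))
#' @rdname MetabolicModel
#' @export
setMethod("gprRules", "MetabolicModel", function(x) x@gpr)

#' @rdname MetabolicModel
#' @export
setGeneric("objectiveReaction", function(x) standardGeneric("objectiveReaction"))
#' @rdname MetabolicModel
#' @export
setMethod("objectiveReaction", "MetabolicModel",
          function(x) x@objectiveReaction)

#' @rdname MetabolicModel
#' @export
setGeneric("maintenanceReaction",
           function(x) standardGeneric("maintenanceReaction"))
#' @rdname MetabolicModel
#' @export
setMethod("maintenanceReaction", "MetabolicModel",
          function(x) x@maintenanceReaction)

#' Replace flux bounds of selected reactions
#'
#' @param x A `MetabolicModel`.
#' @param reaction Reaction id(s).
#' @param lower,upper New bounds (recycled to the length of `reaction`; `NULL`
#'   keeps the current value).
#' @return The modified model.
#' @export
setGeneric("setBounds",
           function(x, reaction, lower = NULL, upper = NULL)
             standardGeneric("setBounds"))
#' @rdname setBounds
#' @export
setMethod("setBounds", "MetabolicModel", function(x, reaction, lower, upper) {
  missing_rxn <- setdiff(reaction, reactionIds(x))
  if (length(missing_rxn))
    inputError("unknown reaction(s): ", paste(missing_rxn, collapse = ", "))
  if (!is.null(lower)) x@lowerBounds[reaction] <- rep_len(lower, length(reaction))
  if (!is.null(upper)) x@upperBounds[reaction] <- rep_len(upper, length(reaction))
  methods::validObject(x)
  x
})

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", ncol(object@stoichiometry), "reactions,",
      nrow(object@stoichiometry), "metabolites,",
      length(object@genes), "genes\n")
  cat("  objective:  ", object@objectiveReaction, "\n")
  cat("  maintenance:", object@maintenanceReaction, "\n")
  rev <- sum(object@lowerBounds < 0)
  cat("  reversible reactions (lb < 0):", rev, "\n")
})

setMethod("show", "FluxDistribution", function(object) {
  cat("FluxDistribution (", object@status, ")\n", sep = "")
  if (object@status == "optimal")
    cat("  objective", object@objectiveReaction, "=",
        format(object@objectiveValue, digits = 6), "\n")
})

#' @rdname fluxes
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))
#' Fluxes of a FluxDistribution
#' @param x A `FluxDistribution`.
#' @return Named numeric vector of fluxes (mmol/gDCW/h).
#' @export
setMethod("fluxes", "FluxDistribution", function(x) x@fluxes)

#' @rdname fluxes
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))
#' @rdname fluxes
#' @export
setMethod("objectiveValue", "FluxDistribution", function(x) x@objectiveValue)

#' @rdname fluxes
#' @export
setGeneric("solverStatus", function(x) standardGeneric("solverStatus"))
#' @rdname fluxes
#' @export
setMethod("solverStatus", "FluxDistribution", function(x) x@status)

setMethod("show", "FVAResult", function(object) {
  cat("FVAResult:", length(object@minFlux), "reactions, objective",
      object@objectiveReaction, "fixed at",
      format(object@objectiveValue, digits = 6), "\n")
})

#' Flux intervals of an FVAResult as a data.frame
#'
#' @param x An `FVAResult`.
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
setGeneric("fluxIntervals", function(x) standardGeneric("fluxIntervals"))
#' @rdname fluxIntervals
#' @export
setMethod("fluxIntervals", "FVAResult", function(x) {
  data.frame(reaction = names(x@minFlux), min = unname(x@minFlux),
             max = unname(x@maxFlux), row.names = NULL)
})

setMethod("show", "FVADistance", function(object) {
  cat("FVA-distance: d_min =", format(object@dMin, digits = 6),
      ", d_max =", format(object@dMax, digits = 6),
      "over", nrow(object@perReaction), "measured reactions\n")
})

setMethod("show", "BiomassEquation", function(object) {
  cat("BiomassEquation:", length(object@consumed), "consumed,",
      length(object@produced), "produced species; GAM =",
      object@gamATP, "mmol ATP/gDCW\n")
  m <- sum(object@consumed * object@speciesMass[names(object@consumed)]) -
    sum(object@produced * object@speciesMass[names(object@produced)])
  cat("  net consumed mass per unit flux:", format(m / 1000, digits = 8), "g\n")
})
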