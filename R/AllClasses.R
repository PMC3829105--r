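## S4 classes for the constraint-based model layer and derived results.

#' @import methods
#' @importFrom Matrix Matrix sparseMatrix
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' MetabolicModel: a stoichiometric model with bounds and GPR rules
#'
#' Container for a constraint-based metabolic model: sparse stoichiometric
#' matrix (metabolites x reactions, coefficients in mmol per unit flux), flux
#' bounds in mmol/gDCW/h, gene-protein-reaction (GPR) boolean rules, optional
#' elemental formulas for metabolites, and the identities of the biomass
#' (objective) and ATP maintenance reactions. Reversibility is encoded solely
#' through the bounds. The biomass reaction is scaled so that its flux equals
#' the specific growth rate (h^-1) and one unit of flux makes 1 g of biomass.
#'
#' @slot stoichiometry sparse metabolite x reaction matrix.
#' @slot lowerBounds,upperBounds named numeric flux bounds per reaction.
#' @slot gpr named character vector of GPR expressions ("" = spontaneous).
#' @slot genes character vector of gene identifiers.
#' @slot metFormula named character vector of elemental formulas ("" allowed).
#' @slot objectiveReaction id of the biomass/objective reaction.
#' @slot maintenanceReaction id of the ATP maintenance (hydrolysis) reaction.
#' @slot gamATP GAM ATP coefficient (mmol/gDCW) currently embedded in the
#'   biomass reaction as a multiple of the ATP-hydrolysis couple; updated by
#'   [setMaintenance()].
#'
#' @export
setClass("MetabolicModel",
  slots = c(
    stoichiometry = "Matrix",
    lowerBounds = "numeric",
    upperBounds = "numeric",
    gpr = "character",
    genes = "character",
    metFormula = "character",
    objectiveReaction = "character",
    maintenanceReaction = "character",
    gamATP = "numeric"
  ),
  prototype = list(gamATP = 0)
)

setValidity("MetabolicModel", function(object) {
  msg <- character(0)
  S <- object@stoichiometry
  rxns <- colnames(S)
  mets <- rownames(S)
  if (is.null(rxns) || is.null(mets))
    msg <- c(msg, "stoichiometry must have metabolite row and reaction column names")
  if (anyDuplicated(rxns)) msg <- c(msg, "duplicate reaction ids")
  if (anyDuplicated(mets)) msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate gene ids")
  for (nm in c("lowerBounds", "upperBounds", "gpr")) {
    v <- slot(object, nm)
    if (!identical(names(v), rxns))
      msg <- c(msg, sprintf("%s must be named by the reaction ids in order", nm))
  }
  if (length(object@metFormula) &&
      !identical(names(object@metFormula), mets))
    msg <- c(msg, "metFormula must be named by the metabolite ids in order")
  if (any(object@lowerBounds > object@upperBounds))
    msg <- c(msg, "lower bound exceeds upper bound for at least one reaction")
  if (length(object@objectiveReaction) != 1L ||
      !(object@objectiveReaction %in% rxns))
    msg <- c(msg, "objectiveReaction must name an existing reaction")
  if (length(object@maintenanceReaction) != 1L ||
      !(object@maintenanceReaction %in% rxns))
    msg <- c(msg, "maintenanceReaction must name an existing reaction")
  ## every column must have at least one nonzero coefficient
  if (ncol(S) && any(Matrix::colSums(S != 0) == 0))
    msg <- c(msg, "every reaction needs non-empty stoichiometry")
  gpr_genes <- unique(unlist(lapply(object@gpr, gprGenes)))
  if (length(setdiff(gpr_genes, object@genes)))
    msg <- c(msg, "GPR rules reference genes missing from the gene list")
  if (length(msg)) msg else TRUE
})

#' FluxDistribution: one FBA solution
#'
#' @slot fluxes named numeric vector (mmol/gDCW/h) per reaction.
#' @slot objectiveValue value of the optimized linear objective.
#' @slot status "optimal", "infeasible" or "unbounded".
#' @slot objectiveReaction reaction that was optimized.
#' @export
setClass("FluxDistribution",
  slots = c(
    fluxes = "numeric",
    objectiveValue = "numeric",
    status = "character",
    objectiveReaction = "character"
  )
)

#' FVAResult: per-reaction flux intervals at a fixed objective
#'
#' Flux variability analysis result: for each reaction the minimal and maximal
#' flux attainable while the objective flux is held at its prescribed value
#' and all other fluxes vary freely within their bounds. Endpoints touching a
#' numerically unbounded side are reported as -Inf/Inf.
#'
#' @slot minFlux,maxFlux named numeric vectors per reaction.
#' @slot objectiveReaction,objectiveValue description of the fixed objective.
#' @slot fixed named numeric vector of additionally fixed fluxes.
#' @export
setClass("FVAResult",
  slots = c(
    minFlux = "numeric",
    maxFlux = "numeric",
    objectiveReaction = "character",
    objectiveValue = "numeric",
    fixed = "numeric"
  )
)

setValidity("FVAResult", function(object) {
  if (!identical(names(object@minFlux), names(object@maxFlux)))
    return("minFlux and maxFlux must share reaction names")
  if (any(object@minFlux > object@maxFlux + 1e-6))
    return("minFlux exceeds maxFlux")
  TRUE
})

#' BiomassEquation: a normalized biomass pseudo-reaction
#'
#' Metabolite coefficients (mmol per unit biomass flux) for the consumed
#' monomers and the produced by-products of biomass assembly, plus the
#' growth-associated maintenance ATP term. By construction one unit of flux
#' through the equation consumes a net 1.000 g of monomer mass.
#'
#' @slot consumed,produced named numeric coefficient vectors (mmol/gDCW).
#' @slot gamATP GAM ATP coefficient (mmol ATP/gDCW) included in `consumed`.
#' @slot speciesMass named numeric residue masses (g/mol) for all species.
#' @slot speciesFormula named character elemental formulas for all species.
#' @export
setClass("BiomassEquation",
  slots = c(
    consumed = "numeric",
    produced = "numeric",
    gamATP = "numeric",
    speciesMass = "numeric",
    speciesFormula = "character"
  )
)

#' FVADistance: squared-distance pair between measurements and FVA intervals
#'
#' For each measured reaction flux f and interval [lo, hi], the minimal
#' contribution is 0 when f lies in the interval and otherwise the squared
#' distance to the nearest endpoint; the maximal contribution is the squared
#' distance to the farthest endpoint. `dMin`/`dMax` are the sums over
#' reactions; an interval with an unbounded endpoint makes `dMax` infinite.
#'
#' @slot dMin,dMax the two summed squared distances.
#' @slot perReaction data.frame breakdown (reaction, measured, lo, hi,
#'   minContribution, maxContribution).
#' @export
setClass("FVADistance",
  slots = c(
    dMin = "numeric",
    dMax = "numeric",
    perReaction = "data.frame"
  )
)

#' ExpressionDataset: per-gene expression values with detection calls
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] with two assays:
#' `log2` (numeric log2 expression) and `calls` (character "P"/"A"/"M"
#' present/absent/marginal detection calls), genes as rows and arrays as
#' columns.
#'
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("log2", "calls") %in% a))
    return("ExpressionDataset needs assays 'log2' and 'calls'")
  calls <- SummarizedExperiment::assay(object, "calls")
  if (!all(calls %in% c("P", "A", "M")))
    return("calls must be one of P, A, M")
  TRUE
})
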