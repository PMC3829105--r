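## Flux balance and flux variability analysis by linear optimization.
##
## The LP engine is the package's bounded-variable primal simplex (see
## simplex.R). Infinite bounds are capped at .BIG internally; a solution
## touching the cap on an originally infinite side is reported "unbounded".

.BIG <- 1e5          # internal cap replacing infinite bounds (mmol/gDCW/h)
.LP_EPS <- 1e-9      # solver feasibility/optimality tolerance
.ASSERT_TOL <- 1e-6  # tolerance used when checking solutions

## Solve max/min c'v s.t. S v = 0, lb <= v <= ub.
## Returns list(status, value, fluxes).
solveLP <- function(S, lb, ub, objective_coefs, sense = c("max", "min")) {
  sense <- match.arg(sense)
  n <- length(lb)
  lb_cap <- pmax(lb, -.BIG)
  ub_cap <- pmin(ub, .BIG)
  if (any(lb_cap > ub_cap))
    return(list(status = "infeasible", value = NA_real_,
                fluxes = stats::setNames(rep(NA_real_, n), colnames(S))))
  res <- boundedSimplex(objective_coefs, as.matrix(S), rep(0, nrow(S)),
                        lb_cap, ub_cap, maximize = (sense == "max"),
                        tol = .LP_EPS)
  if (res$status != "optimal")
    return(list(status = res$status, value = NA_real_,
                fluxes = stats::setNames(rep(NA_real_, n), colnames(S))))
  v <- stats::setNames(res$x, colnames(S))
  ## unbounded if the optimum rides an artificial cap
  hit_cap <- (is.infinite(ub) & v > .BIG * (1 - 1e-6) &
                objective_coefs != 0) |
             (is.infinite(lb) & v < -.BIG * (1 - 1e-6) &
                objective_coefs != 0)
  status <- if (any(hit_cap)) "unbounded" else "optimal"
  list(status = status, value = sum(objective_coefs * v), fluxes = v)
}

#' Flux balance analysis
#'
#' Maximizes or minimizes the flux of one reaction subject to steady-state
#' mass balance (S v = 0) and the model's flux bounds, optionally with
#' additional fluxes held at fixed values.
#'
#' @param model A [MetabolicModel-class].
#' @param objective Reaction id to optimize; defaults to the model's biomass
#'   reaction.
#' @param sense `"max"` or `"min"`.
#' @param fixed Named numeric vector of fluxes to hold exactly (each value
#'   must lie within the reaction's bounds).
#' @return A [FluxDistribution-class]; non-optimal outcomes are reported via
#'   its status (`"infeasible"`/`"unbounded"`), never silently.
#' @examples
#' m <- exampleChainModel()
#' fba(m, objective = "BIO", sense = "max")
#' @export
fba <- function(model, objective = objectiveReaction(model),
                sense = c("max", "min"), fixed = NULL) {
  sense <- match.arg(sense)
  rxns <- reactionIds(model)
  if (!(objective %in% rxns))
    inputError("unknown objective reaction: ", objective)
  lb <- lowerBounds(model)
  ub <- upperBounds(model)
  if (!is.null(fixed) && length(fixed)) {
    if (is.null(names(fixed)) || any(!nzchar(names(fixed))))
      inputError("'fixed' must be a named vector")
    missing_rxn <- setdiff(names(fixed), rxns)
    if (length(missing_rxn))
      inputError("unknown fixed reaction(s): ",
                 paste(missing_rxn, collapse = ", "))
    out_of_bounds <- fixed < lb[names(fixed)] - .ASSERT_TOL |
      fixed > ub[names(fixed)] + .ASSERT_TOL
    if (any(out_of_bounds))
      inputError("fixed flux outside bounds for: ",
                 paste(names(fixed)[out_of_bounds], collapse = ", "))
    lb[names(fixed)] <- fixed
    ub[names(fixed)] <- fixed
  }
  obj <- as.numeric(rxns == objective)
  res <- solveLP(stoichiometry(model), lb, ub, obj, sense)
  methods::new("FluxDistribution",
    fluxes = res$fluxes,
    objectiveValue = res$value,
    status = res$status,
    objectiveReaction = objective
  )
}

#' Flux variability analysis
#'
#' Computes, for each reaction, the interval of flux values attainable while
#' the objective reaction is held at a prescribed value (and any additional
#' `fixed` fluxes are held), all other fluxes varying freely within their
#' bounds. Interval endpoints that ride a numerically unbounded side are
#' reported as `-Inf`/`Inf`.
#'
#' @inheritParams fba
#' @param objectiveValue Flux at which the objective is fixed. When `NULL` it
#'   is first computed by FBA with the given `sense`.
#' @param reactions Reactions to analyze (default: all).
#' @return An [FVAResult-class].
#' @examples
#' m <- exampleChainModel()
#' fva(m, objectiveValue = 0.5)
#' @export
fva <- function(model, objective = objectiveReaction(model),
                objectiveValue = NULL, sense = "max", fixed = NULL,
                reactions = NULL) {
  rxns <- reactionIds(model)
  if (is.null(reactions)) reactions <- rxns
  if (length(setdiff(reactions, rxns)))
    inputError("unknown reaction(s) requested")
  if (is.null(objectiveValue)) {
    sol <- fba(model, objective, sense, fixed)
    if (solverStatus(sol) != "optimal")
      inputError("objective FBA not optimal: ", solverStatus(sol))
    objectiveValue <- objectiveValue(sol)
  }
  lb <- lowerBounds(model)
  ub <- upperBounds(model)
  if (objectiveValue < lb[objective] - .ASSERT_TOL ||
      objectiveValue > ub[objective] + .ASSERT_TOL)
    inputError("objectiveValue outside the objective reaction's bounds")
  lb[objective] <- objectiveValue
  ub[objective] <- objectiveValue
  if (!is.null(fixed) && length(fixed)) {
    lb[names(fixed)] <- fixed
    ub[names(fixed)] <- fixed
  }
  S <- stoichiometry(model)
  lo <- hi <- stats::setNames(rep(NA_real_, length(reactions)), reactions)
  orig_lb <- lowerBounds(model)
  orig_ub <- upperBounds(model)
  for (r in reactions) {
    obj <- as.numeric(rxns == r)
    rmin <- solveLP(S, lb, ub, obj, "min")
    rmax <- solveLP(S, lb, ub, obj, "max")
    if (rmin$status == "infeasible" || rmax$status == "infeasible")
      inputError("FVA infeasible at the fixed objective value")
    lo[r] <- if (rmin$status == "unbounded" ||
                 (is.infinite(orig_lb[r]) &&
                    rmin$value < -.BIG * (1 - 1e-6))) -Inf else rmin$value
    hi[r] <- if (rmax$status == "unbounded" ||
                 (is.infinite(orig_ub[r]) &&
                    rmax$value > .BIG * (1 - 1e-6))) Inf else rmax$value
  }
  ## clip tiny numerical inversions
  swap <- which(lo > hi & lo - hi < .ASSERT_TOL)
  if (length(swap)) { m <- (lo[swap] + hi[swap]) / 2; lo[swap] <- hi[swap] <- m }
  methods::new("FVAResult",
    minFlux = lo, maxFlux = hi,
    objectiveReaction = objective,
    objectiveValue = objectiveValue,
    fixed = if (is.null(fixed)) numeric(0) else fixed
  )
}

#' Apply gene deletions to a model
#'
#' Reactions whose GPR rule evaluates inactive under the deletion set get
#' bounds \[0, 0\]; spontaneous (empty-GPR) reactions are unaffected.
#'
#' @param model A [MetabolicModel-class].
#' @param genes Character vector of gene ids to delete.
#' @return The constrained model.
#' @export
deleteGenes <- function(model, genes) {
  unknown <- setdiff(genes, geneIds(model))
  if (length(unknown))
    inputError("unknown gene(s): ", paste(unknown, collapse = ", "))
  gpr <- gprRules(model)
  affected <- names(gpr)[vapply(gpr, function(g) {
    nzchar(g) && any(gprGenes(g) %in% genes) && !evaluateGPR(g, genes)
  }, logical(1))]
  if (length(affected))
    model <- setBounds(model, affected, lower = 0, upper = 0)
  model
}

#' Essential genes by single-gene deletion
#'
#' A gene is essential when deleting it (and zeroing all reactions whose GPR
#' becomes inactive) drops the FBA-maximal biomass flux below
#' `growth_threshold` times the wild-type maximum.
#'
#' @param model A [MetabolicModel-class]; its wild type must grow.
#' @param growth_threshold Fraction of wild-type growth below which a
#'   deletion counts as lethal (default 0.01).
#' @return Character vector of essential gene ids.
#' @export
essentialGenes <- function(model, growth_threshold = 0.01) {
  wt <- fba(model)
  if (solverStatus(wt) != "optimal" || objectiveValue(wt) <= .ASSERT_TOL)
    inputError("wild-type model does not grow")
  cutoff <- growth_threshold * objectiveValue(wt)
  ess <- vapply(geneIds(model), function(g) {
    sol <- fba(deleteGenes(model, g))
    solverStatus(sol) != "optimal" || objectiveValue(sol) < cutoff
  }, logical(1))
  geneIds(model)[ess]
}

#' Set maintenance-energy parameters of a model
#'
#' Writes the growth-associated maintenance (GAM) into the biomass reaction
#' as a multiple of the ATP-hydrolysis couple, and the non-growth-associated
#' maintenance (NGAM) as the lower bound of the ATP maintenance reaction. The
#' ATP-hydrolysis couple is taken from the maintenance reaction's own
#' stoichiometry, and the model's recorded GAM is replaced (not stacked).
#'
#' @param model A [MetabolicModel-class].
#' @param gam GAM in mmol ATP/gDCW (>= 0).
#' @param ngam NGAM in mmol ATP/gDCW/h (>= 0).
#' @return The updated model.
#' @export
setMaintenance <- function(model, gam = NULL, ngam = NULL) {
  if (!is.null(gam)) {
    if (gam < 0) inputError("gam must be >= 0")
    S <- stoichiometry(model)
    bio <- objectiveReaction(model)
    atpm <- maintenanceReaction(model)
    S[, bio] <- S[, bio] + (gam - model@gamATP) * S[, atpm]
    model@stoichiometry <- S
    model@gamATP <- gam
  }
  if (!is.null(ngam)) {
    if (ngam < 0) inputError("ngam must be >= 0")
    model <- setBounds(model, maintenanceReaction(model), lower = ngam)
  }
  methods::validObject(model)
  model
}

#' A minimal linear-chain demo model
#'
#' Uptake of an external metabolite through a transporter into a conversion
#' chain ending in a biomass reaction that consumes 10 mmol of precursor per
#' unit flux, with a free ATP maintenance drain. Used in examples and tests.
#'
#' @param uptake_bound Maximal uptake flux (default 10).
#' @return A [MetabolicModel-class].
#' @export
exampleChainModel <- function(uptake_bound = 10) {
  MetabolicModel(
    reactions = list(
      EX_a = list(stoichiometry = c(a_e = -1),
                  lower_bound = -uptake_bound, upper_bound = 0),
      T_a  = list(stoichiometry = c(a_e = -1, a = 1),
                  lower_bound = 0, upper_bound = 1000, gpr = "gT"),
      AB   = list(stoichiometry = c(a = -1, b = 1, atp = 1),
                  lower_bound = 0, upper_bound = 1000, gpr = "gAB"),
      ATPM = list(stoichiometry = c(atp = -1),
                  lower_bound = 0, upper_bound = 1000),
      BIO  = list(stoichiometry = c(b = -10, atp = -1),
                  lower_bound = 0, upper_bound = 1000)
    ),
    objective = "BIO", atp_maintenance = "ATPM"
  )
}
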