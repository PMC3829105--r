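## Comparing FVA intervals with measured (13C-derived) fluxes: the
## FVA-distance statistic and constraint-perturbation experiments.

#' Measured flux set
#'
#' Normalizes a table of measured fluxes (e.g. 13C-derived central-carbon
#' fluxes) onto model reaction ids. An optional mapping table aligns
#' measurement ids with model reactions and re-signs measured values to the
#' model's flux direction convention. Unmapped measurements are kept in the
#' `unmapped` attribute and reported, never silently dropped.
#'
#' @param fluxes data.frame with columns `reaction`, `flux` and optionally
#'   `sd`, or a named numeric vector.
#' @param mapping Optional data.frame with columns `measurement`,
#'   `model_reaction`, `sign` (+1/-1).
#' @return Named numeric vector of fluxes on model ids with attributes `sd`
#'   and `unmapped`.
#' @export
measuredFluxSet <- function(fluxes, mapping = NULL) {
  if (is.numeric(fluxes) && !is.null(names(fluxes)))
    fluxes <- data.frame(reaction = names(fluxes), flux = as.numeric(fluxes))
  fluxes <- as.data.frame(fluxes)
  sd <- if ("sd" %in% names(fluxes)) fluxes$sd else rep(NA_real_, nrow(fluxes))
  ids <- fluxes$reaction
  vals <- fluxes$flux
  unmapped <- character(0)
  if (!is.null(mapping)) {
    mapping <- as.data.frame(mapping)
    hit <- match(ids, mapping$measurement)
    unmapped <- ids[is.na(hit)]
    if (length(unmapped))
      warning("unmapped measurement(s): ", paste(unmapped, collapse = ", "))
    keep <- !is.na(hit)
    vals <- vals[keep] * mapping$sign[hit[keep]]
    sd <- sd[keep]
    ids <- mapping$model_reaction[hit[keep]]
  }
  if (anyDuplicated(ids)) inputError("duplicate measured reaction ids")
  out <- stats::setNames(vals, ids)
  attr(out, "sd") <- stats::setNames(sd, ids)
  attr(out, "unmapped") <- unmapped
  out
}

#' FVA-distance between flux intervals and measured fluxes
#'
#' For each measured reaction with flux f and FVA interval \[lo, hi\], the
#' minimal squared distance is 0 when f lies inside the interval and
#' otherwise `min((f-lo)^2, (f-hi)^2)`; the maximal squared distance is
#' `max((f-lo)^2, (f-hi)^2)`. The FVA-distance is the pair of sums over all
#' measured reactions. Intervals with an unbounded endpoint contribute
#' infinity to the maximal distance and the offending reactions are listed.
#'
#' @param fva An [FVAResult-class] covering every measured reaction.
#' @param measured A [measuredFluxSet()] (or named numeric vector).
#' @param sd_weight If `TRUE`, each reaction's contributions are divided by
#'   its squared measurement SD (requires SDs on `measured`).
#' @return An [FVADistance-class].
#' @examples
#' f <- methods::new("FVAResult", minFlux = c(R = 3), maxFlux = c(R = 4),
#'                   objectiveReaction = "BIO", objectiveValue = 1,
#'                   fixed = numeric(0))
#' fvaDistance(f, c(R = 5))  # d_min 1, d_max 4
#' @export
fvaDistance <- function(fva, measured, sd_weight = FALSE) {
  ids <- names(measured)
  missing_ids <- setdiff(ids, names(fva@minFlux))
  if (length(missing_ids))
    inputError("no FVA interval for measured reaction(s): ",
               paste(missing_ids, collapse = ", "))
  lo <- fva@minFlux[ids]
  hi <- fva@maxFlux[ids]
  f <- as.numeric(measured)
  inside <- f >= lo & f <= hi
  d_lo <- (f - lo)^2
  d_hi <- (f - hi)^2
  minc <- ifelse(inside, 0, pmin(d_lo, d_hi))
  maxc <- pmax(d_lo, d_hi)
  maxc[is.infinite(lo) | is.infinite(hi)] <- Inf
  minc[is.nan(minc)] <- Inf  # measured against an all-infinite interval
  if (sd_weight) {
    sd <- attr(measured, "sd")
    if (is.null(sd) || any(is.na(sd)) || any(sd <= 0))
      inputError("sd_weight requires positive SDs for all measurements")
    minc <- minc / sd[ids]^2
    maxc <- maxc / sd[ids]^2
  }
  methods::new("FVADistance",
    dMin = sum(minc), dMax = sum(maxc),
    perReaction = data.frame(
      reaction = ids, measured = f, lo = unname(lo), hi = unname(hi),
      minContribution = unname(minc), maxContribution = unname(maxc),
      row.names = NULL
    )
  )
}

#' Constrain one reaction to its measured flux and recompare
#'
#' Fixes a reaction's bounds to a measured value, recomputes FVA under the
#' same objective specification and reports the FVA-distance before and
#' after. Because fixing a flux only tightens the feasible set, every other
#' reaction's interval after fixing is nested inside its interval before,
#' and the fixed reaction's own contribution becomes zero.
#'
#' @param model A [MetabolicModel-class].
#' @param reaction Reaction id to constrain.
#' @param value Flux value (must lie within the reaction's current bounds).
#' @param measured A [measuredFluxSet()].
#' @param ... Passed to [fva()] (objective specification, `fixed`, ...).
#' @return List with elements `before`/`after` ([FVADistance-class]) and
#'   `fva_before`/`fva_after`.
#' @export
constrainAndCompare <- function(model, reaction, value, measured, ...) {
  lb <- lowerBounds(model); ub <- upperBounds(model)
  if (!(reaction %in% reactionIds(model)))
    inputError("unknown reaction: ", reaction)
  if (value < lb[reaction] - 1e-9 || value > ub[reaction] + 1e-9)
    inputError("value outside the reaction's original bounds")
  fva_before <- fva(model, ...)
  constrained <- setBounds(model, reaction, lower = value, upper = value)
  fva_after <- tryCatch(
    fva(constrained, ...),
    error = function(e)
      inputError("model infeasible with ", reaction, " fixed at ", value,
                 " (measurement-model conflict): ", conditionMessage(e))
  )
  list(
    before = fvaDistance(fva_before, measured),
    after = fvaDistance(fva_after, measured),
    fva_before = fva_before,
    fva_after = fva_after
  )
}

#' Read measured fluxes / mapping tables
#'
#' Tab-separated files: fluxes with columns `reaction`, `flux`, optional
#' `sd`; mapping with columns `measurement`, `model_reaction`, `sign`.
#'
#' @param path Flux table path.
#' @param mapping_path Optional mapping table path.
#' @return A [measuredFluxSet()].
#' @export
readMeasuredFluxes <- function(path, mapping_path = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  mapping <- if (!is.null(mapping_path))
    utils::read.delim(mapping_path, stringsAsFactors = FALSE) else NULL
  measuredFluxSet(df, mapping)
}
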