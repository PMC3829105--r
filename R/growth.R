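## Steady-state chemostat analytics: calibration, rates, Pirt regression,
## washout fitting and elemental balances.
##
## Unit conventions: D and mu in 1/h, concentrations in g/L (glucose feed and
## residual in mmol/L), rates in g/L/h, q_s in g_glc/gDCW/h, yields in
## gDCW/g_glc.

#' OD600-to-dry-weight calibration
#'
#' Least-squares regression of dry cell weight on optical density, forced
#' through the origin (the calibration has no blank term; blank correction of
#' direct dry-weight measurements is a separate `residue` parameter).
#'
#' @param pairs data.frame with columns `od` and `dcw` (g/L), or a
#'   two-column matrix.
#' @param residue Filter blank correction subtracted from direct dry-weight
#'   measurements (g/L).
#' @param direct_dcw_factor Dimensionless correction applied to direct
#'   dry-weight measurements (ratio of the OD calibration slope to the slope
#'   implied by the direct measurements).
#' @return A `CalibrationModel`: list with `slope` (g/L per OD unit),
#'   `r_squared`, `residue`, `direct_dcw_factor`.
#' @examples
#' calibrateOD(data.frame(od = c(1, 2), dcw = c(0.35, 0.70)))
#' @export
calibrateOD <- function(pairs, residue = 0.356,
                        direct_dcw_factor = 0.35 / 0.399) {
  pairs <- as.data.frame(pairs)
  if (!all(c("od", "dcw") %in% names(pairs)))
    names(pairs)[1:2] <- c("od", "dcw")
  if (nrow(pairs) < 2L || length(unique(pairs$od)) < 2L)
    inputError("calibration needs at least two distinct OD values")
  fit <- stats::lm(dcw ~ 0 + od, data = pairs)
  calibrationModel(slope = unname(stats::coef(fit)[["od"]]),
                   r_squared = suppressWarnings(summary(fit))$r.squared,
                   residue = residue,
                   direct_dcw_factor = direct_dcw_factor)
}

#' @rdname calibrateOD
#' @param slope Calibration slope (g/L per OD600 unit), must be positive.
#' @param r_squared Coefficient of determination of the calibration fit.
#' @export
calibrationModel <- function(slope, r_squared = NA_real_, residue = 0.356,
                             direct_dcw_factor = 0.35 / 0.399) {
  if (!is.numeric(slope) || slope <= 0)
    inputError("calibration slope must be positive")
  structure(
    list(slope = slope, r_squared = r_squared, residue = residue,
         direct_dcw_factor = direct_dcw_factor),
    class = "CalibrationModel"
  )
}

#' @export
print.CalibrationModel <- function(x, ...) {
  cat("OD600 calibration: Cx =", format(x$slope, digits = 4), "* OD600",
      if (!is.na(x$r_squared)) paste0("(r^2 = ",
                                      format(x$r_squared, digits = 4), ")"),
      "\n  residue:", x$residue, "g/L, direct-DCW factor:",
      format(x$direct_dcw_factor, digits = 4), "\n")
  invisible(x)
}

#' Corrected dry cell weight for one steady state
#'
#' Computes the dry cell weight concentration from the OD600 route
#' (`slope * OD600`), the direct route (`(Cx_raw - residue) *
#' direct_dcw_factor`), or the unweighted mean of the two when both
#' measurements are present.
#'
#' @param record List or one-row data.frame with `OD600` and/or `Cx_raw`.
#' @param cal A `CalibrationModel`.
#' @return Dry cell weight in g/L.
#' @examples
#' cal <- calibrationModel(0.35)
#' correctedDCW(list(OD600 = 2), cal)
#' @export
correctedDCW <- function(record, cal) {
  record <- as.list(record)
  od <- if ("OD600" %in% names(record)) record[["OD600"]] else NULL
  raw <- if ("Cx_raw" %in% names(record)) record[["Cx_raw"]] else NULL
  has_od <- !is.null(od) && !is.na(od)
  has_raw <- !is.null(raw) && !is.na(raw)
  if (!has_od && !has_raw)
    inputError("record needs OD600 or Cx_raw")
  vals <- c(
    if (has_od) cal$slope * od,
    if (has_raw) (raw - cal$residue) * cal$direct_dcw_factor
  )
  if (any(vals < 0))
    inputError("negative corrected dry weight; check the blank residue")
  mean(vals)
}

#' Volumetric and specific rates at steady state
#'
#' For each chemostat record computes the biomass production rate
#' `Rx = D * Cx`, glucose uptake rate `Rglc = D * (feed - residual) *
#' M_glc / 1000`, CO2 production rate from the off-gas mole-fraction
#' difference via the ideal gas law, the specific substrate uptake rate
#' `qs = Rglc / Cx` and the yield `Yxs = Rx / Rglc`.
#'
#' @param records data.frame of chemostat steady states with columns `D`
#'   (1/h), `OD600` and/or `Cx_raw`, `Cglc_feed`, `Cglc_residual` (mmol/L)
#'   and optionally `co2_offgas_fraction` (outflow-minus-inflow CO2 mole
#'   fraction), `gas_flow` (L/min), `temperature` (K), `pressure` (Pa).
#' @param cal A `CalibrationModel`; when `records` already has a `Cx` column
#'   it is used directly and `cal` may be `NULL`.
#' @param volume Culture working volume in L.
#' @param M_glc Glucose molar mass (g/mol).
#' @return `records` with columns `Cx`, `Rx`, `Rglc`, `Rco2`, `qs`, `Yxs`
#'   appended.
#' @export
steadyStateRates <- function(records, cal = NULL, volume = 0.75,
                             M_glc = fluxreconConstants$M_glc) {
  records <- as.data.frame(records)
  if (any(records$D <= 0)) inputError("dilution rates must be positive")
  if (!("Cx" %in% names(records))) {
    if (is.null(cal)) inputError("need a CalibrationModel or a Cx column")
    records[["Cx"]] <- vapply(seq_len(nrow(records)), function(i)
      correctedDCW(records[i, , drop = FALSE], cal), numeric(1))
  }
  if (any(records$Cx <= 0)) inputError("non-positive dry cell weight")
  dglc <- records$Cglc_feed - records$Cglc_residual
  if (any(dglc < 0)) inputError("residual glucose exceeds the feed")
  if (any(dglc == 0)) inputError("zero glucose consumption in some record")
  records$Rx <- records$D * records$Cx
  records$Rglc <- records$D * dglc * M_glc / 1000
  records$Rco2 <- if (is.null(records$co2_offgas_fraction)) NA_real_ else {
    temperature <- if (is.null(records$temperature)) 303.15 else
      records$temperature
    pressure <- if (is.null(records$pressure)) 101325 else records$pressure
    molar_conc <- pressure / (fluxreconConstants$R_gas * temperature)  # mol/L
    records$co2_offgas_fraction * records$gas_flow * 60 * molar_conc *
      fluxreconConstants$M_co2 / volume
  }
  records$qs <- records$Rglc / records$Cx
  records$Yxs <- records$Rx / records$Rglc
  records
}

#' Pirt regression of substrate uptake on growth rate
#'
#' Fits the linear maintenance model `qs = D / Yxs_max + ms` by ordinary
#' least squares of the specific substrate uptake rate on the dilution rate.
#' The maximal biomass yield is the inverse slope and the maintenance
#' coefficient the intercept.
#'
#' @param points data.frame with columns `D` (1/h) and `qs` (g_glc/gDCW/h).
#' @return List of class `GrowthParameters`: `Yxs_max` (gDCW/g_glc), `ms`
#'   (g_glc/gDCW/h), `r_squared`, and the underlying `fit`.
#' @examples
#' d <- data.frame(D = c(0.1, 0.2, 0.4))
#' d$qs <- d$D / 0.4 + 0.05
#' fitPirt(d)
#' @export
fitPirt <- function(points) {
  points <- as.data.frame(points)
  if (nrow(points) < 3L || length(unique(points$D)) < 3L)
    inputError("Pirt regression needs >= 3 distinct dilution rates")
  fit <- stats::lm(qs ~ D, data = points)
  slope <- unname(stats::coef(fit)[["D"]])
  if (slope <= 0)
    inputError("non-positive Pirt slope: no substrate-limited growth signal")
  structure(
    list(Yxs_max = 1 / slope,
         ms = unname(stats::coef(fit)[["(Intercept)"]]),
         r_squared = suppressWarnings(summary(fit))$r.squared,
         fit = fit),
    class = "GrowthParameters"
  )
}

#' @export
print.GrowthParameters <- function(x, ...) {
  cat("Pirt growth parameters:\n",
      " Yxs_max =", format(x$Yxs_max, digits = 4), "gDCW/g_glc\n",
      " ms      =", format(x$ms, digits = 4), "g_glc/gDCW/h\n",
      " r^2     =", format(x$r_squared, digits = 4), "\n")
  invisible(x)
}

#' Maximal growth rate from a washout experiment
#'
#' During washout (D > mu_max) the cell density decays as
#' `Cx(t) = Cx(0) * exp((mu_max - D) * t)`. The fit is log-linear least
#' squares of `ln Cx` on time; `mu_max` is the slope plus D.
#'
#' @param series data.frame with columns `t` (h) and `Cx` (g/L, positive).
#' @param D Dilution rate during the washout (1/h).
#' @return List with `mu_max` (1/h), `slope`, `r_squared`, `fit`.
#' @examples
#' s <- data.frame(t = 0:3)
#' s$Cx <- exp(-0.61 * s$t)
#' fitWashout(s, D = 1.2)$mu_max  # 0.59
#' @export
fitWashout <- function(series, D) {
  series <- as.data.frame(series)
  if (nrow(series) < 3L) inputError("washout fit needs >= 3 time points")
  if (any(series$Cx <= 0)) inputError("non-positive cell density")
  fit <- stats::lm(log(Cx) ~ t, data = series)
  slope <- unname(stats::coef(fit)[["t"]])
  list(mu_max = slope + D, slope = slope,
       r_squared = suppressWarnings(summary(fit))$r.squared, fit = fit)
}

#' Carbon and nitrogen mass fractions of biomass from culture balances
#'
#' The carbon fraction per record is the difference between carbon inflow (as
#' glucose consumed) and carbon outflow (as CO2) in g_C/L/h, divided by the
#' biomass production rate; the nitrogen fraction is the ammonium-nitrogen
#' consumed divided by the cell density. Records are balanced individually
#' and averaged.
#'
#' @param records data.frame as returned by [steadyStateRates()], with
#'   `NH4_feed`/`NH4_residual` (g_N/L) for the nitrogen balance.
#' @return List with `carbon_frac`, `nitrogen_frac` (mass fractions, NA when
#'   the inputs lack the needed columns) and the `per_record` breakdown.
#' @export
elementBalance <- function(records) {
  records <- as.data.frame(records)
  if (any(records$Rx <= 0)) inputError("non-positive biomass production rate")
  C_atom <- fluxreconConstants$atomic_masses[["C"]]
  carbon <- rep(NA_real_, nrow(records))
  if (!is.null(records$Rco2) && !all(is.na(records$Rco2))) {
    C_in <- records$D * (records$Cglc_feed - records$Cglc_residual) / 1000 *
      6 * C_atom                                    # g_C/L/h from glucose
    C_out <- records$Rco2 * C_atom / fluxreconConstants$M_co2
    carbon <- (C_in - C_out) / records$Rx
  }
  nitrogen <- rep(NA_real_, nrow(records))
  if (!is.null(records$NH4_feed) && !is.null(records$NH4_residual))
    nitrogen <- (records$NH4_feed - records$NH4_residual) / records$Cx
  list(carbon_frac = mean(carbon), nitrogen_frac = mean(nitrogen),
       per_record = data.frame(D = records$D, carbon_frac = carbon,
                               nitrogen_frac = nitrogen))
}

#' Read a chemostat steady-state table
#'
#' Tab-separated file, one row per steady state, columns named as in
#' [steadyStateRates()].
#'
#' @param path File path.
#' @return data.frame.
#' @export
readChemostatTable <- function(path) {
  if (!file.exists(path)) inputError("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!("D" %in% names(df))) inputError("chemostat table needs a 'D' column")
  if (any(df$D <= 0)) inputError("dilution rates must be positive")
  df
}
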