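## Seeded synthetic-data generators. Defaults reproduce the study
## conditions of the chemostat dataset the package is designed around:
## glucose-limited growth at D = 0.05-0.5/h on 10 mM glucose feed,
## Yxs_max = 0.397 gDCW/g, ms = 0.037 g/gDCW/h, mu_max = 0.59/h,
## GAM = 85 mmol ATP/gDCW, NGAM = 3.96 mmol ATP/gDCW/h, P:O = 1.33.
## Every generator is a pure function of (arguments, seed); concentration
## noise is multiplicative log-normal-style (positivity), expression noise
## additive on the log2 scale.

#' Simulate steady-state chemostat records
#'
#' Inverts the Pirt relation `qs = D / Yxs_max + ms` to generate consistent
#' steady states: full glucose consumption (carbon limitation), cell density
#' from the realized yield, OD600 and raw dry-weight channels consistent
#' with the package's calibration constants, and off-gas CO2 from the carbon
#' balance at a set biomass carbon fraction.
#'
#' @param Yxs_max,ms,mu_max True growth parameters.
#' @param D Dilution rates (1/h), all below `mu_max`.
#' @param feed_glc Feed glucose (mmol/L).
#' @param biomass_carbon,biomass_nitrogen Carbon/nitrogen mass fractions of
#'   biomass used for the gas and ammonium balances.
#' @param sigma Multiplicative noise SD applied to the measurement channels
#'   (OD600, raw dry weight, off-gas CO2); 0 gives exact Pirt data.
#' @param seed RNG seed (the generators never touch global RNG state).
#' @param cal Calibration constants used to back-compute the OD and raw
#'   dry-weight channels.
#' @param volume,gas_flow,temperature,pressure Culture and off-gas settings.
#' @param nh4_feed Ammonium nitrogen in the feed (g N/L).
#' @return data.frame of chemostat records (one row per D).
#' @examples
#' rec <- simulateChemostat(D = c(0.1, 0.2, 0.3), sigma = 0)
#' fitPirt(steadyStateRates(rec, calibrationModel(0.35)))
#' @export
simulateChemostat <- function(Yxs_max = 0.397, ms = 0.037, mu_max = 0.59,
                              D = seq(0.05, 0.5, by = 0.05),
                              feed_glc = 10,
                              biomass_carbon = 0.488,
                              biomass_nitrogen = 0.143,
                              sigma = 0, seed = 1,
                              cal = calibrationModel(0.35),
                              volume = 0.75, gas_flow = 0.75,
                              temperature = 303.15, pressure = 101325,
                              nh4_feed = 1.0) {
  if (any(D >= mu_max))
    inputError("steady state requires D < mu_max for every record")
  if (any(D <= 0) || sigma < 0) inputError("invalid simulation spec")
  M_glc <- fluxreconConstants$M_glc
  C_atom <- fluxreconConstants$atomic_masses[["C"]]
  withSeed(seed, {
    qs <- D / Yxs_max + ms                    # g_glc/gDCW/h
    consumed <- feed_glc * M_glc / 1000       # g/L, full consumption
    Yxs <- D / qs
    Cx <- Yxs * consumed                      # gDCW/L
    Rx <- D * Cx
    C_in <- D * feed_glc / 1000 * 6 * C_atom  # g_C/L/h
    Rco2 <- (C_in - Rx * biomass_carbon) *
      fluxreconConstants$M_co2 / C_atom       # g/L/h
    molar_conc <- pressure / (fluxreconConstants$R_gas * temperature)
    frac <- Rco2 * volume /
      (gas_flow * 60 * molar_conc * fluxreconConstants$M_co2)
    noisy <- function(x) x * exp(stats::rnorm(length(x), 0, sigma))
    data.frame(
      D = D,
      OD600 = noisy(Cx / cal$slope),
      Cx_raw = noisy(Cx / cal$direct_dcw_factor + cal$residue),
      Cglc_feed = feed_glc,
      Cglc_residual = 0,
      NH4_feed = nh4_feed,
      NH4_residual = nh4_feed - Cx * biomass_nitrogen,
      co2_offgas_fraction = noisy(frac),
      gas_flow = gas_flow,
      temperature = temperature,
      pressure = pressure
    )
  })
}

#' Simulate a washout decay series
#'
#' `Cx(t) = Cx0 * exp((mu_max - D) * t)` with optional multiplicative noise.
#'
#' @param mu_max True maximal growth rate (1/h).
#' @param D Dilution rate during washout; must exceed `mu_max`.
#' @param Cx0 Initial cell density (g/L, positive).
#' @param times Sampling times (h).
#' @param sigma Multiplicative noise SD.
#' @param seed RNG seed.
#' @return data.frame with columns `t`, `Cx`.
#' @export
simulateWashout <- function(mu_max = 0.59, D = 1.2, Cx0 = 1,
                            times = seq(0, 3, length.out = 10),
                            sigma = 0, seed = 1) {
  if (D <= mu_max) inputError("washout requires D > mu_max")
  if (Cx0 <= 0) inputError("Cx0 must be positive")
  withSeed(seed, {
    Cx <- Cx0 * exp((mu_max - D) * times) *
      exp(stats::rnorm(length(times), 0, sigma))
    data.frame(t = times, Cx = Cx)
  })
}

#' Toy central-carbon network of a glucose-grown pseudomonad
#'
#' A fixed ~20-reaction single-compartment network: glucose uptake, an
#' optional periplasmic gluconate loop (direct glucose oxidation with
#' electrons to the quinone pool and gluconate re-entry via the
#' Entner-Doudoroff route), lumped EMP- and ED-style glycolysis variants,
#' pyruvate dehydrogenase, a lumped TCA cycle, electron transport with
#' ATP:NADH stoichiometry equal to the P:O ratio, an ATP maintenance drain,
#' and a biomass reaction whose precursor demands are derived from an
#' assembled [BiomassEquation-class]: pyruvate supplies biomass carbon
#' (1/3 mmol per mmol C), ammonia supplies nitrogen, and a reducing-power
#' demand represents anabolic NADPH. Every enzymatic reaction carries a GPR
#' over synthetic genes, including an isozyme pair (glucose transport) and
#' enzyme complexes (glycolysis, pyruvate dehydrogenase).
#'
#' @param p_to_o P:O ratio (ATP per NADH or quinol oxidized).
#' @param gam,ngam Maintenance parameters (mmol ATP/gDCW, mmol ATP/gDCW/h).
#' @param include_gluconate_loop Include the periplasmic oxidation branch.
#' @param biomass A [BiomassEquation-class] supplying the elemental demands;
#'   defaults to the assembled KT2440 equation (its own GAM term is ignored;
#'   `gam` is used).
#' @param nadph_demand Anabolic reducing-power demand (mmol/gDCW).
#' @param glc_uptake_bound Maximal glucose uptake (mmol/gDCW/h).
#' @return A [MetabolicModel-class] that grows by FBA.
#' @examples
#' m <- toyModel()
#' fba(m)
#' @export
toyModel <- function(p_to_o = 1.33, gam = 85, ngam = 3.96,
                     include_gluconate_loop = TRUE,
                     biomass = NULL, nadph_demand = 5,
                     glc_uptake_bound = 10) {
  if (p_to_o < 0 || gam < 0 || ngam < 0)
    inputError("p_to_o, gam and ngam must be >= 0")
  if (is.null(biomass)) biomass <- buildPutidaBiomass(gam = 0)
  elem <- elementalComposition(biomass)
  am <- fluxreconConstants$atomic_masses
  pyr_demand <- elem[["C"]] / 100 * 1000 / am[["C"]] / 3   # mmol pyruvate/g
  nh3_demand <- elem[["N"]] / 100 * 1000 / am[["N"]]       # mmol N/g
  d <- p_to_o
  rxns <- list(
    EX_glc = list(stoichiometry = c(glc_e = -1),
                  lower_bound = -glc_uptake_bound, upper_bound = 0),
    EX_o2 = list(stoichiometry = c(o2_e = -1),
                 lower_bound = -1000, upper_bound = 0),
    EX_co2 = list(stoichiometry = c(co2_e = -1),
                  lower_bound = 0, upper_bound = 1000),
    EX_nh4 = list(stoichiometry = c(nh4_e = -1),
                  lower_bound = -1000, upper_bound = 0),
    GLCt = list(stoichiometry = c(glc_e = -1, glc = 1),
                lower_bound = 0, upper_bound = 1000,
                gpr = "gUP1 or gUP2"),
    O2t = list(stoichiometry = c(o2_e = -1, o2 = 1),
               lower_bound = 0, upper_bound = 1000, gpr = "gO2T"),
    CO2t = list(stoichiometry = c(co2 = -1, co2_e = 1),
                lower_bound = 0, upper_bound = 1000),
    NH4t = list(stoichiometry = c(nh4_e = -1, nh3 = 1),
                lower_bound = 0, upper_bound = 1000, gpr = "gNH1"),
    EMP = list(stoichiometry = c(glc = -1, pyr = 2, atp = 2, nadh = 2),
               lower_bound = 0, upper_bound = 1000,
               gpr = "gPGI and gPFK"),
    ED = list(stoichiometry = c(glc = -1, pyr = 2, atp = 1, nadh = 2),
              lower_bound = 0, upper_bound = 1000,
              gpr = "gEDD and gEDA"),
    PDH = list(stoichiometry = c(pyr = -1, accoa = 1, co2 = 1, nadh = 1),
               lower_bound = 0, upper_bound = 1000,
               gpr = "gPDH1 and gPDH2"),
    TCA = list(stoichiometry = c(accoa = -1, co2 = 2, nadh = 3, fadh2 = 1,
                                 atp = 1),
               lower_bound = 0, upper_bound = 1000, gpr = "gTCA"),
    NADH_ETC = list(stoichiometry = c(nadh = -1, o2 = -0.5, atp = d),
                    lower_bound = 0, upper_bound = 1000, gpr = "gNUO"),
    FADH_ETC = list(stoichiometry = c(fadh2 = -1, o2 = -0.5, atp = d),
                    lower_bound = 0, upper_bound = 1000, gpr = "gSDH"),
    ATPM = list(stoichiometry = c(atp = -1),
                lower_bound = ngam, upper_bound = 1000),
    BIOMASS = list(stoichiometry = c(
      pyr = -pyr_demand, nh3 = -nh3_demand,
      atp = -gam, nadh = -nadph_demand),
      lower_bound = 0, upper_bound = 1000)
  )
  if (gam == 0) rxns$BIOMASS$stoichiometry <-
    rxns$BIOMASS$stoichiometry[names(rxns$BIOMASS$stoichiometry) != "atp"]
  if (include_gluconate_loop) {
    rxns <- c(rxns, list(
      EX_glcn = list(stoichiometry = c(glcn_e = -1),
                     lower_bound = 0, upper_bound = 1000),
      GDH = list(stoichiometry = c(glc_e = -1, glcn_e = 1, fadh2 = 1),
                 lower_bound = 0, upper_bound = 1000, gpr = "gGDH"),
      GLCNt = list(stoichiometry = c(glcn_e = -1, glcn = 1),
                   lower_bound = 0, upper_bound = 1000, gpr = "gGNT"),
      EDD_GLCN = list(stoichiometry = c(glcn = -1, pyr = 2, nadh = 1),
                      lower_bound = 0, upper_bound = 1000,
                      gpr = "gEDD and gEDA")
    ))
  }
  mets <- c(glc_e = "C6H12O6", glc = "C6H12O6",
            glcn_e = "C6H12O7", glcn = "C6H12O7",
            o2_e = "O2", o2 = "O2", co2_e = "CO2", co2 = "CO2",
            nh4_e = "NH3", nh3 = "NH3", pyr = "C3H4O3",
            accoa = "", nadh = "", fadh2 = "", atp = "")
  if (!include_gluconate_loop)
    mets <- mets[!(names(mets) %in% c("glcn_e", "glcn"))]
  MetabolicModel(rxns, metabolites = mets,
                 objective = "BIOMASS", atp_maintenance = "ATPM",
                 gam = gam)
}

#' Simulate a measured flux set from a model
#'
#' Solves the growth condition by FBA (glucose uptake minimized at a fixed
#' growth rate), selects the central-metabolism reactions and adds seeded
#' Gaussian noise, emulating the role of 13C-derived flux measurements.
#'
#' @param model A [MetabolicModel-class].
#' @param mu Growth rate at which fluxes are measured (1/h).
#' @param reactions Reactions reported by the measurement; defaults to the
#'   toy network's central-carbon set present in the model.
#' @param sigma Additive Gaussian noise SD (mmol/gDCW/h).
#' @param seed RNG seed.
#' @param glucose_reaction Glucose exchange id.
#' @return A [measuredFluxSet()].
#' @export
simulateMeasuredFluxes <- function(model, mu = 0.2, reactions = NULL,
                                   sigma = 0, seed = 1,
                                   glucose_reaction = "EX_glc") {
  if (is.null(reactions)) {
    central <- c("EMP", "ED", "PDH", "TCA", "NADH_ETC", "FADH_ETC", "GLCt")
    reactions <- intersect(central, reactionIds(model))
  }
  sol <- fba(model, objective = glucose_reaction, sense = "max",
             fixed = stats::setNames(mu, objectiveReaction(model)))
  if (solverStatus(sol) != "optimal")
    inputError("infeasible measurement condition (mu = ", mu, ")")
  withSeed(seed, {
    f <- fluxes(sol)[reactions] + stats::rnorm(length(reactions), 0, sigma)
    measuredFluxSet(stats::setNames(f, reactions))
  })
}

#' Simulate a four-array expression dataset with planted signals
#'
#' Background genes draw log2 values from Normal(9, 0.5) with "P" calls;
#' planted not-expressed genes from Normal(6.5, 0.3) with "A" calls; planted
#' highly expressed genes from Normal(11, 0.3) with "P" calls.
#'
#' @param model A [MetabolicModel-class] supplying the gene universe.
#' @param planted_not_expressed,planted_high Character vectors of model
#'   genes to plant.
#' @param n_arrays Number of arrays (default 4).
#' @param seed RNG seed.
#' @return An [ExpressionDataset-class].
#' @export
simulateExpression <- function(model, planted_not_expressed = character(0),
                               planted_high = character(0), n_arrays = 4,
                               seed = 1) {
  genes <- geneIds(model)
  unknown <- setdiff(c(planted_not_expressed, planted_high), genes)
  if (length(unknown))
    inputError("planted gene(s) not in model: ",
               paste(unknown, collapse = ", "))
  withSeed(seed, {
    log2m <- matrix(stats::rnorm(length(genes) * n_arrays, 9, 0.5),
                    length(genes), n_arrays,
                    dimnames = list(genes, paste0("array", seq_len(n_arrays))))
    callm <- matrix("P", length(genes), n_arrays,
                    dimnames = dimnames(log2m))
    if (length(planted_not_expressed)) {
      log2m[planted_not_expressed, ] <-
        stats::rnorm(length(planted_not_expressed) * n_arrays, 6.5, 0.3)
      callm[planted_not_expressed, ] <- "A"
    }
    if (length(planted_high)) {
      log2m[planted_high, ] <-
        stats::rnorm(length(planted_high) * n_arrays, 11, 0.3)
    }
    ExpressionDataset(log2m, callm)
  })
}
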