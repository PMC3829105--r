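## End-to-end reconciliation pipeline: growth fits -> biomass equation ->
## maintenance fit -> FVA concordance -> transcriptomics checks, with a
## structured JSON report.

#' Pipeline configuration
#'
#' Builds a complete configuration for [runPipeline()], merging user
#' settings over documented defaults. Every threshold and constant used by
#' the run is recorded explicitly in the report (no silent defaults). Input
#' tables may be given as file paths; any input left `NULL` is generated by
#' the package's seeded simulators at the configured truth values.
#'
#' @param ... Named overrides of the default settings (see Details).
#' @param config_file Optional YAML file of overrides (applied under `...`).
#' @details Settings: `seed`; chemostat truth `Yxs_max`, `ms`, `mu_max`,
#'   `D`, `feed_glc`, `sigma`; `washout_D`; paths `chemostat_file`,
#'   `washout_file`, `expression_file`, `fluxes_file`, `model_file`;
#'   constants `M_glc`, `y_atp`, `p_to_o`, `gc`; toy-model `nadph_demand`,
#'   `include_gluconate_loop`; condition `mu_condition`; thresholds
#'   `expr_lt`, `flux_lt`, `expr_high` (`NA` = dataset mean);
#'   `growth_threshold` for essentiality; planted sets
#'   `planted_not_expressed`, `planted_high`; `constrain_reaction` for the
#'   perturbation experiment; `out_dir` (`NULL` = no files written).
#' @return List of class `PipelineConfig`.
#' @export
pipelineConfig <- function(..., config_file = NULL) {
  defaults <- list(
    seed = 1,
    Yxs_max = 0.397, ms = 0.037, mu_max = 0.59,
    D = seq(0.05, 0.5, by = 0.05), feed_glc = 10, sigma = 0,
    washout_D = 1.2,
    chemostat_file = NULL, washout_file = NULL, expression_file = NULL,
    fluxes_file = NULL, model_file = NULL,
    M_glc = fluxreconConstants$M_glc, y_atp = 19.25, p_to_o = 1.33,
    gc = 0.615, nadph_demand = 5, include_gluconate_loop = TRUE,
    mu_condition = 0.2,
    expr_lt = 7.5, flux_lt = 0.1, expr_high = NA_real_,
    growth_threshold = 0.01,
    planted_not_expressed = c("gGDH", "gGNT"),
    planted_high = c("gEDD", "gEDA"),
    constrain_reaction = "TCA",
    out_dir = NULL
  )
  overrides <- list(...)
  if (!is.null(config_file)) {
    from_file <- yaml::read_yaml(config_file)
    overrides <- utils::modifyList(from_file, overrides)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    inputError("unknown config setting(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides, keep.null = TRUE)
  for (f in c("chemostat_file", "washout_file", "expression_file",
              "fluxes_file", "model_file")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      inputError("configured file does not exist: ", cfg[[f]])
  }
  if (cfg$expr_lt <= 0 || cfg$flux_lt <= 0)
    inputError("thresholds must be positive")
  structure(cfg, class = c("PipelineConfig", "list"))
}

#' Run the reconciliation pipeline
#'
#' Executes the full chain: chemostat rates and Pirt fit, washout fit,
#' biomass-equation assembly, NGAM from the fitted maintenance coefficient,
#' GAM fitted on the (toy) model against the fitted maximal yield, FVA at
#' the growth condition, FVA-distance against the measured flux set, a
#' constraint-perturbation comparison, and the three transcriptomics
#' consistency assessments. Each stage failure aborts with a stage-tagged
#' error. With `out_dir` set, writes `report.json`, `params.json`,
#' `fva.tsv` and `omics_report.tsv`.
#'
#' @param config A [pipelineConfig()] (or arguments for it as a list).
#' @return The report as a list (invisibly also written to disk when
#'   configured).
#' @examples
#' rep <- runPipeline(pipelineConfig(sigma = 0, seed = 1))
#' rep$growth$Yxs_max
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (!inherits(config, "PipelineConfig"))
    config <- do.call(pipelineConfig, as.list(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- config$seed
  cal <- calibrationModel(0.35)

  records <- stage("chemostat", {
    if (!is.null(config$chemostat_file)) readChemostatTable(config$chemostat_file)
    else simulateChemostat(Yxs_max = config$Yxs_max, ms = config$ms,
                           mu_max = config$mu_max, D = config$D,
                           feed_glc = config$feed_glc, sigma = config$sigma,
                           seed = seed)
  })
  rates <- stage("rates", steadyStateRates(records, cal, M_glc = config$M_glc))
  pirt <- stage("pirt", fitPirt(rates))
  balance <- stage("balance", elementBalance(rates))

  washout_series <- stage("washout", {
    if (!is.null(config$washout_file))
      utils::read.delim(config$washout_file)
    else simulateWashout(mu_max = config$mu_max, D = config$washout_D,
                         sigma = config$sigma, seed = seed + 1)
  })
  washout <- stage("washout", fitWashout(washout_series, D = config$washout_D))

  biomass <- stage("biomass", buildPutidaBiomass(gam = 0, gc = config$gc))
  elem <- stage("biomass", elementalComposition(biomass))

  ngam <- stage("maintenance",
                computeNGAM(pirt$ms, y_atp = config$y_atp,
                            M_glc = config$M_glc))
  model <- stage("model", {
    if (!is.null(config$model_file)) readMetabolicModel(config$model_file)
    else toyModel(p_to_o = config$p_to_o, gam = 0, ngam = 0,
                  include_gluconate_loop = config$include_gluconate_loop,
                  biomass = biomass, nadph_demand = config$nadph_demand)
  })
  gam_fit <- stage("maintenance", fitGAM(model, pirt$Yxs_max,
                                         M_glc = config$M_glc))
  model <- stage("maintenance", setMaintenance(gam_fit$model, ngam = ngam))
  y_atp_model <- stage("maintenance", computeYatp(model))

  mu <- config$mu_condition
  glc_min <- stage("fva", fba(model, objective = "EX_glc", sense = "max",
                              fixed = c(BIOMASS = mu)))
  fva_res <- stage("fva", fva(model, objective = "EX_glc",
                              objectiveValue = objectiveValue(glc_min),
                              fixed = c(BIOMASS = mu)))
  measured <- stage("fluxes", {
    if (!is.null(config$fluxes_file)) readMeasuredFluxes(config$fluxes_file)
    else simulateMeasuredFluxes(model, mu = mu, sigma = config$sigma,
                                seed = seed + 2)
  })
  dist <- stage("concordance", fvaDistance(fva_res, measured))
  ## the perturbation experiment uses the wider biomass-fixed solution
  ## space (glucose free within its bound) so a noisy measured value can
  ## be imposed; an infeasible fix is reported as a conflict, not an abort
  perturb <- stage("concordance", {
    r <- config$constrain_reaction
    if (!is.null(r) && r %in% names(measured)) {
      tryCatch({
        cc <- constrainAndCompare(model, r, measured[[r]], measured,
                                  objective = "BIOMASS",
                                  objectiveValue = mu)
        list(reaction = r, value = measured[[r]],
             before = c(d_min = cc$before@dMin, d_max = cc$before@dMax),
             after = c(d_min = cc$after@dMin, d_max = cc$after@dMax))
      }, error = function(e)
        list(reaction = r, value = measured[[r]],
             conflict = conditionMessage(e)))
    } else NULL
  })

  essentials <- stage("omics", essentialGenes(model, config$growth_threshold))
  expr_ds <- stage("omics", {
    if (!is.null(config$expression_file))
      readExpressionTable(config$expression_file)
    else simulateExpression(model,
                            planted_not_expressed = config$planted_not_expressed,
                            planted_high = config$planted_high,
                            seed = seed + 3)
  })
  expr_high <- if (is.na(config$expr_high)) mean(exprValues(expr_ds))
               else config$expr_high
  omics <- stage("omics",
                 consistencyReport(model, expr_ds, fva_res,
                                   essentials = essentials,
                                   expr_lt = config$expr_lt,
                                   flux_lt = config$flux_lt,
                                   expr_high = expr_high))

  input_files <- Filter(Negate(is.null),
                        config[c("chemostat_file", "washout_file",
                                 "expression_file", "fluxes_file",
                                 "model_file")])
  report <- list(
    schema_version = "1.0",
    provenance = list(
      package_version = as.character(utils::packageVersion("fluxrecon")),
      r_version = as.character(getRversion()),
      seed = seed,
      input_hashes = if (length(input_files))
        as.list(tools::md5sum(unlist(input_files))) else list(),
      timestamp = format(Sys.time(), tz = "UTC")
    ),
    config = unclass(config)[setdiff(names(config), "out_dir")],
    growth = list(
      Yxs_max = pirt$Yxs_max, ms = pirt$ms, r_squared = pirt$r_squared,
      mu_max = washout$mu_max, washout_r_squared = washout$r_squared,
      carbon_frac = balance$carbon_frac,
      nitrogen_frac = balance$nitrogen_frac
    ),
    biomass = list(
      mass_per_flux_g = biomassMass(biomass),
      elemental_composition = as.list(elem)
    ),
    maintenance = list(
      gam = gam_fit$gam, ngam = ngam, yxs_max_achieved = gam_fit$yxs_max,
      y_atp_config = config$y_atp, y_atp_model = y_atp_model
    ),
    concordance = list(
      d_min = dist@dMin, d_max = dist@dMax,
      n_measured = nrow(dist@perReaction),
      perturbation = perturb
    ),
    omics = list(
      n_essential = length(essentials),
      essential = essentials,
      essential_not_expressed = omics$essential_not_expressed$genes,
      low_expr_required_reactions = omics$low_expr_required_reactions,
      high_expr_zero_flux_genes = omics$high_expr_zero_flux_genes,
      thresholds = omics$thresholds
    )
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    jsonlite::write_json(c(report$growth, report$maintenance),
                         file.path(config$out_dir, "params.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(fluxIntervals(fva_res),
                       file.path(config$out_dir, "fva.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    om <- data.frame(
      section = c(
        rep("essential_not_expressed",
            length(report$omics$essential_not_expressed)),
        rep("low_expr_required_reaction",
            length(report$omics$low_expr_required_reactions)),
        rep("high_expr_zero_flux",
            length(report$omics$high_expr_zero_flux_genes))
      ),
      id = c(report$omics$essential_not_expressed,
             report$omics$low_expr_required_reactions,
             report$omics$high_expr_zero_flux_genes)
    )
    utils::write.table(om, file.path(config$out_dir, "omics_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
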