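mkDS <- function(means, calls_str, n_arrays = 4) {
  genes <- names(means)
  log2m <- matrix(rep(means, n_arrays), length(genes), n_arrays,
                  dimnames = list(genes, paste0("a", seq_len(n_arrays))))
  callm <- do.call(rbind, lapply(calls_str, function(s)
    strsplit(s, "")[[1]]))
  dimnames(callm) <- dimnames(log2m)
  ExpressionDataset(log2m, callm)
}

test_that("not-expressed flagging applies the three criteria exactly", {
  ds <- mkDS(c(g1 = 9.0, g2 = 7.4, g3 = 9.0, g4 = 6.0),
             c("AAAP", "PPPP", "PPPP", "AAMP"))
  flags <- flagNotExpressed(ds)
  ## 3 absent calls (>2) and 1 present call (<3), but mean 9.0
  expect_setequal(flags$g1, c("absent_calls", "present_calls"))
  ## all present, mean just below 7.5
  expect_identical(flags$g2, "low_mean")
  ## clean gene: no criteria
  expect_length(flags$g3, 0)
  ## marginal calls count as neither present nor absent:
  ## 2 absent (not >2), 2 present (<3), mean 6.0
  expect_setequal(flags$g4, c("present_calls", "low_mean"))

  expect_error(flagNotExpressed(ds, absent_gt = 4), "inconsistent")
})

test_that("flagging criteria are monotone in their thresholds", {
  withr::with_seed(3, {
    means <- stats::setNames(runif(30, 5, 11), paste0("g", 1:30))
  })
  ds <- mkDS(means, rep("PPPP", 30))
  flagged_at <- function(cut) {
    f <- flagNotExpressed(ds, mean_lt = cut)
    names(f)[lengths(f) > 0]
  }
  f1 <- flagged_at(7.0); f2 <- flagged_at(7.5); f3 <- flagged_at(9.0)
  expect_true(all(f1 %in% f2))
  expect_true(all(f2 %in% f3))
})

test_that("essential-not-expressed is a reported intersection", {
  ds <- mkDS(c(g1 = 9, g2 = 6, g3 = 6), c("PPPP", "AAAA", "AAAA"))
  flags <- flagNotExpressed(ds)
  rep <- essentialNotExpressed(c("g1", "g2"), flags)
  expect_identical(rep$genes, "g2")
  expect_identical(rep$multi_criteria, "g2")  # calls + mean criteria
  expect_length(essentialNotExpressed("g1", flags)$genes, 0)
  expect_warning(essentialNotExpressed(character(0), flags), "empty")
})

test_that("planted non-expressed essential genes are recovered exactly", {
  m <- toyModel()
  ess <- essentialGenes(m)
  planted <- ess[1:2]
  ds <- simulateExpression(m, planted_not_expressed = planted, seed = 3)
  flags <- flagNotExpressed(ds)
  rep <- essentialNotExpressed(ess, flags)
  expect_setequal(rep$genes, planted)
})

test_that("reaction expression follows the GPR algebra", {
  m <- MetabolicModel(
    reactions = list(
      ISO = list(stoichiometry = c(a = -1), lower_bound = 0,
                 upper_bound = 1, gpr = "g1 or g2"),
      CPLX = list(stoichiometry = c(a = -1), lower_bound = 0,
                  upper_bound = 1, gpr = "g1 and g3"),
      ONE = list(stoichiometry = c(a = 1), lower_bound = 0,
                 upper_bound = 1, gpr = "g1"),
      SPONT = list(stoichiometry = c(a = 1), lower_bound = 0,
                   upper_bound = 1),
      MISS = list(stoichiometry = c(a = 1), lower_bound = 0,
                  upper_bound = 1, gpr = "g4")
    ),
    objective = "ONE", atp_maintenance = "ONE"
  )
  ds <- mkDS(c(g1 = 7.0, g2 = 7.2, g3 = 9.0), rep("PPPP", 3))
  expect_warning(re <- reactionExpression(m, ds), "unevaluable")
  expect_equal(re[["ISO"]], 7.2)    # isozymes: max, still below 7.5
  expect_equal(re[["CPLX"]], 7.0)   # complex: min
  expect_equal(re[["ONE"]], 7.0)
  expect_true(is.na(re[["SPONT"]]))
  expect_identical(attr(re, "unevaluable"), "MISS")

  ## invariance to re-parenthesization / operand order
  m2 <- MetabolicModel(
    reactions = list(
      R1 = list(stoichiometry = c(a = -1), lower_bound = 0, upper_bound = 1,
                gpr = "(g1 or g2) or g3"),
      R2 = list(stoichiometry = c(a = -1), lower_bound = 0, upper_bound = 1,
                gpr = "g3 or (g2 or g1)")
    ),
    objective = "R1", atp_maintenance = "R1"
  )
  re2 <- reactionExpression(m2, ds)
  expect_equal(re2[["R1"]], re2[["R2"]])
})

test_that("required reactions with low expression are identified", {
  f <- methods::new("FVAResult",
                    minFlux = c(A = 0.5, B = 0, C = 0.4, D = -2),
                    maxFlux = c(A = 2, B = 3, C = 1, D = -0.5),
                    objectiveReaction = "BIO", objectiveValue = 1,
                    fixed = numeric(0))
  expr <- c(A = 7.0, B = 6.0, C = 9.0, D = 7.2)
  hits <- lowExprRequiredReactions(f, expr, expr_lt = 7.5)
  ## A: required and low; B: zero min flux; C: required but expressed;
  ## D: reversible, always carries |flux| >= 0.5, low expression
  expect_setequal(hits, c("A", "D"))
})

test_that("highly expressed genes on low-flux reactions are recovered", {
  m <- toyModel()
  mu <- 0.2
  glc_min <- fba(m, objective = "EX_glc", sense = "max",
                 fixed = c(BIOMASS = mu))
  f <- fva(m, objective = "EX_glc",
           objectiveValue = objectiveValue(glc_min),
           fixed = c(BIOMASS = mu))
  planted <- c("gEDD", "gEDA")  # ED variant carries no flux at optimum
  ds <- simulateExpression(m, planted_high = planted, seed = 11)
  hits <- highExprZeroFlux(ds, m, f, flux_lt = 0.1, expr_high = 10.5)
  expect_setequal(hits, planted)
  ## a gene with one active reaction is never listed
  expect_false("gUP1" %in%
    highExprZeroFlux(ds, m, f, flux_lt = 0.1, expr_high = 8))
  ## tightening the flux threshold never grows the list
  hits_tight <- highExprZeroFlux(ds, m, f, flux_lt = 0.01,
                                 expr_high = 10.5)
  expect_true(all(hits_tight %in% hits))
  expect_error(highExprZeroFlux(ds, m, f), "expr_high")
})

test_that("the combined consistency report ties the assessments together", {
  m <- toyModel()
  ess <- essentialGenes(m)
  ds <- simulateExpression(m, planted_not_expressed = ess[1],
                           planted_high = c("gEDD", "gEDA"), seed = 7)
  mu <- 0.2
  glc_min <- fba(m, objective = "EX_glc", sense = "max",
                 fixed = c(BIOMASS = mu))
  f <- fva(m, objective = "EX_glc",
           objectiveValue = objectiveValue(glc_min),
           fixed = c(BIOMASS = mu))
  rep <- consistencyReport(m, ds, f, essentials = ess, expr_high = 10.5)
  expect_identical(rep$essential_not_expressed$genes, ess[1])
  expect_setequal(rep$high_expr_zero_flux_genes, c("gEDD", "gEDA"))
  expect_identical(rep$thresholds$expr_high, 10.5)
})

test_that("expression tables round-trip through the long TSV format", {
  ds <- simulateExpression(toyModel(), seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- expand.grid(gene = rownames(exprValues(ds)),
                    array_id = colnames(exprValues(ds)),
                    stringsAsFactors = FALSE)
  df$log2 <- exprValues(ds)[cbind(df$gene, df$array_id)]
  df$call <- exprCalls(ds)[cbind(df$gene, df$array_id)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ds2 <- readExpressionTable(path)
  expect_equal(exprValues(ds2)[rownames(exprValues(ds)), ],
               exprValues(ds), tolerance = 1e-9)
})
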