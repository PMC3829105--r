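test_that("FBA solves the linear chain in closed form", {
  m <- exampleChainModel(uptake_bound = 10)
  sol <- fba(m, objective = "BIO", sense = "max")
  expect_equal(solverStatus(sol), "optimal")
  expect_equal(objectiveValue(sol), 1.0, tolerance = 1e-9)

  ## biomass fixed at 0.2: minimal uptake scales linearly to 2
  sol2 <- fba(m, objective = "EX_a", sense = "max", fixed = c(BIO = 0.2))
  expect_equal(objectiveValue(sol2), -2.0, tolerance = 1e-9)
  expect_equal(fluxes(sol2)[["BIO"]], 0.2, tolerance = 1e-9)

  ## above the attainable maximum the problem is infeasible, never silent
  expect_equal(solverStatus(fba(m, fixed = c(BIO = 5))), "infeasible")
  ## fixed values outside the declared bounds are rejected up front
  expect_error(fba(m, fixed = c(BIO = 5000)), "outside bounds")
})

test_that("optimal flux distributions satisfy mass balance and bounds", {
  models <- list(exampleChainModel(), toyModel(), parallelRoutesModel())
  for (m in models) {
    sol <- fba(m)
    expect_equal(solverStatus(sol), "optimal")
    v <- fluxes(sol)
    imbalance <- max(abs(as.vector(stoichiometry(m) %*% v)))
    expect_lt(imbalance, 1e-6)
    expect_true(all(v >= lowerBounds(m) - 1e-6))
    expect_true(all(v <= upperBounds(m) + 1e-6))
  }
})

test_that("minimized uptake and maximized growth give reciprocal yields", {
  m <- toyModel()
  mu <- 0.2
  qmin <- fba(m, objective = "EX_glc", sense = "max", fixed = c(BIOMASS = mu))
  u <- -objectiveValue(qmin)
  vmax <- fba(m, objective = "BIOMASS", sense = "max",
              fixed = stats::setNames(-u, "EX_glc"))
  expect_equal(objectiveValue(vmax), mu, tolerance = 1e-6)
})

test_that("FVA splits flux freely between parallel equivalent routes", {
  m <- parallelRoutesModel(uptake = 10)
  res <- fva(m, objective = "BIO", objectiveValue = 10)
  iv <- fluxIntervals(res)
  for (r in c("R1", "R2")) {
    expect_equal(iv$min[iv$reaction == r], 0, tolerance = 1e-6)
    expect_equal(iv$max[iv$reaction == r], 10, tolerance = 1e-6)
  }
  ## dead-ended reaction disconnected from the objective is blocked
  expect_equal(iv$min[iv$reaction == "DEAD"], 0, tolerance = 1e-9)
  expect_equal(iv$max[iv$reaction == "DEAD"], 0, tolerance = 1e-9)
})

test_that("FVA intervals contain every brute-force basic solution", {
  m <- parallelRoutesModel(uptake = 8)
  obj_val <- 5
  res <- fva(m, objective = "BIO", objectiveValue = obj_val)
  vertices <- enumerateBasicSolutions(m, "BIO", obj_val)
  expect_gt(length(vertices), 0)
  for (v in vertices) {
    expect_true(all(v >= res@minFlux[names(v)] - 1e-6))
    expect_true(all(v <= res@maxFlux[names(v)] + 1e-6))
  }
  ## and the intervals are tight: every endpoint is attained by a vertex
  V <- do.call(rbind, vertices)
  for (r in reactionIds(m)) {
    expect_equal(min(V[, r]), res@minFlux[[r]], tolerance = 1e-6)
    expect_equal(max(V[, r]), res@maxFlux[[r]], tolerance = 1e-6)
  }
})

test_that("tightening any bound nests the FVA intervals", {
  m <- toyModel()
  mu <- 0.2
  sol <- fba(m, objective = "EX_glc", sense = "max", fixed = c(BIOMASS = mu))
  ## leave slack on glucose so intervals have width
  base <- fva(m, objective = "BIOMASS", objectiveValue = mu)
  tightened <- setBounds(m, "GDH", upper = 1)
  nested <- fva(tightened, objective = "BIOMASS", objectiveValue = mu)
  expect_true(all(nested@minFlux >= base@minFlux - 1e-6))
  expect_true(all(nested@maxFlux <= base@maxFlux + 1e-6))
})

test_that("gene deletions zero out inactive reactions only", {
  m <- toyModel()
  del <- deleteGenes(m, "gUP1")           # isozyme remains
  expect_equal(upperBounds(del)[["GLCt"]], upperBounds(m)[["GLCt"]])
  del2 <- deleteGenes(m, c("gUP1", "gUP2"))
  expect_equal(upperBounds(del2)[["GLCt"]], 0)
  expect_equal(lowerBounds(del2)[["GLCt"]], 0)
  ## spontaneous reactions are untouched
  expect_equal(upperBounds(del2)[["CO2t"]], upperBounds(m)[["CO2t"]])
  expect_error(deleteGenes(m, "nonexistent"), "unknown gene")
})

test_that("essential genes match a brute-force single-deletion oracle", {
  m <- toyModel()
  ess <- essentialGenes(m, growth_threshold = 0.01)
  wt <- objectiveValue(fba(m))
  oracle <- character(0)
  for (g in geneIds(m)) {
    gpr <- gprRules(m)
    dead <- names(gpr)[vapply(gpr, function(rule)
      nzchar(rule) && !evalGprIndependent(rule, g), logical(1))]
    md <- if (length(dead)) setBounds(m, dead, lower = 0, upper = 0) else m
    sol <- fba(md)
    if (solverStatus(sol) != "optimal" ||
        objectiveValue(sol) < 0.01 * wt) oracle <- c(oracle, g)
  }
  expect_setequal(ess, oracle)
  ## an isozyme pair on a required reaction leaves neither gene essential
  expect_false(any(c("gUP1", "gUP2") %in% ess))
})

test_that("maintenance parameters act on yield as energy drains", {
  m <- toyModel(gam = 85, ngam = 3.96)
  ## NGAM is a hard lower bound on the maintenance flux
  sol <- fba(m)
  expect_gte(fluxes(sol)[["ATPM"]], 3.96 - 1e-9)
  ## removing all maintenance strictly increases the predicted yield
  m0 <- setMaintenance(m, gam = 0, ngam = 0)
  expect_gt(objectiveValue(fba(m0)), objectiveValue(fba(m)))
  ## doubling GAM strictly increases minimal glucose demand at fixed mu
  m2 <- setMaintenance(m, gam = 170)
  u1 <- -objectiveValue(fba(m, "EX_glc", "max", fixed = c(BIOMASS = 0.2)))
  u2 <- -objectiveValue(fba(m2, "EX_glc", "max", fixed = c(BIOMASS = 0.2)))
  expect_gt(u2, u1)
  expect_error(setMaintenance(m, gam = -1), ">= 0")
  expect_error(setMaintenance(m, ngam = -1), ">= 0")
})

test_that("setMaintenance replaces rather than stacks the GAM term", {
  m <- toyModel(gam = 85)
  m2 <- setMaintenance(setMaintenance(m, gam = 40), gam = 85)
  expect_equal(as.matrix(stoichiometry(m2)), as.matrix(stoichiometry(m)),
               tolerance = 1e-12)
})
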