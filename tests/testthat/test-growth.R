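test_that("OD calibration recovers the slope through the origin", {
  cal <- calibrateOD(data.frame(od = c(1, 2), dcw = c(0.35, 0.70)))
  expect_equal(cal$slope, 0.35, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)

  k <- 0.8123
  cal2 <- calibrateOD(data.frame(od = c(0, 1), dcw = c(0, k)))
  expect_equal(cal2$slope, k, tolerance = 1e-12)

  ## noisy calibration: the true slope lies within the 95% CI
  withr::with_seed(1, {
    od <- runif(50, 0.2, 3)
    dcw <- 0.35 * od + rnorm(50, 0, 0.01)
  })
  cal3 <- calibrateOD(data.frame(od = od, dcw = dcw))
  fit <- lm(dcw ~ 0 + od)
  ci <- confint(fit, level = 0.95)
  expect_gte(0.35, ci[1]); expect_lte(0.35, ci[2])
  expect_equal(cal3$slope, unname(coef(fit)[1]), tolerance = 1e-12)

  expect_error(calibrateOD(data.frame(od = c(1, 1), dcw = c(1, 2))),
               "distinct")
})

test_that("dry-weight correction handles both measurement routes", {
  cal <- calibrationModel(0.35, residue = 0.356,
                          direct_dcw_factor = 0.35 / 0.399)
  expect_equal(correctedDCW(list(OD600 = 2.0), cal), 0.70,
               tolerance = 1e-12)
  direct <- (1.156 - 0.356) * (0.35 / 0.399)
  expect_equal(correctedDCW(list(Cx_raw = 1.156), cal), direct,
               tolerance = 1e-12)
  expect_equal(direct, 0.7018, tolerance = 1e-4)
  ## both present: unweighted mean of the two routes
  both <- correctedDCW(list(OD600 = 2.0, Cx_raw = 1.156), cal)
  expect_equal(both, (0.70 + direct) / 2, tolerance = 1e-12)
  expect_error(correctedDCW(list(Cx_raw = 0.3), cal), "negative")
  expect_error(correctedDCW(list(other = 1), cal), "OD600 or Cx_raw")
})

test_that("steady-state rates follow the defining arithmetic", {
  rec <- data.frame(D = 0.2, Cx = 0.70, Cglc_feed = 10, Cglc_residual = 0)
  r <- steadyStateRates(rec)
  expect_equal(r$Rglc, 0.2 * 10 * 180.16 / 1000, tolerance = 1e-12)
  expect_equal(r$Rglc, 0.36032, tolerance = 1e-9)
  expect_equal(r$qs, 0.36032 / 0.70, tolerance = 1e-9)
  expect_equal(r$Yxs, 0.14 / 0.36032, tolerance = 1e-9)
  expect_equal(r$Yxs, r$D / r$qs, tolerance = 1e-12)  # algebraic identity

  expect_error(
    steadyStateRates(data.frame(D = 0.2, Cx = 0.7, Cglc_feed = 10,
                                Cglc_residual = 10)),
    "zero glucose consumption")

  ## zero off-gas difference gives zero CO2 rate
  rec2 <- data.frame(D = 0.2, Cx = 0.7, Cglc_feed = 10, Cglc_residual = 0,
                     co2_offgas_fraction = 0, gas_flow = 0.75,
                     temperature = 303.15, pressure = 101325)
  expect_equal(steadyStateRates(rec2)$Rco2, 0)
})

test_that("Pirt regression inverts exactly on noise-free lines", {
  mk <- function(Yxs_max, ms, D) data.frame(D = D, qs = D / Yxs_max + ms)
  p1 <- fitPirt(mk(0.4, 0.05, c(0.1, 0.2, 0.4)))
  expect_equal(p1$Yxs_max, 0.4, tolerance = 1e-12)
  expect_equal(p1$ms, 0.05, tolerance = 1e-12)

  p2 <- fitPirt(mk(0.397, 0.037, seq(0.05, 0.5, by = 0.05)))
  expect_equal(p2$Yxs_max, 0.397, tolerance = 1e-12)
  expect_equal(p2$ms, 0.037, tolerance = 1e-12)
  expect_equal(p2$r_squared, 1, tolerance = 1e-9)

  expect_error(fitPirt(data.frame(D = c(0.1, 0.2), qs = c(1, 2))), ">= 3")
  expect_error(fitPirt(data.frame(D = c(0.1, 0.2, 0.3),
                                  qs = c(3, 2, 1))), "slope")
})

test_that("the Pirt estimator is unbiased over noisy replicates", {
  n_rep <- 200
  D <- seq(0.05, 0.5, by = 0.05)
  truth <- 0.397
  est <- withr::with_seed(42, vapply(seq_len(n_rep), function(i) {
    qs <- D / truth + 0.037 + rnorm(length(D), 0, 0.02)
    fitPirt(data.frame(D = D, qs = qs))$Yxs_max
  }, numeric(1)))
  expect_lt(abs(mean(est) - truth), 0.005)
  se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - truth), 3 * se + 0.002)
})

test_that("washout fitting recovers mu_max as slope + D", {
  s <- data.frame(t = 0:3, Cx = exp(-0.61 * (0:3)))
  w <- fitWashout(s, D = 1.2)
  expect_equal(w$mu_max, 0.59, tolerance = 1e-12)
  expect_equal(w$mu_max, w$slope + 1.2, tolerance = 1e-12)

  flat <- data.frame(t = 0:4, Cx = rep(0.8, 5))
  expect_equal(fitWashout(flat, D = 0.3)$mu_max, 0.3, tolerance = 1e-12)

  withr::with_seed(7, {
    t <- seq(0, 3, length.out = 10)
    Cx <- exp(-0.61 * t) * exp(rnorm(10, 0, 0.02))
  })
  w2 <- fitWashout(data.frame(t = t, Cx = Cx), D = 1.2)
  ci <- confint(w2$fit)["t", ] + 1.2
  expect_gte(0.59, ci[1]); expect_lte(0.59, ci[2])

  expect_error(fitWashout(data.frame(t = 0:2, Cx = c(1, 0, -1)), D = 1),
               "non-positive")
})

test_that("element balances recover biomass carbon and nitrogen content", {
  ## inflow 12 Cmmol/L/h (D = 0.2, 10 mmol/L glucose), outflow 5.7 Cmmol/L/h
  Rco2 <- 5.7 / 1000 * 44.01
  rec <- data.frame(D = 0.2, Cx = 0.7, Cglc_feed = 10, Cglc_residual = 0,
                    Rx = 0.144, Rco2 = Rco2,
                    NH4_feed = 1.0, NH4_residual = 0.9)
  bal <- elementBalance(rec)
  expect_equal(bal$carbon_frac, 6.3 * 12.011 / 144, tolerance = 1e-9)
  expect_equal(bal$carbon_frac, 0.5255, tolerance = 1e-3)
  expect_equal(bal$nitrogen_frac, 0.1 / 0.7, tolerance = 1e-12)

  ## CO2 outflow equal to carbon inflow zeroes the carbon fraction
  rec0 <- rec; rec0$Rco2 <- 12 / 1000 * 44.01
  expect_equal(elementBalance(rec0)$carbon_frac, 0, tolerance = 1e-9)
  expect_error(elementBalance(transform(rec, Rx = 0)), "non-positive")
})
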