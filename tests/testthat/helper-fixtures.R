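## Shared fixtures and independent oracles for the test suite.

## Two parallel equivalent routes from an external substrate to biomass.
parallelRoutesModel <- function(uptake = 10) {
  MetabolicModel(
    reactions = list(
      EX_a = list(stoichiometry = c(a_e = -1),
                  lower_bound = -uptake, upper_bound = 0),
      R1 = list(stoichiometry = c(a_e = -1, b = 1),
                lower_bound = 0, upper_bound = 1000, gpr = "g1"),
      R2 = list(stoichiometry = c(a_e = -1, b = 1),
                lower_bound = 0, upper_bound = 1000, gpr = "g2"),
      DEAD = list(stoichiometry = c(c = -1, d = 1),
                  lower_bound = 0, upper_bound = 1000),
      FEED_C = list(stoichiometry = c(c = 1),
                    lower_bound = 0, upper_bound = 0),
      SINK_D = list(stoichiometry = c(d = -1),
                    lower_bound = 0, upper_bound = 0),
      ATPM = list(stoichiometry = c(b = -0.001),
                  lower_bound = 0, upper_bound = 1000),
      BIO = list(stoichiometry = c(b = -1),
                 lower_bound = 0, upper_bound = 1000)
    ),
    objective = "BIO", atp_maintenance = "ATPM"
  )
}

## Brute-force FVA oracle: enumerate candidate basic solutions of
## {S v = 0, objective fixed, lb <= v <= ub} by fixing subsets of variables
## at their bounds and solving the remaining square linear system. Returns
## the feasible vertices found (independent of the simplex implementation).
enumerateBasicSolutions <- function(model, objective, objective_value,
                                    tol = 1e-8) {
  S <- as.matrix(stoichiometry(model))
  rxns <- reactionIds(model)
  obj_row <- as.numeric(rxns == objective)
  A <- rbind(S, obj_row)
  b <- c(rep(0, nrow(S)), objective_value)
  lb <- lowerBounds(model)
  ub <- upperBounds(model)
  n <- ncol(A)
  ## drop linearly dependent rows
  qrA <- qr(t(A))
  keep <- qrA$pivot[seq_len(qrA$rank)]
  A <- A[keep, , drop = FALSE]
  b <- b[keep]
  m <- nrow(A)
  stopifnot(n - m <= 6)  # fixture guard: keep enumeration cheap
  out <- list()
  for (fix_idx in utils::combn(n, n - m, simplify = FALSE)) {
    free_idx <- setdiff(seq_len(n), fix_idx)
    Af <- A[, free_idx, drop = FALSE]
    if (abs(det(Af)) < 1e-10) next
    k <- length(fix_idx)
    for (mask in seq_len(2^k) - 1L) {
      at_ub <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
      vfix <- ifelse(at_ub, ub[fix_idx], lb[fix_idx])
      rhs <- b - as.vector(A[, fix_idx, drop = FALSE] %*% vfix)
      vfree <- solve(Af, rhs)
      v <- numeric(n)
      v[fix_idx] <- vfix
      v[free_idx] <- vfree
      if (all(v >= lb - tol) && all(v <= ub + tol)) {
        names(v) <- rxns
        out[[length(out) + 1L]] <- v
      }
    }
  }
  out
}

## Independent GPR evaluation: rewrite and/or to R operators and eval().
evalGprIndependent <- function(gpr, deleted) {
  if (!nzchar(trimws(gpr))) return(TRUE)
  expr <- gsub("\\band\\b", "&&", gsub("\\bor\\b", "||", gpr,
                                       ignore.case = TRUE),
               ignore.case = TRUE)
  genes <- unique(regmatches(gpr,
    gregexpr("[A-Za-z_][A-Za-z0-9_]*", gpr))[[1]])
  genes <- setdiff(genes, c("and", "or", "AND", "OR"))
  env <- new.env()
  for (g in genes) assign(g, !(g %in% deleted), envir = env)
  eval(parse(text = expr), envir = env)
}

## Closed-form maximal growth of the toy network under EMP-only operation
## (ATP-limited regime): derived by hand from the fixed toy stoichiometry.
## Per glucose: EMP gives 2 pyr + 2 ATP + 2 NADH; each burned pyruvate gives
## 1 ATP (TCA substrate-level) + 4 NADH + 1 FADH2; the electron transport
## converts NADH/FADH2 at delta = P:O. Biomass consumes p pyruvate, r NADH
## and (gam) ATP per gram. ATP balance at uptake u with maintenance ngam:
##   u (4 + 12 d) = v (gam + p (1 + 5 d) + d r) + ngam
## valid while burned pyruvate b = 2u - p v >= 0.
toyClosedFormGrowth <- function(u = 10, p_to_o = 1.33, gam = 85,
                                ngam = 3.96, pyr_demand, nadph_demand = 5) {
  d <- p_to_o
  v_atp <- (u * (4 + 12 * d) - ngam) /
    (gam + pyr_demand * (1 + 5 * d) + d * nadph_demand)
  v_carbon <- 2 * u / pyr_demand
  min(v_atp, v_carbon)
}

## Biomass precursor demands used by the toy network (mirrors toyModel()).
toyPyrDemand <- function() {
  eq <- buildPutidaBiomass(gam = 0)
  el <- elementalComposition(eq)
  el[["C"]] / 100 * 1000 / 12.011 / 3
}
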