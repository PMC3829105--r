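## A dense bounded-variable primal simplex with Bland's anti-cycling rule.
##
## Solves  max/min c'x  s.t.  A x = b,  l <= x <= u  (all bounds finite).
## Two phases: phase 1 drives signed artificial variables to zero, phase 2
## optimizes the true objective with the artificials clamped at zero.
## Written for the small, often degenerate LPs of flux balance analysis,
## where termination and deterministic behaviour matter more than speed;
## problem sizes here are tens of variables, so the dense O(m^3) basis
## solve per iteration is immaterial.

boundedSimplex <- function(obj, A, b, lb, ub, maximize = TRUE,
                           tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n,
            length(b) == m, all(is.finite(lb)), all(is.finite(ub)))
  if (any(lb > ub)) return(list(status = "infeasible"))
  if (!maximize) {
    res <- boundedSimplex(-obj, A, b, lb, ub, TRUE, tol, max_iter)
    if (res$status == "optimal") res$value <- -res$value
    return(res)
  }
  ## start structural variables at the bound of smaller magnitude
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  at_upper <- abs(lb) > abs(ub)
  r <- b - as.vector(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  ## extended problem: n structural + m artificial columns
  Ae <- cbind(A, diag(sgn, m))
  N <- n + m
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))
  xe <- c(x, abs(r))
  at_up <- c(at_upper, rep(FALSE, m))
  basis <- (n + 1L):N
  in_basis <- c(rep(FALSE, n), rep(TRUE, m))

  iterate <- function(costs, xe, at_up, basis, in_basis, lbe, ube) {
    for (it in seq_len(max_iter)) {
      B <- Ae[, basis, drop = FALSE]
      Binv <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Binv)) return(NULL)  # singular basis: numerical failure
      y <- as.vector(crossprod(Binv, costs[basis]))   # duals
      nonbasic <- which(!in_basis)
      d <- costs[nonbasic] - as.vector(y %*% Ae[, nonbasic, drop = FALSE])
      enter_ok <- (!at_up[nonbasic] & d > tol) | (at_up[nonbasic] & d < -tol)
      if (!any(enter_ok))
        return(list(xe = xe, at_up = at_up, basis = basis,
                    in_basis = in_basis, iters = it))
      j <- nonbasic[enter_ok][which.min(nonbasic[enter_ok])]  # Bland
      increasing <- !at_up[j]
      w <- as.vector(Binv %*% Ae[, j])
      if (!increasing) w <- -w
      ## entering variable moves by delta >= 0; basic vars change by -w*delta
      delta <- ube[j] - lbe[j]
      leave <- 0L
      for (k in seq_along(basis)) {
        i <- basis[k]
        if (w[k] > tol) {
          lim <- (xe[i] - lbe[i]) / w[k]
        } else if (w[k] < -tol) {
          lim <- (ube[i] - xe[i]) / (-w[k])
        } else next
        if (lim < delta - tol || (lim < delta + tol &&
                                  (leave == 0L || i < basis[leave]))) {
          delta <- min(delta, lim)
          leave <- k
        }
      }
      if (!is.finite(delta)) return(list(unbounded = TRUE))
      delta <- max(delta, 0)
      xe[basis] <- xe[basis] - w * delta
      xe[j] <- xe[j] + (if (increasing) delta else -delta)
      if (leave == 0L) {
        at_up[j] <- !at_up[j]  # bound flip, basis unchanged
      } else {
        out <- basis[leave]
        ## leaving variable lands on the bound it hit
        hit_lower <- w[leave] > 0
        xe[out] <- if (hit_lower) lbe[out] else ube[out]
        at_up[out] <- !hit_lower
        in_basis[out] <- FALSE
        basis[leave] <- j
        in_basis[j] <- TRUE
        at_up[j] <- FALSE
      }
    }
    NULL  # iteration limit
  }

  ## phase 1: maximize -(sum of artificials)
  costs1 <- c(rep(0, n), rep(-1, m))
  ph1 <- iterate(costs1, xe, at_up, basis, in_basis, lbe, ube)
  if (is.null(ph1) || isTRUE(ph1$unbounded))
    stop("LP phase-1 failure (numerical)")
  if (sum(ph1$xe[(n + 1L):N]) > 1e-7) return(list(status = "infeasible"))
  ## phase 2: clamp artificials to zero, optimize the true objective
  ube[(n + 1L):N] <- 0
  xe <- ph1$xe
  xe[(n + 1L):N] <- pmax(0, pmin(xe[(n + 1L):N], 0))
  costs2 <- c(obj, rep(0, m))
  ph2 <- iterate(costs2, xe, ph1$at_up, ph1$basis, ph1$in_basis, lbe, ube)
  if (is.null(ph2)) stop("LP phase-2 failure (numerical)")
  if (isTRUE(ph2$unbounded)) return(list(status = "unbounded"))
  x <- ph2$xe[seq_len(n)]
  list(status = "optimal", x = x, value = sum(obj * x))
}
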