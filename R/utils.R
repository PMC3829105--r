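## Shared constants and small helpers.

#' Physical and chemical constants used across the package
#'
#' Molar masses in g/mol, gas constant in J/(mol K). The glucose molar mass is
#' the anhydrous free-sugar value (180.16 g/mol); it is an argument everywhere
#' it enters a computation so other conventions can be supplied.
#'
#' @format A named list with elements `M_glc`, `M_co2`, `R_gas` and
#'   `atomic_masses` (named vector for C, H, N, O, P, S).
#' @export
fluxreconConstants <- list(
  M_glc = 180.16,
  M_co2 = 44.01,
  R_gas = 8.314462,
  atomic_masses = c(
    C = 12.011, H = 1.008, N = 14.007,
    O = 15.999, P = 30.974, S = 32.06
  )
)

## Run expr with a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv()),
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Parse an elemental formula
#'
#' Parses a Hill-style elemental formula such as `"C6H12O6"` into a named
#' vector of atom counts. Only element symbols with an optional integer count
#' are supported (no isotopes, charges or parentheses).
#'
#' @param formula Character scalar, e.g. `"C10H12N5O6P"`.
#' @return Named numeric vector of atom counts.
#' @examples
#' parseFormula("C6H12O6")
#' @export
parseFormula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  f <- gsub("\\s", "", formula)
  if (!nzchar(f)) return(stats::setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  if (sum(nchar(parts)) != nchar(f))
    stop("cannot parse formula: ", formula)
  elems <- sub("[0-9]*$", "", parts)
  counts <- as.numeric(ifelse(grepl("[0-9]+$", parts),
                              sub("^[A-Za-z]+", "", parts), "1"))
  tapply(counts, elems, sum)[unique(elems)]
}

#' Molar mass of an elemental formula
#'
#' @param formula Character scalar formula (see [parseFormula()]).
#' @param atomic_masses Named vector of atomic masses (g/mol).
#' @return Molar mass in g/mol.
#' @examples
#' formulaMass("C6H12O6")
#' @export
formulaMass <- function(formula,
                        atomic_masses = fluxreconConstants$atomic_masses) {
  counts <- parseFormula(formula)
  if (length(counts) == 0L) return(0)
  unknown <- setdiff(names(counts), names(atomic_masses))
  if (length(unknown))
    stop("no atomic mass for element(s): ", paste(unknown, collapse = ", "))
  sum(counts * atomic_masses[names(counts)])
}

## sum of per-element atom counts scaled by coefficients, as a named vector
sumFormulas <- function(formulas, coefs) {
  acc <- numeric(0)
  for (i in seq_along(formulas)) {
    cnt <- parseFormula(formulas[[i]])
    for (el in names(cnt)) {
      acc[el] <- (if (el %in% names(acc)) acc[[el]] else 0) +
        coefs[[i]] * cnt[[el]]
    }
  }
  acc
}

## stop() with a consistent prefix for user input problems
inputError <- function(...) stop(..., call. = FALSE)
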