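## Transcriptomics-model consistency checks: flagging potentially
## non-expressed genes, low-expression reactions required for growth, and
## highly expressed genes confined to zero-flux reactions.

#' Construct an ExpressionDataset
#'
#' @param log2 Numeric matrix of log2 expression values, genes x arrays.
#' @param calls Character matrix of detection calls ("P"/"A"/"M"), same
#'   dimensions.
#' @return An [ExpressionDataset-class].
#' @examples
#' ds <- ExpressionDataset(
#'   log2 = matrix(9, 1, 4, dimnames = list("g1", paste0("a", 1:4))),
#'   calls = matrix("P", 1, 4, dimnames = list("g1", paste0("a", 1:4)))
#' )
#' @export
ExpressionDataset <- function(log2, calls) {
  stopifnot(identical(dim(log2), dim(calls)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = log2, calls = calls)
  )
  methods::as(se, "ExpressionDataset")
}

#' @rdname ExpressionDataset
#' @param x An `ExpressionDataset`.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "log2")

#' @rdname ExpressionDataset
#' @export
exprCalls <- function(x) SummarizedExperiment::assay(x, "calls")

#' @rdname ExpressionDataset
#' @export
geneMeans <- function(x) rowMeans(exprValues(x))

#' Flag genes as potentially not expressed
#'
#' A gene is flagged when it meets at least one of three criteria: (i) more
#' than `absent_gt` "absent" calls, (ii) fewer than `present_lt` "present"
#' calls, or (iii) a mean log2 expression below `mean_lt`. Marginal ("M")
#' calls count as neither present nor absent.
#'
#' @param ds An [ExpressionDataset-class].
#' @param absent_gt Absent-call count threshold (criterion fires when the
#'   count is strictly greater; default 2 of 4 arrays).
#' @param present_lt Present-call count threshold (fires when strictly
#'   lower; default 3 of 4 arrays).
#' @param mean_lt Mean log2 expression threshold (fires when strictly
#'   lower; default 7.5).
#' @return Named list per gene of the criteria that fired (subset of
#'   `"absent_calls"`, `"present_calls"`, `"low_mean"`); genes with an empty
#'   vector are not flagged.
#' @export
flagNotExpressed <- function(ds, absent_gt = 2, present_lt = 3,
                             mean_lt = 7.5) {
  calls <- exprCalls(ds)
  n_arrays <- ncol(calls)
  if (absent_gt >= n_arrays || present_lt > n_arrays)
    inputError("call thresholds inconsistent with ", n_arrays, " arrays")
  n_absent <- rowSums(calls == "A")
  n_present <- rowSums(calls == "P")
  means <- geneMeans(ds)
  genes <- rownames(calls)
  out <- lapply(seq_along(genes), function(i) {
    c(if (n_absent[i] > absent_gt) "absent_calls",
      if (n_present[i] < present_lt) "present_calls",
      if (means[i] < mean_lt) "low_mean")
  })
  stats::setNames(out, genes)
}

#' Essential genes that appear not to be expressed
#'
#' Intersects a set of in-silico essential genes with the genes flagged by
#' [flagNotExpressed()], reporting per gene the criteria that fired and the
#' subset meeting at least two criteria.
#'
#' @param essentials Character vector of essential gene ids.
#' @param flags Result of [flagNotExpressed()].
#' @return List with `genes` (flagged essential genes), `criteria` (named
#'   list of fired criteria) and `multi_criteria` (genes with >= 2
#'   criteria).
#' @export
essentialNotExpressed <- function(essentials, flags) {
  if (!length(essentials))
    warning("empty essential gene set")
  flagged <- names(flags)[lengths(flags) > 0]
  hits <- intersect(essentials, flagged)
  crit <- flags[hits]
  list(
    genes = hits,
    criteria = crit,
    multi_criteria = names(crit)[lengths(crit) >= 2]
  )
}

#' Reaction-level expression values from GPR rules
#'
#' Aggregates per-gene mean log2 expression onto reactions through the GPR
#' algebra: OR (isozymes) takes the maximum of its operands, AND (complex
#' subunits) the minimum. Spontaneous reactions get no value; reactions
#' whose rule references genes missing from the dataset are marked
#' unevaluable and listed in the `unevaluable` attribute.
#'
#' @param model A [MetabolicModel-class].
#' @param ds An [ExpressionDataset-class].
#' @return Named numeric vector of reaction expression values (NA for
#'   spontaneous/unevaluable reactions) with attribute `unevaluable`.
#' @export
reactionExpression <- function(model, ds) {
  means <- geneMeans(ds)
  gpr <- gprRules(model)
  evalTree <- function(node) {
    switch(node$op,
      gene = {
        if (!(node$gene %in% names(means))) NA_real_
        else means[[node$gene]]
      },
      and = min(vapply(node$args, evalTree, numeric(1))),
      or = max(vapply(node$args, evalTree, numeric(1)))
    )
  }
  out <- vapply(gpr, function(g) {
    if (!nzchar(g)) return(NA_real_)
    evalTree(gprParse(g))
  }, numeric(1))
  unevaluable <- names(gpr)[nzchar(gpr) & is.na(out)]
  if (length(unevaluable))
    warning("reaction(s) unevaluable (genes missing from dataset): ",
            paste(unevaluable, collapse = ", "))
  attr(out, "unevaluable") <- unevaluable
  out
}

#' Low-expression reactions required for optimal growth
#'
#' Identifies reactions that must carry flux at the growth condition
#' (non-zero minimal absolute flux in the FVA result, beyond a numerical
#' epsilon) yet have a reaction expression value below the threshold.
#'
#' @param fva An [FVAResult-class] computed at the growth condition.
#' @param rxn_expr Reaction expression values from [reactionExpression()].
#' @param expr_lt Expression threshold (default log2 = 7.5).
#' @param eps Numerical zero for "non-zero minimal flux" (default 1e-9).
#' @return Character vector of reaction ids.
#' @export
lowExprRequiredReactions <- function(fva, rxn_expr, expr_lt = 7.5,
                                     eps = 1e-9) {
  ids <- names(fva@minFlux)
  ## minimal |flux| over the interval: 0 if the interval spans zero
  min_abs <- pmin(abs(fva@minFlux), abs(fva@maxFlux))
  min_abs[fva@minFlux <= 0 & fva@maxFlux >= 0] <- 0
  required <- ids[min_abs > eps]
  expr <- rxn_expr[required]
  required[!is.na(expr) & expr < expr_lt]
}

#' Highly expressed genes confined to low-flux reactions
#'
#' Finds genes with mean expression at or above `expr_high` all of whose
#' associated reactions have a maximal absolute flux below `flux_lt` in the
#' FVA result (computed, by the package's convention, at mu = 0.2/h). Genes
#' with no associated reactions are skipped with a notice.
#'
#' @param ds An [ExpressionDataset-class].
#' @param model A [MetabolicModel-class].
#' @param fva An [FVAResult-class] at the growth condition.
#' @param flux_lt Low-flux threshold in mmol/gDCW/h (default 0.1).
#' @param expr_high High-expression threshold (log2); no universal default
#'   exists, a dataset-level summary such as the overall mean is a sensible
#'   explicit choice.
#' @return Character vector of gene ids.
#' @export
highExprZeroFlux <- function(ds, model, fva, flux_lt = 0.1, expr_high) {
  if (missing(expr_high)) inputError("expr_high must be given explicitly")
  means <- geneMeans(ds)
  gpr <- gprRules(model)
  max_abs <- pmax(abs(fva@minFlux), abs(fva@maxFlux))
  gene2rxn <- list()
  for (r in names(gpr)) {
    for (g in gprGenes(gpr[[r]]))
      gene2rxn[[g]] <- c(gene2rxn[[g]], r)
  }
  candidates <- names(means)[means >= expr_high]
  no_rxn <- setdiff(candidates, names(gene2rxn))
  no_rxn <- intersect(no_rxn, geneIds(model))
  if (length(no_rxn))
    message("gene(s) with no associated reactions skipped: ",
            paste(no_rxn, collapse = ", "))
  hits <- vapply(candidates, function(g) {
    rxns <- gene2rxn[[g]]
    length(rxns) > 0 && all(max_abs[rxns] < flux_lt)
  }, logical(1))
  candidates[hits]
}

#' Full transcriptomics-model consistency report
#'
#' Runs the three consistency assessments against one expression dataset and
#' one FVA result: essential-but-not-expressed genes, low-expression
#' reactions with obligatory flux, and highly expressed genes confined to
#' low-flux reactions.
#'
#' @inheritParams highExprZeroFlux
#' @param essentials Character vector of essential genes (computed via
#'   [essentialGenes()] when omitted).
#' @param expr_lt Low-expression threshold for assessments i-ii.
#' @return List of class `ConsistencyReport`.
#' @export
consistencyReport <- function(model, ds, fva, essentials = NULL,
                              expr_lt = 7.5, flux_lt = 0.1, expr_high) {
  if (is.null(essentials)) essentials <- essentialGenes(model)
  flags <- flagNotExpressed(ds, mean_lt = expr_lt)
  rxn_expr <- reactionExpression(model, ds)
  structure(
    list(
      essential_not_expressed = essentialNotExpressed(essentials, flags),
      low_expr_required_reactions =
        lowExprRequiredReactions(fva, rxn_expr, expr_lt = expr_lt),
      high_expr_zero_flux_genes =
        highExprZeroFlux(ds, model, fva, flux_lt = flux_lt,
                         expr_high = expr_high),
      thresholds = list(expr_lt = expr_lt, flux_lt = flux_lt,
                        expr_high = expr_high)
    ),
    class = "ConsistencyReport"
  )
}

#' @export
print.ConsistencyReport <- function(x, ...) {
  cat("Transcriptomics-model consistency report\n")
  cat("  essential, potentially not expressed:",
      length(x$essential_not_expressed$genes), "gene(s)\n")
  cat("  required reactions with low expression:",
      length(x$low_expr_required_reactions), "reaction(s)\n")
  cat("  highly expressed genes at low flux:",
      length(x$high_expr_zero_flux_genes), "gene(s)\n")
  invisible(x)
}

#' Read an expression table
#'
#' Long-format TSV with columns `gene`, `array_id`, `log2`, `call`.
#'
#' @param path File path.
#' @return An [ExpressionDataset-class].
#' @export
readExpressionTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "array_id", "log2", "call")
  if (!all(need %in% names(df)))
    inputError("expression table needs columns: ",
               paste(need, collapse = ", "))
  genes <- unique(df$gene)
  arrays <- unique(df$array_id)
  log2m <- matrix(NA_real_, length(genes), length(arrays),
                  dimnames = list(genes, arrays))
  callm <- matrix(NA_character_, length(genes), length(arrays),
                  dimnames = list(genes, arrays))
  log2m[cbind(df$gene, df$array_id)] <- df$log2
  callm[cbind(df$gene, df$array_id)] <- df$call
  if (anyNA(log2m) || anyNA(callm))
    inputError("expression table is not complete over genes x arrays")
  ExpressionDataset(log2m, callm)
}
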