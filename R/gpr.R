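## Gene-protein-reaction (GPR) boolean rules.
##
## Grammar (case-insensitive keywords, genome-scale-model convention):
##   expr   := term ("or" term)*
##   term   := factor ("and" factor)*
##   factor := gene | "(" expr ")"
## No negation. The empty rule denotes a spontaneous reaction (always active).

gprTokenize <- function(gpr) {
  s <- gsub("([()])", " \\1 ", gpr)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

## Recursive-descent parse into nested lists: list(op = "and"/"or"/"gene", ...)
gprParse <- function(gpr) {
  toks <- gprTokenize(gpr)
  if (!length(toks)) return(NULL)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  advance <- function() { tok <- toks[[pos]]; pos <<- pos + 1L; tok }
  parseExpr <- function() {
    node <- parseTerm()
    args <- list(node)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args <- c(args, list(parseTerm()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parseTerm <- function() {
    node <- parseFactor()
    args <- list(node)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args <- c(args, list(parseFactor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parseFactor <- function() {
    tok <- peek()
    if (is.na(tok)) inputError("malformed GPR (unexpected end): ", gpr)
    if (tok == "(") {
      advance()
      node <- parseExpr()
      if (is.na(peek()) || peek() != ")")
        inputError("malformed GPR (missing ')'): ", gpr)
      advance()
      return(node)
    }
    if (tok == ")" || tolower(tok) %in% c("and", "or"))
      inputError("malformed GPR (unexpected '", tok, "'): ", gpr)
    advance()
    list(op = "gene", gene = tok)
  }
  tree <- parseExpr()
  if (pos <= length(toks))
    inputError("malformed GPR (trailing tokens): ", gpr)
  tree
}

#' Genes referenced by a GPR rule
#'
#' @param gpr GPR expression string (may be empty).
#' @return Character vector of gene identifiers (unique, in order of first use).
#' @examples
#' gprGenes("(g1 and g2) or g3")
#' @export
gprGenes <- function(gpr) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(character(0))
  toks <- gprTokenize(gpr)
  unique(toks[!(tolower(toks) %in% c("and", "or")) & !(toks %in% c("(", ")"))])
}

evalGprTree <- function(node, present) {
  switch(node$op,
    gene = isTRUE(present[[node$gene]]) || !(node$gene %in% names(present)),
    and  = all(vapply(node$args, evalGprTree, logical(1), present = present)),
    or   = any(vapply(node$args, evalGprTree, logical(1), present = present))
  )
}

#' Evaluate a GPR rule under a set of gene deletions
#'
#' AND operands model enzyme-complex subunits (all required), OR operands
#' model isozymes (any one suffices). An empty rule denotes a spontaneous or
#' unannotated reaction and always evaluates active.
#'
#' @param gpr GPR expression string.
#' @param deleted Character vector of deleted gene ids.
#' @return `TRUE` if the reaction retains catalytic capability.
#' @examples
#' evaluateGPR("(g1 and g2) or g3", deleted = "g3")  # TRUE
#' evaluateGPR("(g1 and g2) or g3", deleted = c("g1", "g3"))  # FALSE
#' @export
evaluateGPR <- function(gpr, deleted = character(0)) {
  tree <- gprParse(gpr)
  if (is.null(tree)) return(TRUE)
  genes <- gprGenes(gpr)
  present <- stats::setNames(!(genes %in% deleted), genes)
  evalGprTree(tree, as.list(present))
}
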