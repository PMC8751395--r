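# Gene-protein-reaction (GPR) rules: boolean expressions over gene ids with
# case-insensitive AND/OR and parentheses (no NOT). An empty rule means the
# reaction is not gene-associated (spontaneous or unannotated) and is
# unaffected by gene deletions.

.gprTokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

# Recursive-descent parser. Grammar:
#   expr   := term ( OR term )*
#   term   := factor ( AND factor )*
#   factor := gene | "(" expr ")"
# Returns a nested list: list(op = "and"/"or", args = list(...)) or a gene id
# character scalar at the leaves; NULL for an empty rule.
.gprParse <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- .gprTokenize(rule)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }
  expect <- function(what) {
    if (is.na(peek()) || peek() != what)
      stop("malformed GPR rule ", sQuote(rule), ": expected ", sQuote(what),
           call. = FALSE)
    advance()
  }
  parseFactor <- function() {
    t <- peek()
    if (is.na(t))
      stop("malformed GPR rule ", sQuote(rule), ": unexpected end",
           call. = FALSE)
    if (t == "(") {
      advance()
      e <- parseExpr()
      expect(")")
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("malformed GPR rule ", sQuote(rule), ": unexpected ", sQuote(t),
           call. = FALSE)
    advance()
    t
  }
  parseTerm <- function() {
    args <- list(parseFactor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args <- c(args, list(parseFactor()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parseExpr <- function() {
    args <- list(parseTerm())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args <- c(args, list(parseTerm()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  ast <- parseExpr()
  if (!is.na(peek()))
    stop("malformed GPR rule ", sQuote(rule), ": trailing ", sQuote(peek()),
         call. = FALSE)
  ast
}

.gprEvalAst <- function(ast, alive) {
  if (is.null(ast)) return(TRUE)
  if (is.character(ast)) return(alive(ast))
  vals <- vapply(ast$args, .gprEvalAst, logical(1), alive = alive)
  if (ast$op == "and") all(vals) else any(vals)
}

#' Evaluate a GPR rule under a set of gene deletions
#'
#' Determines whether a reaction remains catalysable when the listed genes
#' are deleted. AND encodes an enzyme complex (all subunits required), OR
#' encodes isoenzymes (any suffices). An empty rule always evaluates to TRUE.
#'
#' @param rule GPR rule string, e.g. \code{"(g1 and g2) or g3"}.
#' @param deletedGenes character vector of deleted gene ids.
#' @return logical scalar: TRUE if the reaction can still be catalysed.
#' @examples
#' evaluateGpr("(g1 and g2) or g3", "g1")        # TRUE (isoenzyme g3)
#' evaluateGpr("(g1 and g2) or g3", c("g1", "g3"))  # FALSE
#' evaluateGpr("", "g1")                          # TRUE (no gene association)
#' @export
evaluateGpr <- function(rule, deletedGenes = character()) {
  ast <- .gprParse(rule)
  .gprEvalAst(ast, function(g) !(g %in% deletedGenes))
}

#' Genes referenced by a GPR rule
#'
#' @param rule GPR rule string.
#' @return character vector of distinct gene ids (empty for an empty rule).
#' @export
gprGenes <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule)))
    return(character())
  toks <- .gprTokenize(rule)
  unique(toks[!(tolower(toks) %in% c("and", "or")) & toks != "(" & toks != ")"])
}

# Aggregate a per-gene numeric value over a GPR: OR takes the max of its
# operands (isoenzymes add capacity), AND the min (a complex is limited by
# its scarcest subunit). Genes absent from `values` contribute `missing`.
.gprAggregate <- function(rule, values, missing = NA_real_) {
  ast <- .gprParse(rule)
  if (is.null(ast)) return(NA_real_)
  rec <- function(node) {
    if (is.character(node)) {
      v <- values[node]
      if (is.na(v)) missing else unname(v)
    } else {
      vals <- vapply(node$args, rec, numeric(1))
      if (node$op == "and") min(vals) else max(vals)
    }
  }
  rec(ast)
}
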