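# Boolean gene-protein-reaction (GPR) rules: "and" means all gene products
# are required, "or" means any suffices. Rules are stored as strings and
# parsed on demand into an expression tree (used for SBML export and the
# optional gene-level knockout mode).

#' Parse a gene rule into an expression tree
#'
#' Grammar: `expr := term (or term)*`, `term := factor (and factor)*`,
#' `factor := gene | ( expr )`. Operators are case-insensitive.
#'
#' @param rule gene rule string; the empty string yields `NULL`
#'   (orphan/diffusion reaction).
#' @return `NULL`, a gene token (character), or a list
#'   `list(op = "and"/"or", args = list(...))`.
#' @export
parse_gene_rule <- function(rule) {
  rule <- trimws(rule)
  if (!nzchar(rule)) return(NULL)
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance(); args <- c(args, list(parse_term()))
    }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance(); args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed gene rule: ", rule)
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (is.na(peek()) || peek() != ")") stop("unbalanced parentheses in gene rule: ", rule)
      advance()
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("malformed gene rule: ", rule)
    advance()
  }
  out <- parse_expr()
  if (pos <= length(toks)) stop("trailing tokens in gene rule: ", rule)
  out
}

#' Genes referenced by a gene rule
#' @param rule gene rule string.
#' @return character vector of unique gene tokens (empty for empty rule).
#' @export
gene_rule_genes <- function(rule) {
  tree <- parse_gene_rule(rule)
  collect <- function(node) {
    if (is.null(node)) return(character(0))
    if (is.character(node)) return(node)
    unlist(lapply(node$args, collect))
  }
  unique(collect(tree))
}

#' Evaluate a gene rule given a set of knocked-out genes
#'
#' @param rule gene rule string; empty rules evaluate to `TRUE` (no gene
#'   requirement).
#' @param knocked_out character vector of deleted gene tokens.
#' @return `TRUE` if the reaction can still be catalysed.
#' @export
evaluate_gene_rule <- function(rule, knocked_out) {
  tree <- parse_gene_rule(rule)
  evl <- function(node) {
    if (is.null(node)) return(TRUE)
    if (is.character(node)) return(!(node %in% knocked_out))
    vals <- vapply(node$args, evl, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  evl(tree)
}
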