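# Gene-protein-reaction (GPR) rule parsing and evaluation.
#
# Grammar (case-insensitive): expr := term ("or" term)*
#                             term := factor ("and" factor)*
#                             factor := gene-id | "(" expr ")"
# "and" binds tighter than "or", the standard GPR convention (AND = complex
# subunits that are all required, OR = isoenzymes that substitute).

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean gene association string such as `"g1 and (g2 or g3)"`
#' into an expression tree. `and`/`or` are case-insensitive and `and` binds
#' tighter than `or`. An empty or all-whitespace rule returns `NULL`
#' (the reaction is not gene-associated).
#'
#' @param rule character scalar, possibly empty.
#' @return a nested list tree with nodes `list(op = "and"|"or", args = ...)`
#'   and leaves `list(op = "gene", id = ...)`, or `NULL` for an empty rule.
#' @export
parse_gene_rule <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  tokens <- .gpr_tokenize(rule)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  tree <- .gpr_expr(state)
  if (state$pos <= length(state$tokens)) {
    stop("malformed gene rule near '", state$tokens[state$pos], "' in: ", rule,
         call. = FALSE)
  }
  tree
}

.gpr_tokenize <- function(rule) {
  rule <- gsub("\\(", " ( ", rule)
  rule <- gsub("\\)", " ) ", rule)
  tokens <- strsplit(trimws(rule), "\\s+")[[1]]
  if (length(tokens) == 0L) stop("empty gene rule", call. = FALSE)
  tokens
}

.gpr_peek <- function(state) {
  if (state$pos > length(state$tokens)) NA_character_ else state$tokens[state$pos]
}

.gpr_expr <- function(state) {
  args <- list(.gpr_term(state))
  while (!is.na(tok <- .gpr_peek(state)) && tolower(tok) == "or") {
    state$pos <- state$pos + 1L
    args[[length(args) + 1L]] <- .gpr_term(state)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

.gpr_term <- function(state) {
  args <- list(.gpr_factor(state))
  while (!is.na(tok <- .gpr_peek(state)) && tolower(tok) == "and") {
    state$pos <- state$pos + 1L
    args[[length(args) + 1L]] <- .gpr_factor(state)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

.gpr_factor <- function(state) {
  tok <- .gpr_peek(state)
  if (is.na(tok)) stop("unexpected end of gene rule", call. = FALSE)
  state$pos <- state$pos + 1L
  if (tok == "(") {
    inner <- .gpr_expr(state)
    if (is.na(.gpr_peek(state)) || .gpr_peek(state) != ")") {
      stop("unbalanced parentheses in gene rule", call. = FALSE)
    }
    state$pos <- state$pos + 1L
    return(inner)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop("malformed gene rule near '", tok, "'", call. = FALSE)
  }
  list(op = "gene", id = tok)
}

#' Evaluate a parsed gene rule against a set of deleted genes
#'
#' Genes mentioned in the rule but absent from `deleted` are treated as
#' present (conservative: an unknown gene never switches a reaction off).
#' A `NULL` tree (empty rule) always evaluates `TRUE`.
#'
#' @param tree parsed rule from [parse_gene_rule()].
#' @param deleted character vector of deleted gene ids.
#' @return logical: does the reaction retain enzymatic support?
#' @export
eval_gene_rule <- function(tree, deleted = character()) {
  if (is.null(tree)) return(TRUE)
  switch(tree$op,
    gene = !(tree$id %in% deleted),
    and  = all(vapply(tree$args, eval_gene_rule, logical(1), deleted = deleted)),
    or   = any(vapply(tree$args, eval_gene_rule, logical(1), deleted = deleted)),
    stop("invalid gene-rule node: ", tree$op, call. = FALSE)
  )
}

#' List the genes appearing in a parsed gene rule
#'
#' @param tree parsed rule from [parse_gene_rule()] (or `NULL`).
#' @return character vector of unique gene ids (empty for `NULL`).
#' @export
rule_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (tree$op == "gene") return(tree$id)
  unique(unlist(lapply(tree$args, rule_genes)))
}

# Render a parsed rule back to its canonical string form.
.gpr_deparse <- function(tree) {
  if (is.null(tree)) return("")
  if (tree$op == "gene") return(tree$id)
  parts <- vapply(tree$args, function(a) {
    s <- .gpr_deparse(a)
    if (tree$op == "and" && !is.null(a$op) && a$op == "or") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}
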