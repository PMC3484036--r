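# Gene-protein-reaction (GPR) rules: boolean expressions over gene ids with
# `and` (enzyme complex) and `or` (isozymes). One recursive-descent parser
# feeds two evaluators: a boolean one (knockout semantics) and a numeric one
# (AND = min, OR = max) used to map expression levels onto reactions.

gpr_tokenize <- function(rule) {
  s <- gsub("\\(", " ( ", rule)
  s <- gsub("\\)", " ) ", s)
  s <- gsub("&&|&", " and ", s)
  s <- gsub("\\|\\||\\|", " or ", s)
  tokens <- strsplit(trimws(s), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

#' Parse a gene-protein-reaction rule
#'
#' @param rule A GPR string such as `"(g1 and g2) or g3"`. `and`/`or` are
#'   case-insensitive; `&`/`|` are accepted as synonyms. An empty or `NA`
#'   rule denotes a non-genetic reaction.
#' @return A parse tree: `NULL` for the empty rule, a character scalar for a
#'   single gene, otherwise nested lists with elements `op` (`"and"`/`"or"`)
#'   and `args`.
#' @export
parse_gene_rule <- function(rule) {
  if (is.null(rule) || length(rule) == 0L || is.na(rule) || !nzchar(trimws(rule))) {
    return(NULL)
  }
  tokens <- gpr_tokenize(rule)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NA_character_
  advance <- function() {
    tok <- peek()
    pos <<- pos + 1L
    tok
  }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    tok <- advance()
    if (is.na(tok)) stop("unexpected end of gene rule: '", rule, "'", call. = FALSE)
    if (tok == "(") {
      node <- parse_expr()
      if (is.na(peek()) || advance() != ")") {
        stop("unbalanced parentheses in gene rule: '", rule, "'", call. = FALSE)
      }
      return(node)
    }
    if (tok == ")" || tolower(tok) %in% c("and", "or")) {
      stop("malformed gene rule: '", rule, "'", call. = FALSE)
    }
    tok
  }
  tree <- parse_expr()
  if (pos <= length(tokens)) {
    stop("trailing tokens in gene rule: '", rule, "'", call. = FALSE)
  }
  tree
}

gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

gpr_eval_bool <- function(tree, present) {
  if (is.null(tree)) return(TRUE)
  if (is.character(tree)) return(isTRUE(present[[tree]]) || !(tree %in% names(present)))
  vals <- vapply(tree$args, gpr_eval_bool, logical(1), present = present)
  if (tree$op == "and") all(vals) else any(vals)
}

gpr_eval_value <- function(tree, values, default = NA_real_) {
  if (is.null(tree)) return(default)
  if (is.character(tree)) {
    return(if (tree %in% names(values)) values[[tree]] else default)
  }
  vals <- vapply(tree$args, gpr_eval_value, numeric(1),
                 values = values, default = default)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(default)
  if (tree$op == "and") min(vals) else max(vals)
}

#' Evaluate whether a reaction stays active under gene deletions
#'
#' Knockout semantics: a reaction is inactive when its GPR rule evaluates to
#' `FALSE` with the deleted genes absent. An `and` conjunct requires every
#' member of the complex, an `or` disjunct any isozyme; the empty rule is
#' always active (non-genetic reaction).
#'
#' @param rule A GPR string or a tree from [parse_gene_rule()].
#' @param deleted Character vector of deleted gene ids.
#' @param genes Optional character vector of known genes; deletions naming
#'   genes outside it trigger a warning and are ignored.
#' @return `TRUE` if the reaction remains active.
#' @examples
#' evaluate_gene_rule("(g1 and g2)", deleted = "g1") # FALSE
#' evaluate_gene_rule("(g1 or g2)", deleted = "g1")  # TRUE
#' evaluate_gene_rule("", deleted = "g1")            # TRUE
#' @export
evaluate_gene_rule <- function(rule, deleted = character(0), genes = NULL) {
  tree <- if (is.character(rule) || is.null(rule)) parse_gene_rule(rule) else rule
  if (!is.null(genes) && length(deleted)) {
    unknown <- setdiff(deleted, genes)
    if (length(unknown)) {
      warning("ignoring deletions of unknown genes: ",
              paste(unknown, collapse = ", "), call. = FALSE)
      deleted <- intersect(deleted, genes)
    }
  }
  rule_genes <- gpr_genes(tree)
  present <- stats::setNames(!(rule_genes %in% deleted), rule_genes)
  gpr_eval_bool(tree, as.list(present))
}

#' Map gene expression levels onto a reaction through its GPR rule
#'
#' Enzyme-complex semantics: `and` takes the minimum expression of its
#' members (the complex is limited by its scarcest subunit), `or` the maximum
#' (any isozyme suffices). Genes without measurements are skipped; a rule
#' with no measured gene returns `default`.
#'
#' @inheritParams evaluate_gene_rule
#' @param expression Named numeric vector of gene expression levels.
#' @param default Value returned for non-genetic or unmeasured reactions.
#' @return A single numeric expression level.
#' @export
reaction_expression <- function(rule, expression, default = NA_real_) {
  tree <- if (is.character(rule) || is.null(rule)) parse_gene_rule(rule) else rule
  gpr_eval_value(tree, as.list(expression), default = default)
}
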