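# Gene-protein-reaction (GPR) rules: Boolean AND/OR trees over gene ids.
# "g1 and (g2 or g3)" means the reaction needs g1 plus either isozyme g2/g3.

gpr_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(stringr::str_trim(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a GPR rule
#'
#' Accepts `and`/`or` (any case), `&`/`|`, `&&`/`||` and parentheses; any
#' other token is a gene id.  `""` parses to `NULL` (no rule).
#'
#' @param text the rule string.
#' @return a parse tree: a gene id (character) or
#'   `list(op = "and"|"or", args = list(...))`; `NULL` for an empty rule.
#' @export
parse_gpr <- function(text) {
  if (is.na(text) || !nzchar(stringr::str_trim(text))) return(NULL)
  toks <- gpr_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L; toks[pos - 1L] }
  is_op <- function(tk, ops) !is.na(tk) && tolower(tk) %in% ops

  parse_expr <- function() {
    args <- list(parse_term())
    while (is_op(peek(), c("or", "|", "||"))) {
      advance()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_op(peek(), c("and", "&", "&&"))) {
      advance()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    tk <- peek()
    if (is.na(tk)) stop("GPR parse error: unexpected end of rule in: ", text)
    if (tk == "(") {
      advance()
      inner <- parse_expr()
      if (!identical(peek(), ")"))
        stop("GPR parse error: missing ')' in: ", text)
      advance()
      return(inner)
    }
    if (tk == ")" || is_op(tk, c("and", "or", "&", "|", "&&", "||")))
      stop("GPR parse error: unexpected '", tk, "' in: ", text)
    advance()
  }
  out <- parse_expr()
  if (pos <= length(toks))
    stop("GPR parse error: trailing tokens in: ", text)
  out
}

#' Genes mentioned in a GPR rule
#' @param gpr a rule string or parsed tree.
#' @return character vector of gene ids.
#' @export
gpr_genes <- function(gpr) {
  tree <- if (is.character(gpr) && length(gpr) == 1L && !is.list(gpr))
    parse_gpr(gpr) else gpr
  if (is.null(tree)) return(character())
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Evaluate a GPR rule
#'
#' Two algebras share the same tree walk:
#' \describe{
#'   \item{logical}{`values` maps genes to `TRUE`/`FALSE` presence;
#'     `and = all`, `or = any`.  Used for knockouts.}
#'   \item{ordinal}{`values` maps genes to regulation codes
#'     (-1 down, 0 unchanged, +1 up); `and = min` (the most restrictive
#'     subunit limits the enzyme), `or = max` (the least restricted isozyme
#'     rescues it).  Used for fold-change propagation.}
#' }
#'
#' @param gpr rule string or parsed tree.
#' @param values named vector of gene values.
#' @param default value assumed for genes absent from `values`.
#' @return the rule value; `NA` for an empty rule.
#' @export
eval_gpr <- function(gpr, values, default = TRUE) {
  tree <- if (!is.list(gpr) && is.character(gpr) && length(gpr) == 1L)
    parse_gpr(gpr) else gpr
  if (is.null(tree)) return(NA)
  logical_mode <- is.logical(default) ||
    (length(values) > 0 && is.logical(values[[1]]))
  walk <- function(node) {
    if (is.character(node)) {
      if (node %in% names(values)) return(values[[node]])
      return(default)
    }
    vals <- unlist(lapply(node$args, walk))
    if (logical_mode) {
      if (node$op == "and") all(vals) else any(vals)
    } else {
      if (node$op == "and") min(vals) else max(vals)
    }
  }
  walk(tree)
}
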