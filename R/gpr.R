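#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers with `and` / `or`
#' operators and parentheses. `and` encodes an enzyme complex (all subunits
#' required), `or` encodes isozymes (any one suffices). Keywords are
#' case-insensitive; `&`/`&&` and `|`/`||` are accepted as synonyms. An empty
#' or all-whitespace rule parses to `NULL` (no gene association).
#'
#' @param rule Character scalar, e.g. `"(g1 and g2) or g3"`.
#' @return A parse tree: `NULL` for an empty rule, a list
#'   `list(gene = "id")` for a leaf, or `list(op = "and"|"or", args = list(...))`
#'   for an operator node.
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L || is.na(rule)) return(NULL)
  stopifnot(is.character(rule), length(rule) == 1L)
  if (!nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  st$src <- rule
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop(sprintf("GPR parse error in %s: unexpected token '%s'",
                 dQuote(rule), st$toks[st$pos]), call. = FALSE)
  }
  tree
}

gpr_tokenize <- function(rule) {
  # identifiers may contain letters, digits, '_', '.', '-', ':'
  pat <- "\\(|\\)|&&|\\|\\||&|\\||[A-Za-z0-9_.:-]+"
  m <- gregexpr(pat, rule)[[1]]
  toks <- regmatches(rule, list(m))[[1]]
  leftover <- gsub(pat, "", rule)
  leftover <- gsub("[[:space:]]", "", leftover)
  if (nzchar(leftover)) {
    stop(sprintf("GPR parse error in %s: illegal character '%s'",
                 dQuote(rule), substr(leftover, 1L, 1L)), call. = FALSE)
  }
  toks
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_is_op <- function(tok, which) {
  if (is.na(tok)) return(FALSE)
  lt <- tolower(tok)
  if (which == "and") lt %in% c("and", "&", "&&") else lt %in% c("or", "|", "||")
}

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (gpr_is_op(gpr_peek(st), "or")) {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_and(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (gpr_is_op(gpr_peek(st), "and")) {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_atom(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) {
    stop(sprintf("GPR parse error in %s: unexpected end of rule", dQuote(st$src)),
         call. = FALSE)
  }
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) {
      stop(sprintf("GPR parse error in %s: missing ')'", dQuote(st$src)), call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok == ")" || gpr_is_op(tok, "and") || gpr_is_op(tok, "or")) {
    stop(sprintf("GPR parse error in %s: unexpected token '%s'", dQuote(st$src), tok),
         call. = FALSE)
  }
  st$pos <- st$pos + 1L
  list(gene = tok)
}

#' Evaluate a GPR rule over trinary gene states
#'
#' Applies complex/isozyme semantics over the trinary alphabet
#' \{-1 low, 0 moderate, +1 high\}: an `and` node takes the minimum of its
#' children (a complex is only as available as its scarcest subunit), an `or`
#' node the maximum (the most available isozyme carries the reaction). An
#' empty rule evaluates to 0, as does a gene absent from `gene_states`
#' (absence of evidence is not a cue).
#'
#' @param gpr A parse tree from [parse_gpr()], or a character rule which is
#'   parsed on the fly.
#' @param gene_states Named integer vector of gene states in \{-1, 0, 1\}.
#' @return Integer scalar in \{-1, 0, 1\}.
#' @examples
#' evaluate_gpr("(g1 and g2) or g3", c(g1 = 1L, g2 = 0L, g3 = -1L))  # 0
#' @export
evaluate_gpr <- function(gpr, gene_states) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) return(0L)
  stopifnot(is.numeric(gene_states) || length(gene_states) == 0L)
  eval_node <- function(node) {
    if (!is.null(node$gene)) {
      i <- match(node$gene, names(gene_states))
      if (is.na(i) || is.na(gene_states[i])) 0L else as.integer(gene_states[i])
    } else {
      vals <- vapply(node$args, eval_node, integer(1))
      if (node$op == "and") min(vals) else max(vals)
    }
  }
  eval_node(gpr)
}

#' @keywords internal
gpr_genes <- function(gpr) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) return(character(0))
  if (!is.null(gpr$gene)) return(gpr$gene)
  unique(unlist(lapply(gpr$args, gpr_genes)))
}
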