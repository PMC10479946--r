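#' Parse a gene-protein-reaction (GPR) rule
#'
#' Parses boolean rules such as `"(g1 and g2) or g3"` into a tree. `and`
#' marks an enzyme complex (all subunits required), `or` marks isozymes
#' (alternatives). Parsing is case-insensitive for the operators; gene ids
#' may contain letters, digits, `_`, `.` and `-`.
#'
#' @param text GPR string; `""`, `NA` or `NULL` yield `NULL` (no gene
#'   association).
#' @return a parse tree: a character leaf, or `list(op = "and"|"or",
#'   args = list(...))`; `NULL` for an empty rule.
#' @export
gpr_parse <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  tokens <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens; st$pos <- 1L; st$text <- text
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$tokens)) {
    stop("malformed GPR '", text, "': unexpected token '",
         st$tokens[st$pos], "'")
  }
  tree
}

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[A-Za-z0-9_.-]+"
  m <- gregexpr(pat, text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  leftover <- gsub(pat, "", text)
  if (grepl("[^[:space:]]", leftover)) {
    stop("malformed GPR '", text, "': unrecognized characters")
  }
  toks
}

gpr_peek <- function(st) if (st$pos <= length(st$tokens)) st$tokens[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) stop("malformed GPR '", st$text, "': unexpected end")
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") {
      stop("malformed GPR '", st$text, "': missing ')'")
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop("malformed GPR '", st$text, "': unexpected '", tok, "'")
  }
  st$pos <- st$pos + 1L
  tok
}

#' List the genes appearing in a GPR tree
#'
#' @param tree a parse tree from [gpr_parse()] (or `NULL`).
#' @return character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Serialize a GPR tree back to its rule string
#'
#' @param tree a parse tree (or `NULL`).
#' @return normalized rule string (lower-case operators, full parentheses on
#'   nested nodes); `""` for `NULL`.
#' @export
gpr_deparse <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- gpr_deparse(a)
    if (!is.character(a) && a$op != tree$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}

#' Fold gene scores through a GPR rule
#'
#' Aggregates per-gene scores (e.g. mean FPKM) into a single reaction score.
#' `and` nodes model enzyme complexes and default to the minimum of their
#' children (the limiting subunit); `or` nodes model isozymes and default to
#' the maximum (best alternative), with `"sum"` available to model additive
#' isozyme capacity.
#'
#' Genes without a score are "absent" (`NA`): an `and` with an absent child
#' is absent (unless `absent_and = "ignore"`, which folds over the scored
#' children only); an `or` ignores absent children and is absent only when
#' all alternatives are absent. An empty rule always returns `NA`.
#'
#' @param gpr a GPR rule string or a tree from [gpr_parse()].
#' @param gene_scores named numeric vector of per-gene scores; missing genes
#'   are treated as absent.
#' @param and_rule aggregation at `and` nodes; only `"min"` is supported.
#' @param or_rule aggregation at `or` nodes: `"max"` (default) or `"sum"`.
#' @param absent_and `"propagate"` (default) or `"ignore"`.
#' @return the reaction score, or `NA_real_` if absent.
#' @export
evaluate_gpr <- function(gpr, gene_scores, and_rule = "min",
                         or_rule = c("max", "sum"),
                         absent_and = c("propagate", "ignore")) {
  and_rule <- match.arg(and_rule, "min")
  or_rule <- match.arg(or_rule)
  absent_and <- match.arg(absent_and)
  tree <- if (is.character(gpr) && length(gpr) == 1L) gpr_parse(gpr) else gpr
  gpr_eval_tree(tree, gene_scores, or_rule, absent_and)
}

gpr_eval_tree <- function(tree, scores, or_rule, absent_and) {
  if (is.null(tree)) return(NA_real_)
  if (is.character(tree)) {
    v <- scores[tree]
    return(if (length(v) == 0 || is.na(v)) NA_real_ else as.numeric(v))
  }
  vals <- vapply(tree$args, gpr_eval_tree, numeric(1),
                 scores = scores, or_rule = or_rule, absent_and = absent_and)
  if (tree$op == "and") {
    if (absent_and == "propagate" && anyNA(vals)) return(NA_real_)
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NA_real_)
    min(vals)
  } else {
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NA_real_)
    if (or_rule == "max") max(vals) else sum(vals)
  }
}
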