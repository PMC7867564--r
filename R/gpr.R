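#' Parse a gene-protein-reaction (GPR) boolean rule
#'
#' GPR rules associate reactions with the genes whose products catalyse them.
#' The grammar is the usual one: gene identifiers combined with \code{and}
#' (enzyme complexes: all subunits required) and \code{or} (isozymes: any one
#' suffices), with parentheses for grouping. \code{or} binds more loosely than
#' \code{and}. An empty rule denotes a spontaneous (gene-independent) reaction.
#'
#' @param rule character string, e.g. \code{"(gA and gB) or gC"}; \code{NULL},
#'   \code{NA} or a blank string yield \code{NULL} (spontaneous).
#' @return a parse tree: nested lists with \code{op} in \code{"and"},
#'   \code{"or"}, \code{"gene"}, or \code{NULL} for spontaneous reactions.
#' @examples
#' tree <- parse_gpr("(gA and gB) or gC")
#' evaluate_gpr(tree, present = "gC")
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L) return(NULL)
  if (length(rule) != 1L) stop("parse_gpr() expects a single rule string")
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("malformed GPR rule, unexpected token '", st$toks[st$pos], "' in: ", rule)
  }
  tree
}

gpr_tokenize <- function(rule) {
  m <- gregexpr("\\(|\\)|[A-Za-z0-9_.:-]+", rule)[[1]]
  toks <- regmatches(rule, list(m))[[1]]
  residue <- gsub("\\(|\\)|[A-Za-z0-9_.:-]+|\\s+", "", rule)
  if (nzchar(residue)) {
    stop("malformed GPR rule, illegal characters '", residue, "' in: ", rule)
  }
  toks
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_and(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_atom(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("malformed GPR rule: unexpected end of input")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") {
      stop("malformed GPR rule: unbalanced parentheses")
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    stop("malformed GPR rule: unexpected token '", tk, "'")
  }
  st$pos <- st$pos + 1L
  list(op = "gene", gene = tk)
}

#' Evaluate a GPR rule against a set of present genes
#'
#' @param rule a parse tree from [parse_gpr()] (or \code{NULL} for a
#'   spontaneous reaction, which always evaluates \code{TRUE}).
#' @param present character vector of present gene ids.
#' @return logical scalar.
#' @export
evaluate_gpr <- function(rule, present) {
  if (is.null(rule)) return(TRUE)
  if (!is.list(rule) || is.null(rule$op)) stop("malformed GPR tree")
  switch(rule$op,
    gene = rule$gene %in% present,
    and  = all(vapply(rule$args, evaluate_gpr, logical(1), present = present)),
    or   = any(vapply(rule$args, evaluate_gpr, logical(1), present = present)),
    stop("malformed GPR tree: unknown operator '", rule$op, "'")
  )
}

#' Genes referenced by a GPR rule
#'
#' @param rule a parse tree from [parse_gpr()].
#' @return character vector of gene ids (empty for spontaneous reactions).
#' @export
gpr_genes <- function(rule) {
  if (is.null(rule)) return(character(0))
  if (!is.list(rule) || is.null(rule$op)) stop("malformed GPR tree")
  if (rule$op == "gene") return(rule$gene)
  unique(unlist(lapply(rule$args, gpr_genes)))
}

# Render a parse tree back to rule text (used when writing network JSON).
deparse_gpr <- function(rule) {
  if (is.null(rule)) return("")
  if (rule$op == "gene") return(rule$gene)
  parts <- vapply(rule$args, function(a) {
    s <- deparse_gpr(a)
    if (!is.null(a$op) && a$op %in% c("and", "or") && a$op != rule$op) {
      s <- paste0("(", s, ")")
    }
    s
  }, character(1))
  paste(parts, collapse = paste0(" ", rule$op, " "))
}
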