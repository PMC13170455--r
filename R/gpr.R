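## Gene-protein-reaction rules.
##
## GPR strings are boolean expressions over gene ids with "and"/"or"
## (case-insensitive) and parentheses, the de facto dialect of published
## models. AND means an enzyme complex (all subunits required), OR isozymes
## (any suffices). An empty string means the reaction has no gene association.

.gprTokenize <- function(text) {
  pat <- "\\(|\\)|[^\\s()]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(character())
  regmatches(text, list(m))[[1]]
}

#' Parse a GPR rule
#'
#' Parses a gene-protein-reaction string into a nested expression tree.
#' Leaves are gene ids; internal nodes are lists with elements \code{op}
#' ("and"/"or") and \code{args}. \code{or} binds more loosely than
#' \code{and}, matching the convention of COBRA-style model files.
#'
#' @param rule GPR string, e.g. \code{"HK1 or (G6PD and TKT)"}.
#' @return Parse tree, or \code{NULL} for an empty rule.
#' @export
parseGPR <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  tokens <- .gprTokenize(rule)
  pos <- 1L

  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L; tokens[pos - 1L] }

  parsePrimary <- function() {
    tk <- peek()
    if (is.na(tk)) stop("unexpected end of GPR rule: ", rule)
    if (tk == "(") {
      advance()
      node <- parseOr()
      if (!identical(peek(), ")")) stop("unbalanced parentheses in GPR: ", rule)
      advance()
      return(node)
    }
    if (tk == ")" || tolower(tk) %in% c("and", "or"))
      stop("unexpected token '", tk, "' in GPR: ", rule)
    advance()
  }
  parseAnd <- function() {
    args <- list(parsePrimary())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args <- c(args, list(parsePrimary()))
    }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parseOr <- function() {
    args <- list(parseAnd())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args <- c(args, list(parseAnd()))
    }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }

  tree <- parseOr()
  if (pos <= length(tokens))
    stop("trailing token '", tokens[pos], "' in GPR: ", rule)
  tree
}

#' Genes referenced by a GPR rule
#'
#' @param rule GPR string.
#' @return Character vector of gene ids (empty for an empty rule).
#' @export
gprGenes <- function(rule) {
  tree <- parseGPR(rule)
  collect <- function(node) {
    if (is.character(node)) return(node)
    unlist(lapply(node$args, collect))
  }
  if (is.null(tree)) character() else unique(collect(tree))
}

#' Evaluate a GPR rule against expression values
#'
#' AND nodes take the minimum of their operands (complex limited by its
#' scarcest subunit), OR the maximum (isozymes are additive routes, scored by
#' the best-expressed one). Genes absent from \code{values} count as 0:
#' absence from an RNA-seq profile means not detected.
#'
#' @param rule GPR string.
#' @param values named numeric vector of gene expression.
#' @return Numeric score, or \code{NA} for an empty rule.
#' @export
evalGPR <- function(rule, values) {
  tree <- parseGPR(rule)
  if (is.null(tree)) return(NA_real_)
  ev <- function(node) {
    if (is.character(node)) {
      v <- values[node]
      if (is.na(v)) 0 else unname(v)
    } else if (node$op == "and") {
      min(vapply(node$args, ev, 0))
    } else {
      max(vapply(node$args, ev, 0))
    }
  }
  ev(tree)
}
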