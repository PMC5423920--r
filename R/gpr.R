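#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are Boolean expressions over gene identifiers that state which
#' gene products a reaction needs: isozymes are combined with `or`, enzyme
#' complexes with `and`. `parse_gpr()` turns the textual rule into a
#' normalised Boolean tree. `and` binds tighter than `or`; parentheses
#' override; keywords are case-insensitive.
#'
#' Normalisation flattens nested nodes of the same type (so
#' `a and (b and c)` has a single `and` node with three children) and
#' collapses single-child nodes, guaranteeing that every interior node has at
#' least two children.
#'
#' @param rule_text Rule string, e.g. `"(g1 or g2) and g3"`.
#' @param known_genes Optional character vector of valid gene ids. Tokens not
#'   in this set are recorded in the `unknown_genes` attribute of the result
#'   and raise a warning; parsing still succeeds.
#' @return An object of class `gpr`: a nested list with `type` one of
#'   `"leaf"`, `"and"`, `"or"`; leaves carry `gene`, interior nodes
#'   `children`.
#' @examples
#' parse_gpr("g1 and g2 or g3")
#' parse_gpr("(g1 or g2) and g3")
#' @export
parse_gpr <- function(rule_text, known_genes = NULL) {
  if (!is.character(rule_text) || length(rule_text) != 1L || is.na(rule_text)) {
    stop("`rule_text` must be a single string", call. = FALSE)
  }
  tokens <- gpr_tokenize(rule_text)
  if (nrow(tokens) == 0L) {
    stop("empty GPR rule", call. = FALSE)
  }
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  tree <- gpr_parse_or(state)
  if (state$pos <= nrow(state$tokens)) {
    tok <- state$tokens[state$pos, ]
    stop(sprintf("GPR parse error at position %d: unexpected '%s'",
                 tok$at, tok$text), call. = FALSE)
  }
  tree <- gpr_normalize(tree)
  if (!is.null(known_genes)) {
    unknown <- setdiff(gpr_genes(tree), known_genes)
    if (length(unknown) > 0L) {
      warning(sprintf("GPR references unknown genes: %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
      attr(tree, "unknown_genes") <- unknown
    }
  }
  tree
}

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[^\\s()]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble::tibble(text = character(), type = character(), at = integer()))
  }
  pieces <- regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
  type <- dplyr::case_when(
    pieces == "(" ~ "lparen",
    pieces == ")" ~ "rparen",
    tolower(pieces) == "and" ~ "and",
    tolower(pieces) == "or" ~ "or",
    tolower(pieces) == "&" ~ "and",
    tolower(pieces) == "|" ~ "or",
    .default = "gene"
  )
  tibble::tibble(text = pieces, type = type, at = as.integer(m))
}

gpr_peek <- function(state) {
  if (state$pos > nrow(state$tokens)) NULL else state$tokens[state$pos, ]
}

gpr_parse_or <- function(state) {
  children <- list(gpr_parse_and(state))
  repeat {
    tok <- gpr_peek(state)
    if (is.null(tok) || tok$type != "or") break
    state$pos <- state$pos + 1L
    children <- c(children, list(gpr_parse_and(state)))
  }
  if (length(children) == 1L) children[[1]] else list(type = "or", children = children)
}

gpr_parse_and <- function(state) {
  children <- list(gpr_parse_atom(state))
  repeat {
    tok <- gpr_peek(state)
    if (is.null(tok) || tok$type != "and") break
    state$pos <- state$pos + 1L
    children <- c(children, list(gpr_parse_atom(state)))
  }
  if (length(children) == 1L) children[[1]] else list(type = "and", children = children)
}

gpr_parse_atom <- function(state) {
  tok <- gpr_peek(state)
  if (is.null(tok)) {
    stop("GPR parse error: unexpected end of rule", call. = FALSE)
  }
  if (tok$type == "lparen") {
    state$pos <- state$pos + 1L
    inner <- gpr_parse_or(state)
    close <- gpr_peek(state)
    if (is.null(close) || close$type != "rparen") {
      stop(sprintf("GPR parse error: unbalanced parenthesis opened at position %d",
                   tok$at), call. = FALSE)
    }
    state$pos <- state$pos + 1L
    return(inner)
  }
  if (tok$type == "gene") {
    state$pos <- state$pos + 1L
    return(list(type = "leaf", gene = tok$text))
  }
  stop(sprintf("GPR parse error at position %d: unexpected '%s'",
               tok$at, tok$text), call. = FALSE)
}

gpr_normalize <- function(node) {
  if (node$type == "leaf") {
    return(structure(node, class = "gpr"))
  }
  kids <- lapply(node$children, gpr_normalize)
  flat <- list()
  for (k in kids) {
    if (k$type == node$type) {
      flat <- c(flat, k$children)
    } else {
      flat <- c(flat, list(unclass(k)))
    }
  }
  if (length(flat) == 1L) {
    return(structure(flat[[1]], class = "gpr"))
  }
  structure(list(type = node$type, children = lapply(flat, unclass)), class = "gpr")
}

#' Genes referenced by a GPR tree
#'
#' @param expr A `gpr` object from [parse_gpr()].
#' @return Character vector of distinct gene ids, in first-appearance order.
#' @export
gpr_genes <- function(expr) {
  walk <- function(node) {
    if (node$type == "leaf") return(node$gene)
    unlist(lapply(node$children, walk))
  }
  unique(walk(expr))
}

#' Evaluate a GPR tree under a gene deletion
#'
#' Returns `TRUE` when the reaction remains catalysable: deleted genes are
#' assigned `FALSE`, all other genes `TRUE`, and the Boolean tree is
#' evaluated.
#'
#' @param expr A `gpr` object.
#' @param deleted_genes Character vector of deleted (or unexpressed) gene ids.
#' @return Logical scalar.
#' @examples
#' evaluate_gpr(parse_gpr("g1 or g2"), "g1")   # isozyme survives: TRUE
#' evaluate_gpr(parse_gpr("g1 and g2"), "g1")  # complex broken: FALSE
#' @export
evaluate_gpr <- function(expr, deleted_genes = character()) {
  walk <- function(node) {
    switch(node$type,
      leaf = !(node$gene %in% deleted_genes),
      and  = all(vapply(node$children, walk, logical(1))),
      or   = any(vapply(node$children, walk, logical(1))),
      stop("invalid GPR node type: ", node$type, call. = FALSE)
    )
  }
  walk(expr)
}

#' Serialise a GPR tree back to rule text
#'
#' Printing uses the minimal parenthesisation consistent with `and` binding
#' tighter than `or`, so `parse_gpr(format_gpr(x))` reproduces `x` exactly.
#'
#' @param expr A `gpr` object.
#' @return A single string.
#' @export
format_gpr <- function(expr) {
  walk <- function(node, parent) {
    if (node$type == "leaf") return(node$gene)
    sep <- if (node$type == "and") " and " else " or "
    body <- paste(vapply(node$children, walk, character(1), node$type),
                  collapse = sep)
    if (node$type == "or" && identical(parent, "and")) paste0("(", body, ")") else body
  }
  walk(expr, NA_character_)
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", format_gpr(x), "\n", sep = "")
  invisible(x)
}
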