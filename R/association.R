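#' Parse a transcript-reaction association expression
#'
#' Grammar: transcript ids combined with `AND` / `OR` (case-insensitive)
#' and parentheses; `OR` binds weaker than `AND`. The result is a tree of
#' nodes `list(op = "and"|"or", children = ...)` with leaves
#' `list(op = "leaf", id = <transcript>)`.
#'
#' @param text association string, e.g. `"(tA AND tB) OR tC"`.
#' @return association tree, or `NULL` for an empty string.
#' @export
parse_association <- function(text) {
  if (is.null(text) || is.na(text) || trimws(text) == "") return(NULL)
  toks <- assoc_tokens(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- assoc_expr(st)
  if (st$pos <= length(st$toks))
    stop("trailing tokens in association: ", sQuote(text))
  tree
}

assoc_tokens <- function(text) {
  text <- gsub("(", " ( ", text, fixed = TRUE)
  text <- gsub(")", " ) ", text, fixed = TRUE)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[toks != ""]
}

assoc_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

assoc_expr <- function(st) {
  kids <- list(assoc_term(st))
  while (!is.na(assoc_peek(st)) && toupper(assoc_peek(st)) == "OR") {
    st$pos <- st$pos + 1L
    kids <- c(kids, list(assoc_term(st)))
  }
  if (length(kids) == 1L) kids[[1]] else list(op = "or", children = kids)
}

assoc_term <- function(st) {
  kids <- list(assoc_factor(st))
  while (!is.na(assoc_peek(st)) && toupper(assoc_peek(st)) == "AND") {
    st$pos <- st$pos + 1L
    kids <- c(kids, list(assoc_factor(st)))
  }
  if (length(kids) == 1L) kids[[1]] else list(op = "and", children = kids)
}

assoc_factor <- function(st) {
  tok <- assoc_peek(st)
  if (is.na(tok)) stop("unexpected end of association expression")
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- assoc_expr(st)
    if (is.na(assoc_peek(st)) || assoc_peek(st) != ")")
      stop("unbalanced parentheses in association expression")
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok == ")" || toupper(tok) %in% c("AND", "OR"))
    stop("unexpected token in association expression: ", sQuote(tok))
  st$pos <- st$pos + 1L
  list(op = "leaf", id = tok)
}

#' Format an association tree back to its string form
#'
#' @param tree association tree from [parse_association()], or `NULL`.
#' @return association string (empty for `NULL`).
#' @export
format_association <- function(tree) {
  if (is.null(tree)) return("")
  fmt <- function(node, parent_op) {
    if (node$op == "leaf") return(node$id)
    sep <- if (node$op == "and") " AND " else " OR "
    body <- paste(vapply(node$children, fmt, character(1), node$op),
                  collapse = sep)
    # parenthesise AND under OR-context siblings and any nested OR
    if (node$op == "or" && !is.null(parent_op)) paste0("(", body, ")")
    else if (node$op == "and" && identical(parent_op, "or")) paste0("(", body, ")")
    else body
  }
  fmt(tree, NULL)
}

#' Transcript ids referenced by an association tree
#' @param tree association tree or `NULL`.
#' @return character vector of transcript ids.
#' @export
association_transcripts <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (tree$op == "leaf") return(tree$id)
  unique(unlist(lapply(tree$children, association_transcripts)))
}
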