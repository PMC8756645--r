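#' @useDynLib evoflux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table modifyList
"_PACKAGE"

ARROWS_REV <- c("<==>", "<->", "↔")
ARROWS_IRR <- c("→", "->")

#' Parse a reaction equation string
#'
#' Equations use the `A + 2*B <==> C` notation: terms separated by `+`,
#' optional positive real coefficient attached with `*`, and one arrow.
#' Bidirectional arrows (`<==>`, `<->`, `↔`) mark the reaction
#' reversible; `->` and `→` mark it irreversible. Either side may be
#' empty (exchange reactions, sinks). Whitespace is ignored and a metabolite
#' repeated on one side has its coefficients summed.
#'
#' @param text equation string.
#' @return list with `reactants` and `products` (named numeric vectors of
#'   coefficients) and `reversible` (logical).
#' @examples
#' parse_equation("ATP + AC <==> ADP + ACTP")
#' parse_equation("PPI + H_2_O -> 2*PI + H")
#' @export
parse_equation <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("equation must be a single string")
  # longest arrows first so "->" does not split "<->"
  arrow_re <- "(<==>|<->|↔|→|->)"
  hits <- gregexpr(arrow_re, text)[[1]]
  if (hits[1] == -1L) stop("no arrow found in equation: ", sQuote(text))
  if (length(hits) > 1L) stop("multiple arrows in equation: ", sQuote(text))
  arrow <- regmatches(text, regexpr(arrow_re, text))
  sides <- strsplit(text, arrow_re)[[1]]
  lhs <- if (length(sides) >= 1L) sides[1] else ""
  rhs <- if (length(sides) >= 2L) sides[2] else ""
  list(reactants = parse_side(lhs),
       products = parse_side(rhs),
       reversible = arrow %in% ARROWS_REV)
}

parse_side <- function(side) {
  side <- trimws(side)
  if (side == "") return(setNames(numeric(0), character(0)))
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  out <- numeric(0)
  for (term in terms) {
    if (term == "") stop("empty term in equation side: ", sQuote(side))
    term <- gsub("\\s*\\*\\s*", "*", term)
    if (grepl("*", term, fixed = TRUE)) {
      bits <- strsplit(term, "*", fixed = TRUE)[[1]]
      if (length(bits) != 2L) stop("malformed term: ", sQuote(term))
      coef <- suppressWarnings(as.numeric(bits[1]))
      met <- bits[2]
      if (is.na(coef)) stop("malformed coefficient in term: ", sQuote(term))
      if (coef <= 0) stop("coefficient must be positive in term: ", sQuote(term))
    } else {
      coef <- 1
      met <- term
    }
    if (grepl("\\s", met) || met == "")
      stop("malformed metabolite token: ", sQuote(term))
    out[met] <- if (met %in% names(out)) out[[met]] + coef else coef
  }
  out
}

#' Format reactant/product maps back into an equation string
#'
#' Inverse of [parse_equation()]; coefficients equal to 1 are omitted.
#'
#' @param reactants,products named numeric coefficient vectors.
#' @param reversible logical; emits `<==>` when `TRUE`, `->` otherwise.
#' @return equation string.
#' @export
format_equation <- function(reactants, products, reversible) {
  fmt_side <- function(v) {
    if (length(v) == 0L) return("")
    paste(vapply(seq_along(v), function(i) {
      coef <- v[[i]]
      if (abs(coef - 1) < 1e-12) names(v)[i]
      else paste0(formatC(coef, digits = 15, format = "g"), "*", names(v)[i])
    }, character(1)), collapse = " + ")
  }
  arrow <- if (reversible) "<==>" else "->"
  trimws(paste(fmt_side(reactants), arrow, fmt_side(products)))
}

#' Construct a metabolic model
#'
#' Builds the model container used throughout the package from per-reaction
#' data. Metabolites are collected from the equations; a reaction touching
#' exactly one metabolite is registered as an exchange (sign convention:
#' negative flux = uptake, positive = secretion).
#'
#' @param reactions data.frame with columns `reaction_id`, `name`,
#'   `equation`, `lower_bound`, `upper_bound`, `association`, `subsystem`
#'   (the tabular model dialect; `association`/`subsystem` may be empty).
#' @param id model identifier.
#' @param objective_id,biomass_id reaction ids; default to a reaction whose
#'   id contains "BIO" for biomass and the biomass reaction for the
#'   objective when not given.
#' @return object of class `metabolic_model`.
#' @export
new_metabolic_model <- function(reactions, id = "model",
                                objective_id = NULL, biomass_id = NULL) {
  req <- c("reaction_id", "equation", "lower_bound", "upper_bound")
  if (!all(req %in% names(reactions)))
    stop("reactions table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(reactions$reaction_id))
    stop("duplicate reaction ids")
  if (is.null(reactions$name)) reactions$name <- reactions$reaction_id
  if (is.null(reactions$association)) reactions$association <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  reactions$lower_bound <- as.numeric(reactions$lower_bound)
  reactions$upper_bound <- as.numeric(reactions$upper_bound)
  if (any(reactions$lower_bound > reactions$upper_bound))
    stop("lower bound exceeds upper bound for: ",
         paste(reactions$reaction_id[reactions$lower_bound > reactions$upper_bound],
               collapse = ", "))

  eqs <- lapply(reactions$equation, parse_equation)
  names(eqs) <- reactions$reaction_id
  reactions$reversible <- vapply(eqs, `[[`, logical(1), "reversible")
  irr_neg <- !reactions$reversible & reactions$lower_bound < 0
  if (any(irr_neg))
    stop("irreversible reaction with negative lower bound: ",
         paste(reactions$reaction_id[irr_neg], collapse = ", "))

  mets <- sort(unique(unlist(lapply(eqs, function(e)
    c(names(e$reactants), names(e$products))))))
  n_species <- vapply(eqs, function(e)
    length(unique(c(names(e$reactants), names(e$products)))), integer(1))
  exchange_ids <- reactions$reaction_id[n_species == 1L]

  assoc <- lapply(reactions$association, function(a)
    if (is.na(a) || trimws(a) == "") NULL else parse_association(a))
  names(assoc) <- reactions$reaction_id

  if (is.null(biomass_id)) {
    cand <- grep("BIO", reactions$reaction_id, value = TRUE, ignore.case = TRUE)
    biomass_id <- if (length(cand)) cand[1] else NA_character_
  }
  if (is.null(objective_id)) objective_id <- biomass_id

  model <- structure(list(
    id = id,
    metabolites = data.frame(id = mets, stringsAsFactors = FALSE),
    reactions = reactions,
    equations = eqs,
    associations = assoc,
    exchange_ids = exchange_ids,
    objective_id = objective_id,
    biomass_id = biomass_id
  ), class = "metabolic_model")
  model$S <- build_stoichiometric_matrix(model)
  model
}

#' Stoichiometric matrix of a model
#'
#' `S[i, j]` is the coefficient of metabolite `i` in reaction `j`
#' (products positive, reactants negative); columns follow reaction order.
#' A metabolite appearing on both sides contributes its net coefficient.
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix with metabolite/reaction dimnames.
#' @export
build_stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$reaction_id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    e <- model$equations[[j]]
    for (m in names(e$reactants)) S[m, j] <- S[m, j] - e$reactants[[m]]
    for (m in names(e$products)) S[m, j] <- S[m, j] + e$products[[m]]
  }
  S
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", x$id, "\n")
  cat(" ", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions,",
      length(x$exchange_ids), "exchanges\n")
  cat("  objective:", x$objective_id, " biomass:", x$biomass_id, "\n")
  invisible(x)
}

#' Simulate reaction deletions
#'
#' Sets both flux bounds of the listed reactions to zero, the usual in
#' silico representation of a gene knockout. The input model is not
#' modified.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids character vector of reaction ids to delete.
#' @return the modified model.
#' @export
apply_deletions <- function(model, reaction_ids) {
  unknown <- setdiff(reaction_ids, model$reactions$reaction_id)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  idx <- match(reaction_ids, model$reactions$reaction_id)
  model$reactions$lower_bound[idx] <- 0
  model$reactions$upper_bound[idx] <- 0
  model
}

#' Read a model from the tabular dialect
#'
#' Tab-separated UTF-8 file with header
#' `reaction_id name equation lower_bound upper_bound association subsystem`.
#'
#' @param path file path.
#' @param ... passed to [new_metabolic_model()].
#' @return a `metabolic_model`.
#' @export
read_model_tsv <- function(path, ...) {
  df <- read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                   colClasses = "character", check.names = FALSE)
  new_metabolic_model(df, id = sub("\\.[^.]*$", "", basename(path)), ...)
}

#' Write a model in the tabular dialect
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @export
write_model_tsv <- function(model, path) {
  df <- model$reactions[, c("reaction_id", "name", "equation", "lower_bound",
                            "upper_bound", "association", "subsystem")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
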