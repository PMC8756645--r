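#' Flux balance analysis
#'
#' Solves the LP \eqn{\max_v c^\top v} subject to \eqn{S v = 0} and the
#' model's flux bounds, optionally overridden per reaction for this solve
#' only. Degenerate optima are possible: only the objective value is
#' uniquely determined; individual interior fluxes depend on the vertex the
#' solver lands on.
#'
#' @param model a `metabolic_model`.
#' @param extra_constraints named list `reaction_id -> c(lb, ub)` overriding
#'   the stored bounds for this solve.
#' @param objective reaction id, or a named numeric vector of objective
#'   coefficients; defaults to the model's objective reaction.
#' @param sense `"max"` or `"min"`.
#' @return a `flux_state`: list with `fluxes` (named vector), `objective_value`
#'   and `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`).
#' @export
solve_fba <- function(model, extra_constraints = NULL,
                      objective = model$objective_id,
                      sense = c("max", "min")) {
  sense <- match.arg(sense)
  rxns <- model$reactions$reaction_id
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (!is.null(extra_constraints)) {
    unknown <- setdiff(names(extra_constraints), rxns)
    if (length(unknown))
      stop("extra constraint on unknown reaction: ",
           paste(unknown, collapse = ", "))
    for (rid in names(extra_constraints)) {
      i <- match(rid, rxns)
      lb[i] <- extra_constraints[[rid]][1]
      ub[i] <- extra_constraints[[rid]][2]
    }
  }
  obj <- numeric(length(rxns))
  if (is.character(objective)) {
    i <- match(objective, rxns)
    if (anyNA(i)) stop("unknown objective reaction: ", objective)
    obj[i] <- 1
  } else {
    i <- match(names(objective), rxns)
    if (anyNA(i)) stop("unknown reaction in objective vector")
    obj[i] <- objective
  }
  res <- lp_solve(obj, model$S, rep(0, nrow(model$S)), lb, ub,
                  maximize = sense == "max")
  fluxes <- if (res$status == "optimal") setNames(res$x, rxns) else NULL
  structure(list(fluxes = fluxes,
                 objective_value = res$objective,
                 status = res$status),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state>", x$status)
  if (x$status == "optimal") cat("  objective:", format(x$objective_value))
  cat("\n")
  invisible(x)
}

#' Flux variability of one reaction
#'
#' Minimum and maximum attainable flux of a reaction over the feasible
#' region, via paired min/max LP solves.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction to scan.
#' @param fixed named list `reaction_id -> c(lb, ub)` of constraints
#'   (typically exchange settings) applied during both solves.
#' @return numeric vector `c(min, max)`.
#' @export
flux_variability <- function(model, reaction_id, fixed = NULL) {
  lo <- solve_fba(model, fixed, objective = reaction_id, sense = "min")
  hi <- solve_fba(model, fixed, objective = reaction_id, sense = "max")
  if (lo$status != "optimal" || hi$status != "optimal")
    stop("flux variability infeasible for ", reaction_id,
         " under constraints {",
         paste(names(fixed), collapse = ", "), "}")
  c(min = lo$objective_value, max = hi$objective_value)
}

#' Write a flux state as TSV plus a JSON sidecar
#'
#' @param state a `flux_state`.
#' @param path output TSV path; the sidecar is `<path>.json` with the
#'   objective value and solver status.
#' @export
write_flux_state <- function(state, path) {
  if (is.null(state$fluxes)) stop("cannot write a non-optimal flux state")
  write.table(data.frame(reaction_id = names(state$fluxes),
                         flux = unname(state$fluxes)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(objective = state$objective_value,
                            status = state$status),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
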