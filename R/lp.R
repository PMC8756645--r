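#' Solve a box-constrained linear program
#'
#' Thin interface over the package's dense two-phase simplex. Solves
#' \eqn{\min / \max\; c^\top x} subject to \eqn{A x = b} and
#' \eqn{lb \le x \le ub}. All bounds must be finite; constraint-based models
#' in this package use a large finite default bound (see
#' [default_bound()]) rather than infinities.
#'
#' @param obj numeric objective coefficients, length `ncol(A)`.
#' @param A dense numeric constraint matrix (equality rows).
#' @param b right-hand side, length `nrow(A)`.
#' @param lb,ub finite variable bounds.
#' @param maximize logical; maximize instead of minimize.
#' @return list with `status` (one of `"optimal"`, `"infeasible"`,
#'   `"unbounded"`, `"iteration_limit"`), `x` (solution or `NULL`) and
#'   `objective`.
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  if (length(obj) != ncol(A)) stop("objective length does not match columns")
  if (length(b) != nrow(A)) stop("rhs length does not match rows")
  if (!all(is.finite(lb)) || !all(is.finite(ub)))
    stop("lp_solve requires finite bounds; use default_bound() for open fluxes")
  res <- .simplex_core(as.numeric(obj), A, as.numeric(b),
                       as.numeric(lb), as.numeric(ub), isTRUE(maximize))
  status <- c("optimal", "infeasible", "unbounded", "iteration_limit")[res$status + 1L]
  list(status = status, x = res$x, objective = res$objective)
}

#' Default finite flux bound
#'
#' Magnitude used for nominally unbounded fluxes (the usual +/-1000
#' convention of constraint-based models).
#' @return a single number, 1000.
#' @export
default_bound <- function() 1000
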