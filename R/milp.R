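#' Solve a mixed-integer linear program by branch and bound
#'
#' Depth-first branch and bound over binary variables with LP relaxations
#' from [lp_solve()]; branches on the most fractional binary, prunes by
#' incumbent bound. Intended for the moderate indicator counts of
#' expression-consistency extraction on curated-scale and toy models.
#'
#' @param objective,A_eq,b_eq,A_le,b_le,lower,upper,maximize as in
#'   [lp_solve()].
#' @param binary_idx indices of variables restricted to \{0, 1\}.
#' @param time_limit seconds; exceeding it aborts with an error (a partial
#'   incumbent is never returned silently).
#' @param int_tol integrality tolerance.
#' @return list with `status`, `x`, `value`.
#' @keywords internal
milp_solve <- function(objective, A_eq = NULL, b_eq = NULL,
                       A_le = NULL, b_le = NULL,
                       lower, upper, binary_idx = integer(0),
                       maximize = TRUE, time_limit = 300, int_tol = 1e-6) {
  lower[binary_idx] <- pmax(lower[binary_idx], 0)
  upper[binary_idx] <- pmin(upper[binary_idx], 1)
  t0 <- Sys.time()
  best <- list(value = if (maximize) -Inf else Inf, x = NULL)
  sense <- if (maximize) 1 else -1

  recurse <- function(lo, up) {
    if (as.numeric(difftime(Sys.time(), t0, units = "secs")) > time_limit)
      stop("MILP time limit (", time_limit, " s) exceeded")
    rel <- lp_solve(objective, A_eq, b_eq, A_le, b_le, lo, up, maximize = maximize)
    if (rel$status != "optimal") return(invisible(NULL))
    if (!is.null(best$x) && sense * rel$value <= sense * best$value + 1e-9)
      return(invisible(NULL))
    frac <- abs(rel$x[binary_idx] - round(rel$x[binary_idx]))
    if (!length(binary_idx) || max(frac) <= int_tol) {
      if (is.null(best$x) || sense * rel$value > sense * best$value) {
        best <<- list(value = rel$value, x = rel$x)
      }
      return(invisible(NULL))
    }
    j <- binary_idx[which.max(frac)]
    ## explore the nearer side first
    first_up <- rel$x[j] >= 0.5
    for (side in if (first_up) c(1, 0) else c(0, 1)) {
      lo2 <- lo; up2 <- up
      if (side == 1) lo2[j] <- 1 else up2[j] <- 0
      recurse(lo2, up2)
    }
    invisible(NULL)
  }
  recurse(lower, upper)
  if (is.null(best$x)) return(list(status = "infeasible", x = NULL, value = NA_real_))
  list(status = "optimal", x = best$x, value = best$value)
}
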