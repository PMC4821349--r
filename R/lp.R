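#' Solve a bounded linear program
#'
#' Dense two-phase primal simplex with explicit variable bounds. This is the
#' optimization engine behind all constraint-based analyses in the package
#' (flux balance analysis, linearized MOMA, expression-guided extraction and
#' the strain-design scoring LPs). Problems are of the form
#' \deqn{\max / \min \; c^\top x \quad \mathrm{s.t.}\; A_{eq} x = b_{eq},\;
#'   A_{le} x \le b_{le},\; l \le x \le u.}
#'
#' Redundant equality rows (ubiquitous in stoichiometric matrices, which carry
#' conserved-moiety dependencies) are handled by the phase-1 drive-out: rows
#' whose artificial variable cannot be pivoted to a structural column are
#' dropped as linearly dependent. Anti-cycling uses Dantzig pricing with a
#' switch to Bland's rule after a fixed number of degenerate-prone iterations,
#' which guarantees termination.
#'
#' @param objective numeric objective coefficients, one per variable.
#' @param A_eq,b_eq equality constraint matrix and right-hand side (or NULL).
#' @param A_le,b_le less-than-or-equal constraints (or NULL).
#' @param lower,upper variable bounds; `lower` must be finite, `upper` may be
#'   `Inf`.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol numerical pivot/feasibility tolerance.
#' @param max_iter simplex iteration cap.
#' @return list with `status` ("optimal", "infeasible", "unbounded" or
#'   "maxiter"), `x` (solution vector) and `value` (objective value).
#' @keywords internal
lp_solve <- function(objective, A_eq = NULL, b_eq = NULL,
                     A_le = NULL, b_le = NULL,
                     lower, upper, maximize = TRUE,
                     tol = 1e-9, max_iter = 50000L) {
  n <- length(objective)
  stopifnot(length(lower) == n, length(upper) == n)
  if (any(!is.finite(lower))) stop("lp_solve requires finite lower bounds")
  if (any(upper < lower)) return(list(status = "infeasible", x = NULL, value = NA_real_))

  A_eq <- if (is.null(A_eq)) matrix(0, 0, n) else as.matrix(A_eq)
  A_le <- if (is.null(A_le)) matrix(0, 0, n) else as.matrix(A_le)
  b_eq <- as.numeric(if (is.null(b_eq)) numeric(0) else b_eq)
  b_le <- as.numeric(if (is.null(b_le)) numeric(0) else b_le)
  stopifnot(nrow(A_eq) == length(b_eq), nrow(A_le) == length(b_le))

  ## shift to y = x - lower >= 0
  rng <- upper - lower
  fin <- which(is.finite(rng))
  m_eq <- nrow(A_eq); m_le <- nrow(A_le); m_bd <- length(fin)

  n_sl <- m_le          # slack for <= rows
  n_bs <- m_bd          # slack for upper-bound rows
  ncol_s <- n + n_sl + n_bs
  m <- m_eq + m_le + m_bd

  A <- matrix(0, m, ncol_s)
  b <- numeric(m)
  if (m_eq > 0) {
    A[seq_len(m_eq), seq_len(n)] <- A_eq
    b[seq_len(m_eq)] <- b_eq - as.vector(A_eq %*% lower)
  }
  if (m_le > 0) {
    r <- m_eq + seq_len(m_le)
    A[r, seq_len(n)] <- A_le
    A[cbind(r, n + seq_len(m_le))] <- 1
    b[r] <- b_le - as.vector(A_le %*% lower)
  }
  if (m_bd > 0) {
    r <- m_eq + m_le + seq_len(m_bd)
    A[cbind(r, fin)] <- 1
    A[cbind(r, n + n_sl + seq_len(m_bd))] <- 1
    b[r] <- rng[fin]
  }
  ## drop all-zero rows (orphan balances); inconsistent zero rows -> infeasible
  rmax <- apply(abs(A), 1, max)
  zr <- rmax < tol
  if (any(zr & abs(b) > 1e-7)) return(list(status = "infeasible", x = NULL, value = NA_real_))
  if (any(zr)) { A <- A[!zr, , drop = FALSE]; b <- b[!zr]; m <- nrow(A) }
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }

  ## tableau with artificials on every row
  Tb <- cbind(A, diag(1, m), b)
  basis <- ncol_s + seq_len(m)
  n_tot <- ncol_s + m
  bland_after <- 2000L + 10L * (m + n_tot)

  pivot <- function(Tb, pr, pc) {
    Tb[pr, ] <- Tb[pr, ] / Tb[pr, pc]
    other <- setdiff(seq_len(nrow(Tb)), pr)
    Tb[other, ] <- Tb[other, ] - outer(Tb[other, pc], Tb[pr, ])
    Tb
  }

  run_simplex <- function(Tb, basis, cost, allowed, it0) {
    ## cost: length n_tot vector (minimization); returns updated state
    iter <- it0
    repeat {
      cb <- cost[basis]
      red <- cost[allowed] - as.vector(crossprod(cb, Tb[, allowed, drop = FALSE]))
      if (iter > bland_after) {
        cand <- which(red < -tol)
        if (!length(cand)) break
        pc <- allowed[cand[1L]]
      } else {
        j <- which.min(red)
        if (red[j] >= -tol) break
        pc <- allowed[j]
      }
      col <- Tb[, pc]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tb = Tb, basis = basis, status = "unbounded", iter = iter))
      ratio <- Tb[pos, ncol(Tb)] / col[pos]
      rmin <- min(ratio)
      tiesel <- pos[ratio <= rmin + tol]
      pr <- tiesel[which.min(basis[tiesel])]   # deterministic, Bland-compatible
      Tb <- pivot(Tb, pr, pc)
      basis[pr] <- pc
      iter <- iter + 1L
      if (iter > max_iter) return(list(Tb = Tb, basis = basis, status = "maxiter", iter = iter))
    }
    list(Tb = Tb, basis = basis, status = "optimal", iter = iter)
  }

  ## phase 1: minimize sum of artificials
  c1 <- c(rep(0, ncol_s), rep(1, m))
  ph1 <- run_simplex(Tb, basis, c1, seq_len(n_tot), 0L)
  if (ph1$status != "optimal") return(list(status = ph1$status, x = NULL, value = NA_real_))
  Tb <- ph1$Tb; basis <- ph1$basis
  ph1_obj <- sum(Tb[basis > ncol_s, ncol(Tb)])
  if (ph1_obj > 1e-6 * max(1, max(abs(b)))) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  ## drive out artificials still basic (at zero); drop dependent rows
  drop_rows <- integer(0)
  for (r in which(basis > ncol_s)) {
    js <- which(abs(Tb[r, seq_len(ncol_s)]) > tol)
    if (length(js)) {
      Tb <- pivot(Tb, r, js[1L]); basis[r] <- js[1L]
    } else drop_rows <- c(drop_rows, r)
  }
  if (length(drop_rows)) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }

  ## phase 2 over structural columns only
  c2 <- c(if (maximize) -objective else objective, rep(0, ncol_s - n + nrow(Tb) * 0),
          rep(0, n_tot - ncol_s))
  c2 <- numeric(n_tot)
  c2[seq_len(n)] <- if (maximize) -objective else objective
  ph2 <- run_simplex(Tb, basis, c2, seq_len(ncol_s), ph1$iter)
  if (ph2$status == "maxiter") return(list(status = "maxiter", x = NULL, value = NA_real_))
  if (ph2$status == "unbounded") return(list(status = "unbounded", x = NULL, value = NA_real_))
  Tb <- ph2$Tb; basis <- ph2$basis
  y <- numeric(n_tot)
  y[basis] <- Tb[, ncol(Tb)]
  x <- y[seq_len(n)] + lower
  list(status = "optimal", x = x, value = sum(objective * x))
}
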