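# Independent oracles used across the suite. These deliberately avoid the
# package's solver paths: LPs are checked by enumerating basic solutions of
# the constraint polytope, GPR rules by evaluating the rule text with R's own
# boolean operators, MILPs by brute force over the binary assignments.

# Maximum of obj'v over {S v = 0, lb <= v <= ub} by enumeration of basic
# solutions: every choice of rank(S) basic variables with the remaining
# variables pinned at either bound. Exact for small n.
enum_lp_max <- function(obj, S, lb, ub, tol = 1e-8) {
  n <- length(obj)
  S <- as.matrix(S)
  qd <- qr(t(S))
  r <- qd$rank
  rows <- sort(qd$pivot[seq_len(r)])
  S <- S[rows, , drop = FALSE]
  best <- -Inf
  if (r == 0) {
    # box only: optimum at a bound vertex
    v <- ifelse(obj >= 0, ub, lb)
    return(sum(obj * v))
  }
  for (basic in utils::combn(n, r, simplify = FALSE)) {
    B <- S[, basic, drop = FALSE]
    if (abs(det(B)) < tol) next
    nonbasic <- setdiff(seq_len(n), basic)
    for (mask in 0:(2^length(nonbasic) - 1)) {
      at_ub <- as.logical(bitwAnd(bitwShiftR(mask, seq_along(nonbasic) - 1L), 1L))
      vn <- ifelse(at_ub, ub[nonbasic], lb[nonbasic])
      if (any(!is.finite(vn))) next
      vb <- solve(B, -S[, nonbasic, drop = FALSE] %*% vn)
      v <- numeric(n); v[nonbasic] <- vn; v[basic] <- vb
      if (all(v >= lb - tol) && all(v <= ub + tol)) {
        best <- max(best, sum(obj * v))
      }
    }
  }
  best
}

# Truth of a GPR rule string via R's parser: an oracle independent of the
# package's recursive-descent parser and evaluator.
gpr_truth_oracle <- function(rule, state) {
  expr <- gsub("\\band\\b", "&", gsub("\\bor\\b", "|", rule, ignore.case = TRUE),
               ignore.case = TRUE)
  eval(parse(text = expr), envir = as.list(state))
}

# Random nested GPR rule over the given genes.
random_gpr_string <- function(genes, depth = 2) {
  if (depth == 0 || runif(1) < 0.35) return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  kids <- replicate(k, random_gpr_string(genes, depth - 1))
  paste0("(", paste(kids, collapse = paste0(" ", op, " ")), ")")
}

# Brute-force MILP oracle: enumerate binary assignments, solve the remaining
# LP by basic-solution enumeration.
brute_milp_max <- function(obj, A_eq, b_eq, A_le, b_le, lb, ub, binary_idx) {
  best <- -Inf
  nb <- length(binary_idx)
  for (mask in 0:(2^nb - 1)) {
    bits <- as.numeric(bitwAnd(bitwShiftR(mask, seq_len(nb) - 1L), 1L))
    lo <- lb; up <- ub
    lo[binary_idx] <- bits; up[binary_idx] <- bits
    sol <- metnet:::lp_solve(obj, A_eq = A_eq, b_eq = b_eq, A_le = A_le, b_le = b_le,
                             lower = lo, upper = up, maximize = TRUE)
    if (sol$status == "optimal") best <- max(best, sol$value)
  }
  best
}

# A tiny hand-rolled linear pathway model: A_e -> A_c -> biomass, optional
# second consuming route. Used where make_toy_model is the thing under test.
hand_linear_model <- function(uptake = 10, yield = 0.5) {
  mets <- data.frame(id = c("A_e", "A_c"), name = c("A ext", "A"),
                     compartment = c("e", "c"), boundary = FALSE)
  rxn <- data.frame(id = c("EX_A(e)", "At", "BIOMASS"),
                    name = c("A exchange", "A transport", "biomass"),
                    lb = c(-uptake, 0, 0), ub = c(0, 1000, 1000),
                    subsystem = "", objective = c(0, 0, 1))
  st <- list("EX_A(e)" = c(A_e = -1),
             "At" = c(A_e = -1, A_c = 1),
             "BIOMASS" = c(A_c = -1 / yield))
  metabolic_model("hand_linear", mets, rxn, st,
                  list("EX_A(e)" = NULL, "At" = NULL, "BIOMASS" = NULL))
}
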