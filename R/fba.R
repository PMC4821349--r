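#' Growth media as bound overrides
#'
#' A medium is a set of exchange-reaction bound overrides. Uptake of a
#' nutrient is a negative lower bound on its exchange reaction; the
#' convenience flags reproduce the aerobic glucose-minimal condition used for
#' strain-design simulations (glucose supply 20 mmol/gDW/h, oxygen uptake
#' opened).
#'
#' @param overrides data.frame with columns `reaction`, `lb`, `ub` (NA leaves
#'   a bound untouched), or NULL.
#' @param aerobic if TRUE, set the oxygen exchange lower bound to -1000.
#' @param oxygen_exchange,glucose_exchange exchange reaction ids used by the
#'   convenience flags.
#' @param glucose_uptake glucose supply rate (mmol/gDW/h); applied as a lower
#'   bound of `-glucose_uptake` when `glucose_exchange` is given.
#' @return a data.frame of class `medium_spec`.
#' @export
medium_spec <- function(overrides = NULL, aerobic = FALSE,
                        oxygen_exchange = NULL, glucose_exchange = NULL,
                        glucose_uptake = 20) {
  out <- if (is.null(overrides)) {
    data.frame(reaction = character(0), lb = numeric(0), ub = numeric(0))
  } else {
    stopifnot(all(c("reaction", "lb", "ub") %in% names(overrides)))
    overrides[, c("reaction", "lb", "ub")]
  }
  if (aerobic) {
    if (is.null(oxygen_exchange)) stop("aerobic medium needs oxygen_exchange id")
    out <- rbind(out, data.frame(reaction = oxygen_exchange, lb = -1000, ub = NA))
  }
  if (!is.null(glucose_exchange)) {
    out <- rbind(out, data.frame(reaction = glucose_exchange,
                                 lb = -glucose_uptake, ub = NA))
  }
  class(out) <- c("medium_spec", "data.frame")
  out
}

apply_medium <- function(model, medium) {
  if (is.null(medium)) return(model)
  unknown <- setdiff(medium$reaction, model$reactions$id)
  if (length(unknown))
    stop("medium refers to reactions absent from model: ",
         paste(unknown, collapse = ", "))
  for (i in seq_len(nrow(medium))) {
    j <- match(medium$reaction[i], model$reactions$id)
    if (!is.na(medium$lb[i])) model$reactions$lb[j] <- medium$lb[i]
    if (!is.na(medium$ub[i])) model$reactions$ub[j] <- medium$ub[i]
  }
  model
}

new_flux_distribution <- function(fluxes, objective_value, status,
                                  objective_reaction, extra = list()) {
  structure(c(list(fluxes = fluxes, objective_value = objective_value,
                   status = status, objective_reaction = objective_reaction),
              extra),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("Flux distribution (", x$status, ")\n", sep = "")
  cat("  objective [", x$objective_reaction, "]: ",
      format(x$objective_value, digits = 6), "\n", sep = "")
  if (!is.null(x$biomass)) cat("  biomass: ", format(x$biomass, digits = 6), "\n", sep = "")
  if (!is.null(x$product)) cat("  product: ", format(x$product, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the objective flux subject to steady-state mass balance
#' `S v = 0` (rows over non-boundary metabolites) and flux bounds, with
#' optional medium overrides. The optimal objective value is unique; the flux
#' vector is one optimal vertex.
#'
#' @param model a `metabolic_model`.
#' @param medium optional [medium_spec()] (or data.frame of overrides).
#' @param objective optional objective reaction id (default: the model's
#'   flagged objective, see [find_objective()]).
#' @param maximize maximize (default) or minimize the objective.
#' @return a `flux_distribution`: named `fluxes`, `objective_value`,
#'   `status` (`"optimal"`/`"infeasible"`), `objective_reaction`.
#' @examples
#' toy <- make_toy_model(n_branches = 2, branch_yields = c(0.5, 0.3))
#' solve_fba(toy$model)$objective_value   # 10 * 0.5 = 5
#' @export
solve_fba <- function(model, medium = NULL, objective = NULL, maximize = TRUE) {
  obj_rxn <- find_objective(model, objective)
  model <- apply_medium(model, medium)
  S <- stoich_matrix(model)
  n <- nrow(model$reactions)
  cvec <- numeric(n); cvec[match(obj_rxn, model$reactions$id)] <- 1
  sol <- lp_solve(cvec, A_eq = S, b_eq = rep(0, nrow(S)),
                  lower = model$reactions$lb, upper = model$reactions$ub,
                  maximize = maximize)
  if (sol$status != "optimal") {
    return(new_flux_distribution(NULL, NA_real_, sol$status, obj_rxn))
  }
  fluxes <- stats::setNames(sol$x, model$reactions$id)
  new_flux_distribution(fluxes, sol$value, "optimal", obj_rxn)
}

#' Lexicographic product optimization
#'
#' Two-stage LP used to score strain designs: (1) maximize biomass;
#' (2) fix biomass at its optimum — or at `growth_floor` times the optimum —
#' and maximize the product flux. Both stage values are recorded, matching
#' the paired product/biomass reporting convention of knockout-design tables.
#'
#' @param model a `metabolic_model`.
#' @param medium optional medium overrides.
#' @param product_reaction id of the product (usually an exchange) reaction.
#' @param growth_floor optional fraction in (0, 1]; when given, stage 2
#'   requires biomass >= `growth_floor` x optimum rather than fixing it.
#' @param objective optional biomass reaction id.
#' @return a `flux_distribution` from stage 2 with fields `biomass` and
#'   `product`; on stage failure, `status` reports which stage was
#'   infeasible.
#' @export
lex_maximize_product <- function(model, medium = NULL, product_reaction,
                                 growth_floor = NULL, objective = NULL) {
  if (!product_reaction %in% model$reactions$id)
    stop("product reaction not in model: ", product_reaction)
  obj_rxn <- find_objective(model, objective)
  model <- apply_medium(model, medium)
  stage1 <- solve_fba(model, objective = obj_rxn)
  if (stage1$status != "optimal") {
    return(new_flux_distribution(NULL, NA_real_, "infeasible_biomass_stage", product_reaction,
                                 extra = list(biomass = NA_real_, product = NA_real_)))
  }
  mu <- stage1$objective_value
  j <- match(obj_rxn, model$reactions$id)
  if (is.null(growth_floor)) {
    model$reactions$lb[j] <- mu
    model$reactions$ub[j] <- mu
  } else {
    stopifnot(growth_floor > 0, growth_floor <= 1)
    model$reactions$lb[j] <- growth_floor * mu
  }
  stage2 <- solve_fba(model, objective = product_reaction)
  if (stage2$status != "optimal") {
    return(new_flux_distribution(NULL, NA_real_, "infeasible_product_stage", product_reaction,
                                 extra = list(biomass = mu, product = NA_real_)))
  }
  new_flux_distribution(stage2$fluxes, stage2$objective_value, "optimal",
                        product_reaction,
                        extra = list(biomass = unname(stage2$fluxes[obj_rxn]),
                                     product = stage2$objective_value))
}

#' Parsimonious wild-type flux reference
#'
#' FBA optimum followed by minimization of total absolute flux at fixed
#' optimal biomass. Serves as the reproducible wild-type reference for
#' [solve_lmoma()]: plain FBA optima are degenerate, and the minimal-flux
#' tie-break pins down one canonical point.
#'
#' @inheritParams solve_fba
#' @return a `flux_distribution` at optimal biomass with minimal total |v|.
#' @export
wildtype_reference <- function(model, medium = NULL, objective = NULL) {
  obj_rxn <- find_objective(model, objective)
  model <- apply_medium(model, medium)
  stage1 <- solve_fba(model, objective = obj_rxn)
  if (stage1$status != "optimal") return(stage1)
  mu <- stage1$objective_value
  j <- match(obj_rxn, model$reactions$id)
  model$reactions$lb[j] <- mu; model$reactions$ub[j] <- mu
  S <- stoich_matrix(model)
  n <- nrow(model$reactions)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  amax <- pmax(abs(lb), abs(ub))
  ## vars: v (n), a (n) with a >= |v|; minimize sum a
  A_eq <- cbind(S, matrix(0, nrow(S), n))
  A_le <- rbind(cbind(diag(n), -diag(n)),    #  v - a <= 0
                cbind(-diag(n), -diag(n)))   # -v - a <= 0
  sol <- lp_solve(c(rep(0, n), rep(1, n)),
                  A_eq = A_eq, b_eq = rep(0, nrow(S)),
                  A_le = A_le, b_le = rep(0, 2 * n),
                  lower = c(lb, rep(0, n)), upper = c(ub, amax),
                  maximize = FALSE)
  if (sol$status != "optimal")
    stop("parsimonious reference failed: ", sol$status)
  fluxes <- stats::setNames(sol$x[seq_len(n)], model$reactions$id)
  new_flux_distribution(fluxes, mu, "optimal", obj_rxn,
                        extra = list(total_flux = sol$value))
}

#' Linearized minimization of metabolic adjustment (lMOMA)
#'
#' Finds the mutant flux distribution closest (in L1 distance) to a wild-type
#' reference, subject to mass balance, bounds and zero flux through the
#' knocked-out reactions. The mutant is not assumed to re-optimize growth;
#' its biomass flux is read off the minimally adjusted distribution.
#'
#' @param model a `metabolic_model`.
#' @param wildtype_flux a `flux_distribution` covering all model reactions
#'   (see [wildtype_reference()]).
#' @param knockout_reactions reaction ids forced to zero flux.
#' @param medium optional medium overrides.
#' @return a `flux_distribution` with `objective_value` = L1 distance and
#'   extra fields `growth` (biomass flux; 0 when infeasible) and `distance`.
#' @export
solve_lmoma <- function(model, wildtype_flux, knockout_reactions = character(0),
                        medium = NULL) {
  model <- apply_medium(model, medium)
  wt <- wildtype_flux$fluxes
  if (!all(model$reactions$id %in% names(wt)))
    stop("wild-type flux does not cover all model reactions")
  wt <- wt[model$reactions$id]
  obj_rxn <- wildtype_flux$objective_reaction
  unknown <- setdiff(knockout_reactions, model$reactions$id)
  if (length(unknown)) stop("unknown knockout reactions: ", paste(unknown, collapse = ", "))
  ko <- model$reactions$id %in% knockout_reactions
  lb <- model$reactions$lb; ub <- model$reactions$ub
  lb[ko] <- 0; ub[ko] <- 0
  S <- stoich_matrix(model)
  n <- nrow(model$reactions)
  dmax <- pmax(abs(lb - wt), abs(ub - wt)) + 1
  ## vars: v, d with d >= |v - wt|; minimize sum d
  A_eq <- cbind(S, matrix(0, nrow(S), n))
  A_le <- rbind(cbind(diag(n), -diag(n)),    #  v - d <= wt
                cbind(-diag(n), -diag(n)))   # -v - d <= -wt
  sol <- lp_solve(c(rep(0, n), rep(1, n)),
                  A_eq = A_eq, b_eq = rep(0, nrow(S)),
                  A_le = A_le, b_le = c(wt, -wt),
                  lower = c(lb, rep(0, n)), upper = c(ub, dmax),
                  maximize = FALSE)
  if (sol$status != "optimal") {
    return(new_flux_distribution(NULL, NA_real_, "infeasible", obj_rxn,
                                 extra = list(growth = 0, distance = NA_real_)))
  }
  fluxes <- stats::setNames(sol$x[seq_len(n)], model$reactions$id)
  new_flux_distribution(fluxes, sol$value, "optimal", obj_rxn,
                        extra = list(growth = unname(fluxes[obj_rxn]),
                                     distance = sol$value))
}

#' Feasible flux range of one reaction
#'
#' Flux-variability bounds: minimum and maximum flux the reaction can carry
#' under mass balance and bounds (no objective constraint).
#'
#' @inheritParams solve_fba
#' @param reaction reaction id.
#' @return numeric `c(min, max)`.
#' @export
flux_range <- function(model, reaction, medium = NULL) {
  if (!reaction %in% model$reactions$id) stop("unknown reaction: ", reaction)
  lo <- solve_fba(model, medium = medium, objective = reaction, maximize = FALSE)
  hi <- solve_fba(model, medium = medium, objective = reaction, maximize = TRUE)
  if (lo$status != "optimal" || hi$status != "optimal")
    stop("flux range undefined (", lo$status, "/", hi$status, ") for ", reaction)
  c(lo$objective_value, hi$objective_value)
}

#' Robustness analysis
#'
#' Scans growth as a function of the flux forced through one reaction: for
#' each point of an even grid over the reaction's feasible flux range, the
#' reaction is fixed at that value and biomass is re-maximized. This is the
#' standard diagnostic for haploinsufficiency-like behaviour — a flat profile
#' means the network reroutes around the restriction, a steep one means
#' growth depends on the reaction's flux.
#'
#' @inheritParams solve_fba
#' @param reaction reaction id to scan.
#' @param n_points number of grid points (>= 2; a blocked reaction with a
#'   degenerate range yields a single point).
#' @return data.frame with columns `forced_flux` and `biomass` (NA where the
#'   forced value is infeasible).
#' @export
robustness_scan <- function(model, reaction, n_points = 20, medium = NULL) {
  stopifnot(n_points >= 2)
  model <- apply_medium(model, medium)
  obj_rxn <- find_objective(model)
  rng <- flux_range(model, reaction)
  grid <- if (diff(rng) < 1e-9) rng[1] else seq(rng[1], rng[2], length.out = n_points)
  j <- match(reaction, model$reactions$id)
  biomass <- vapply(grid, function(t) {
    m <- model
    m$reactions$lb[j] <- t; m$reactions$ub[j] <- t
    s <- solve_fba(m, objective = obj_rxn)
    if (s$status == "optimal") s$objective_value else NA_real_
  }, numeric(1))
  data.frame(forced_flux = grid, biomass = biomass)
}
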