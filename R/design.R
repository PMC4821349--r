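#' Strain-design configuration
#'
#' Parameters of knockout design for product overproduction. Defaults follow
#' common practice for local-search designs: neighborhood size 2, at most 5
#' knockouts, minimum growth 0.05 mmol/gDW/h.
#'
#' @param product_reaction id of the target (usually exchange) reaction.
#' @param neighborhood_size k, the maximum number of knockout changes per
#'   local-search move (1 <= k <= max_knockouts).
#' @param max_knockouts K, the knockout budget.
#' @param min_growth minimal acceptable biomass flux for a design.
#' @param medium optional [medium_spec()] applied before scoring.
#' @param candidates knockout candidate reaction ids; default: every
#'   non-exchange, non-objective reaction. Exchange reactions may be added
#'   explicitly (nutrient exchanges are legitimate knockout targets).
#' @return list of class `design_config`.
#' @export
design_config <- function(product_reaction, neighborhood_size = 2,
                          max_knockouts = 5, min_growth = 0.05,
                          medium = NULL, candidates = NULL) {
  stopifnot(neighborhood_size >= 1, min_growth >= 0)
  if (max_knockouts > 0 && neighborhood_size > max_knockouts)
    stop("neighborhood_size must not exceed max_knockouts")
  structure(list(product_reaction = product_reaction,
                 neighborhood_size = neighborhood_size,
                 max_knockouts = max_knockouts,
                 min_growth = min_growth,
                 medium = medium,
                 candidates = candidates),
            class = "design_config")
}

resolve_candidates <- function(model, config) {
  if (!is.null(config$candidates)) {
    unknown <- setdiff(config$candidates, model$reactions$id)
    if (length(unknown)) stop("unknown candidate reactions: ",
                              paste(unknown, collapse = ", "))
    return(sort(config$candidates))
  }
  obj <- find_objective(model)
  sort(setdiff(model$reactions$id,
               c(exchange_reactions(model), obj, config$product_reaction)))
}

#' Evaluate a knockout design
#'
#' Zeroes both bounds of every knocked-out reaction, applies the medium, and
#' scores the design by lexicographic FBA ([lex_maximize_product()]): biomass
#' first, then product at the biomass optimum. A design whose biomass falls
#' below the growth floor (or that is infeasible) is flagged infeasible with
#' biomass and product reported as 0.
#'
#' @param model a `metabolic_model`.
#' @param knockouts reaction ids to delete (set; order irrelevant).
#' @param config a [design_config()].
#' @return list of class `design_result`: `knockouts`, `biomass`, `product`,
#'   `feasible`.
#' @export
evaluate_design <- function(model, knockouts, config) {
  knockouts <- normalize_reaction_ids(knockouts, model$reactions$id)
  ko <- model$reactions$id %in% knockouts
  model$reactions$lb[ko] <- 0
  model$reactions$ub[ko] <- 0
  sol <- lex_maximize_product(model, medium = config$medium,
                              product_reaction = config$product_reaction)
  biomass <- if (is.na(sol$biomass)) 0 else sol$biomass
  product <- if (is.null(sol$product) || is.na(sol$product)) 0 else sol$product
  feasible <- sol$status == "optimal" && biomass >= config$min_growth - 1e-9
  structure(list(knockouts = sort(knockouts),
                 biomass = if (feasible) biomass else if (sol$status == "optimal") biomass else 0,
                 product = if (sol$status == "optimal") product else 0,
                 feasible = feasible),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("Design:", if (length(x$knockouts)) paste(x$knockouts, collapse = ", ") else "(none)", "\n")
  cat(sprintf("  biomass %.4g  product %.4g  %s\n", x$biomass, x$product,
              if (x$feasible) "feasible" else "INFEASIBLE"))
  invisible(x)
}

#' Match printed reaction ids against a model
#'
#' Published knockout lists often typeset ids loosely ("GLYt2 m" for
#' "GLYt2m"); this helper resolves ids case-insensitively after stripping
#' spaces, and errors on anything it cannot match.
#'
#' @param ids character vector of (possibly loosely printed) reaction ids.
#' @param universe the model's reaction ids.
#' @return the matched ids from `universe`.
#' @export
normalize_reaction_ids <- function(ids, universe) {
  if (!length(ids)) return(character(0))
  key <- function(x) tolower(gsub("[[:space:]]", "", x))
  m <- match(key(ids), key(universe))
  if (anyNA(m)) stop("unknown reaction id(s): ", paste(ids[is.na(m)], collapse = ", "))
  universe[m]
}

#' Local-search knockout design (GDLS-style)
#'
#' Iterative bounded local search for a knockout set maximizing product
#' synthesis: starting from no knockouts, each round scores every candidate
#' set within `neighborhood_size` changes (additions, removals or swaps) of
#' the incumbent — subject to the knockout budget and the growth floor — and
#' moves to the best product improvement. Search stops at a local optimum.
#' Ties break deterministically: fewer knockouts first, then lexicographic
#' id order. A single search path is followed.
#'
#' @param model a `metabolic_model`.
#' @param config a [design_config()].
#' @return a `design_result` with an extra `trajectory` data.frame
#'   (iteration, knockout set, product).
#' @export
gdls_search <- function(model, config) {
  if (!config$product_reaction %in% model$reactions$id)
    stop("product reaction not in model: ", config$product_reaction)
  candidates <- resolve_candidates(model, config)
  k <- config$neighborhood_size; K <- config$max_knockouts

  cache <- new.env(parent = emptyenv())
  score <- function(set) {
    keyv <- paste0("k:", paste(sort(set), collapse = "|"))
    hit <- cache[[keyv]]
    if (!is.null(hit)) return(hit)
    r <- evaluate_design(model, set, config)
    cache[[keyv]] <- r
    r
  }

  incumbent <- score(character(0))
  if (!incumbent$feasible)
    stop("no feasible starting design: wild type violates the growth floor")
  traj <- data.frame(iteration = 0L, knockouts = "", product = incumbent$product,
                     stringsAsFactors = FALSE)
  if (K == 0) {
    incumbent$trajectory <- traj
    return(incumbent)
  }

  iter <- 0L
  repeat {
    iter <- iter + 1L
    cur <- incumbent$knockouts
    neighbors <- neighbor_sets(cur, candidates, k, K)
    best <- incumbent
    for (set in neighbors) {
      r <- score(set)
      if (!r$feasible) next
      if (r$product > best$product + 1e-9 ||
          (abs(r$product - best$product) <= 1e-9 && better_tiebreak(r, best))) {
        best <- r
      }
    }
    if (best$product <= incumbent$product + 1e-9) break
    incumbent <- best
    traj <- rbind(traj, data.frame(iteration = iter,
                                   knockouts = paste(incumbent$knockouts, collapse = ","),
                                   product = incumbent$product,
                                   stringsAsFactors = FALSE))
  }
  incumbent$trajectory <- traj
  incumbent
}

better_tiebreak <- function(a, b) {
  if (length(a$knockouts) != length(b$knockouts))
    return(length(a$knockouts) < length(b$knockouts))
  paste(a$knockouts, collapse = ",") < paste(b$knockouts, collapse = ",")
}

## all sets within `k` changes of `cur`, respecting the budget K
neighbor_sets <- function(cur, candidates, k, K) {
  out <- list()
  outside <- setdiff(candidates, cur)
  for (n_rm in 0:min(k, length(cur))) {
    rm_sets <- if (n_rm == 0) list(character(0)) else
      utils::combn(cur, n_rm, simplify = FALSE)
    for (rs in rm_sets) {
      base <- setdiff(cur, rs)
      max_add <- min(k - n_rm, K - length(base), length(outside))
      for (n_add in 0:max_add) {
        add_sets <- if (n_add == 0) list(character(0)) else
          utils::combn(outside, n_add, simplify = FALSE)
        for (as_ in add_sets) {
          cand <- sort(c(base, as_))
          if (length(cand) || length(cur)) out[[length(out) + 1]] <- cand
        }
      }
    }
  }
  unique(out)
}
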