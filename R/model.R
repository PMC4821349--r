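#' Construct a genome-scale metabolic model
#'
#' The central container of the package: a stoichiometric network with flux
#' bounds, gene-protein-reaction (GPR) rules and an objective (typically a
#' biomass pseudo-reaction whose flux proxies growth rate). The gene set is
#' always derived as the union of GPR leaves, never stored independently.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   and logical `boundary` (TRUE marks an external/boundary species that is
#'   excluded from mass-balance rows).
#' @param reactions data.frame with columns `id`, `name`, `lb`, `ub`
#'   (flux bounds, mmol/gDW/h), `subsystem`, `objective` (objective
#'   coefficient, usually 0 or 1).
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector of signed coefficients over metabolite ids (negative =
#'   consumed).
#' @param gpr named list of GPR trees (see [parse_gpr()]), one per reaction
#'   id; entries may be NULL (no gene association).
#' @return an object of class `metabolic_model`.
#' @seealso [read_model()], [validate_model()], [solve_fba()]
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry, gpr) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$boundary)) {
    metabolites$boundary <- grepl("_b$", metabolites$id)
  }
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  if (is.null(reactions$objective)) reactions$objective <- 0
  gpr <- gpr[reactions$id]
  names(gpr) <- reactions$id
  stoichiometry <- stoichiometry[reactions$id]
  m <- structure(list(id = id,
                      metabolites = metabolites,
                      reactions = reactions,
                      stoichiometry = stoichiometry,
                      gpr = gpr),
                 class = "metabolic_model")
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model:", x$id, "\n")
  cat("  metabolites:", nrow(x$metabolites),
      sprintf("(%d boundary)", sum(x$metabolites$boundary)), "\n")
  cat("  reactions:  ", nrow(x$reactions), "\n")
  cat("  genes:      ", length(model_genes(x)), "\n")
  obj <- x$reactions$id[x$reactions$objective != 0]
  if (length(obj)) cat("  objective:  ", paste(obj, collapse = ", "), "\n")
  invisible(x)
}

#' Model accessors
#'
#' @param model a `metabolic_model`.
#' @return `model_genes`: character vector of all gene ids appearing in GPR
#'   rules (the model's derived gene set).
#' @export
model_genes <- function(model) {
  sort(unique(unlist(lapply(model$gpr, gpr_genes))))
}

#' @rdname model_genes
#' @return `stoich_matrix`: dense stoichiometric matrix S with one row per
#'   non-boundary metabolite and one column per reaction; `S v = 0` is the
#'   steady-state mass balance.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id[!model$metabolites$boundary]
  S <- matrix(0, length(mets), nrow(model$reactions),
              dimnames = list(mets, model$reactions$id))
  for (j in seq_along(model$stoichiometry)) {
    st <- model$stoichiometry[[j]]
    keep <- names(st) %in% mets
    if (any(keep)) S[names(st)[keep], j] <- st[keep]
  }
  S
}

#' @rdname model_genes
#' @return `exchange_reactions`: ids of boundary/exchange reactions — those
#'   touching at most one non-boundary metabolite, plus anything with the
#'   conventional `EX_` prefix. Uptake is a negative lower bound on these.
#' @export
exchange_reactions <- function(model) {
  mets <- model$metabolites$id[!model$metabolites$boundary]
  n_int <- vapply(model$stoichiometry, function(st) sum(names(st) %in% mets), integer(1))
  model$reactions$id[n_int <= 1L | grepl("^EX_", model$reactions$id)]
}

#' Resolve the model objective reaction
#'
#' Uses the reaction with a non-zero objective coefficient; if none is
#' flagged, falls back to the unique reaction whose id contains "biomass"
#' (case-insensitive). Errors when the choice is absent or ambiguous.
#'
#' @param model a `metabolic_model`.
#' @param objective optional explicit reaction id overriding the default.
#' @return a reaction id.
#' @export
find_objective <- function(model, objective = NULL) {
  if (!is.null(objective)) {
    if (!objective %in% model$reactions$id)
      stop("objective reaction not in model: ", objective)
    return(objective)
  }
  flagged <- model$reactions$id[model$reactions$objective != 0]
  if (length(flagged) == 1L) return(flagged)
  if (length(flagged) > 1L)
    stop("multiple reactions carry objective coefficients: ",
         paste(flagged, collapse = ", "))
  bio <- model$reactions$id[grepl("biomass", model$reactions$id, ignore.case = TRUE)]
  if (length(bio) == 1L) return(bio)
  if (length(bio) == 0L) stop("no objective flagged and no 'biomass' reaction found")
  stop("no objective flagged and multiple 'biomass' reactions: ",
       paste(bio, collapse = ", "))
}

#' Validate a metabolic model
#'
#' Checks structural invariants and reports violations without throwing:
#' unique non-empty ids, non-empty compartments, ordered bounds, stoichiometry
#' referring only to declared metabolites, at most one objective reaction.
#'
#' @param model a `metabolic_model`.
#' @param allow_multiple_objectives if TRUE, skip the single-objective check.
#' @return character vector of violation messages; empty when the model is
#'   valid.
#' @export
validate_model <- function(model, allow_multiple_objectives = FALSE) {
  v <- character(0)
  met <- model$metabolites; rxn <- model$reactions
  if (anyDuplicated(met$id))
    v <- c(v, paste0("duplicate metabolite id: ",
                     paste(unique(met$id[duplicated(met$id)]), collapse = ", ")))
  if (anyDuplicated(rxn$id))
    v <- c(v, paste0("duplicate reaction id: ",
                     paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", ")))
  if (any(!nzchar(met$id))) v <- c(v, "empty metabolite id")
  if (any(!nzchar(rxn$id))) v <- c(v, "empty reaction id")
  bad_comp <- met$id[!nzchar(trimws(met$compartment))]
  for (id in bad_comp) v <- c(v, paste0("metabolite ", id, ": empty compartment"))
  bad_b <- rxn$id[rxn$lb > rxn$ub]
  for (id in bad_b) v <- c(v, paste0("reaction ", id, ": lower bound exceeds upper bound"))
  for (id in rxn$id) {
    st <- model$stoichiometry[[id]]
    if (is.null(st)) { v <- c(v, paste0("reaction ", id, ": missing stoichiometry")); next }
    unknown <- setdiff(names(st), met$id)
    for (u in unknown)
      v <- c(v, paste0("reaction ", id, ": stoichiometry references undeclared metabolite ", u))
  }
  n_obj <- sum(rxn$objective != 0)
  if (n_obj > 1L && !allow_multiple_objectives)
    v <- c(v, paste0(n_obj, " reactions carry non-zero objective coefficients"))
  v
}

#' Structural diff of two models
#'
#' Compares id sets, stoichiometries, bounds (within tolerance) and GPR rules
#' (as boolean functions, via [gpr_equivalent()]).
#'
#' @param a,b `metabolic_model` objects.
#' @param bound_tol tolerance for bound comparison.
#' @return a list of class `model_diff` with components
#'   `reactions_only_in_a/b`, `metabolites_only_in_a/b`, `genes_only_in_a/b`,
#'   `bound_diffs`, `stoich_diffs`, `gpr_diffs` (shared reactions that
#'   differ). Use [model_diff_is_empty()] to test structural equivalence.
#' @export
compare_models <- function(a, b, bound_tol = 1e-6) {
  shared <- intersect(a$reactions$id, b$reactions$id)
  bnd <- character(0); stc <- character(0); gpd <- character(0)
  la <- a$reactions[match(shared, a$reactions$id), ]
  lbb <- b$reactions[match(shared, b$reactions$id), ]
  for (i in seq_along(shared)) {
    id <- shared[i]
    if (abs(la$lb[i] - lbb$lb[i]) > bound_tol || abs(la$ub[i] - lbb$ub[i]) > bound_tol)
      bnd <- c(bnd, id)
    sa <- a$stoichiometry[[id]]; sb <- b$stoichiometry[[id]]
    sa <- sa[order(names(sa))]; sb <- sb[order(names(sb))]
    if (!identical(names(sa), names(sb)) || any(abs(sa - sb) > bound_tol))
      stc <- c(stc, id)
    if (!gpr_equivalent(a$gpr[[id]], b$gpr[[id]])) gpd <- c(gpd, id)
  }
  structure(list(
    reactions_only_in_a = setdiff(a$reactions$id, b$reactions$id),
    reactions_only_in_b = setdiff(b$reactions$id, a$reactions$id),
    metabolites_only_in_a = setdiff(a$metabolites$id, b$metabolites$id),
    metabolites_only_in_b = setdiff(b$metabolites$id, a$metabolites$id),
    genes_only_in_a = setdiff(model_genes(a), model_genes(b)),
    genes_only_in_b = setdiff(model_genes(b), model_genes(a)),
    bound_diffs = bnd, stoich_diffs = stc, gpr_diffs = gpd
  ), class = "model_diff")
}

#' @rdname compare_models
#' @param diff a `model_diff`.
#' @return TRUE when the diff records no differences.
#' @export
model_diff_is_empty <- function(diff) all(lengths(unclass(diff)) == 0L)

#' @export
print.model_diff <- function(x, ...) {
  if (model_diff_is_empty(x)) {
    cat("Models are structurally equivalent.\n")
  } else {
    for (nm in names(x)) if (length(x[[nm]]))
      cat(nm, ": ", paste(x[[nm]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Restrict a model to a subset of reactions
#'
#' Drops the complement of `keep_reactions`, then prunes metabolites that no
#' longer occur in any reaction. The gene set shrinks automatically since it
#' is derived from the remaining GPR rules.
#'
#' @param model a `metabolic_model`.
#' @param keep_reactions reaction ids to retain.
#' @return the sub-model.
#' @export
subset_model <- function(model, keep_reactions) {
  stopifnot(all(keep_reactions %in% model$reactions$id))
  keep <- model$reactions$id %in% keep_reactions
  rxn <- model$reactions[keep, , drop = FALSE]
  st <- model$stoichiometry[rxn$id]
  used <- unique(unlist(lapply(st, names)))
  met <- model$metabolites[model$metabolites$id %in% used, , drop = FALSE]
  metabolic_model(model$id, met, rxn, st, model$gpr[rxn$id])
}
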