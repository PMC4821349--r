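#' Reactions disabled by a gene deletion
#'
#' A reaction is disabled when its GPR rule evaluates FALSE with the deleted
#' genes set to FALSE and every other gene TRUE: a gene used by several
#' reactions takes all of them down, while isoenzymes ("or") keep a reaction
#' alive under single deletions. Reactions without gene association are never
#' disabled. Unknown genes are ignored.
#'
#' @param model a `metabolic_model`.
#' @param deleted_genes character vector of gene ids.
#' @return character vector of disabled reaction ids.
#' @export
reactions_disabled_by <- function(model, deleted_genes) {
  if (!length(deleted_genes)) return(character(0))
  state <- stats::setNames(rep(FALSE, length(deleted_genes)), deleted_genes)
  hit <- vapply(model$gpr, function(g) {
    if (is.null(g) || !any(gpr_genes(g) %in% deleted_genes)) return(FALSE)
    !gpr_eval(g, state)
  }, logical(1))
  model$reactions$id[hit]
}

classify_growth <- function(growth, wt_growth, growth_zero_tol = 1e-6,
                            unchanged_frac = 0.999) {
  ratio <- if (wt_growth > 0) growth / wt_growth else NA_real_
  phen <- if (growth <= growth_zero_tol) "no_growth"
          else if (!is.na(ratio) && ratio > unchanged_frac) "unchanged"
          else "reduced"
  list(ratio = ratio, phenotype = phen)
}

#' Single-gene deletion screen
#'
#' Deletes each model gene in turn: both bounds of every reaction disabled by
#' the deletion (per [reactions_disabled_by()]) are set to zero and growth is
#' recomputed, either by re-optimizing biomass (`method = "fba"`) or by the
#' minimal L1 adjustment from a parsimonious wild-type reference
#' (`method = "lmoma"`, see [solve_lmoma()]). Phenotypes follow the
#' three-class scheme: `no_growth` (growth <= `growth_zero_tol`), `unchanged`
#' (mutant above 99.9\% of the wild-type rate) and `reduced` (in between).
#' "Lethal" in the classical summary sense corresponds to `no_growth`;
#' `reduced` and `unchanged` genes are non-lethal.
#'
#' @param model a `metabolic_model`.
#' @param method `"fba"` or `"lmoma"`.
#' @param medium optional medium overrides.
#' @param growth_zero_tol absolute growth below which a mutant counts as
#'   non-growing (LP noise floor).
#' @return data.frame of class `deletion_screen` with columns `gene`,
#'   `n_disabled`, `growth`, `growth_ratio`, `phenotype`, plus attributes
#'   `wild_type_growth` and `method`. Infeasible mutants score growth 0.
#' @examples
#' toy <- make_toy_model(gpr_scheme = "simple")
#' screen <- single_gene_deletion_screen(toy$model)
#' table(screen$phenotype)
#' @export
single_gene_deletion_screen <- function(model, method = c("fba", "lmoma"),
                                        medium = NULL, growth_zero_tol = 1e-6) {
  method <- match.arg(method)
  model <- apply_medium(model, medium)
  genes <- model_genes(model)
  if (!length(genes)) stop("model has no genes to delete")
  obj_rxn <- find_objective(model)
  wt <- if (method == "lmoma") wildtype_reference(model) else solve_fba(model)
  if (wt$status != "optimal") stop("wild-type optimization failed: ", wt$status)
  wt_growth <- if (method == "lmoma") unname(wt$fluxes[obj_rxn]) else wt$objective_value

  res <- lapply(genes, function(g) {
    dis <- reactions_disabled_by(model, g)
    if (!length(dis)) {
      growth <- wt_growth
    } else if (method == "fba") {
      m <- model
      ko <- m$reactions$id %in% dis
      m$reactions$lb[ko] <- 0; m$reactions$ub[ko] <- 0
      s <- solve_fba(m, objective = obj_rxn)
      growth <- if (s$status == "optimal") s$objective_value else 0
    } else {
      s <- solve_lmoma(model, wt, knockout_reactions = dis)
      growth <- if (s$status == "optimal") s$growth else 0
    }
    cl <- classify_growth(growth, wt_growth, growth_zero_tol)
    data.frame(gene = g, n_disabled = length(dis), growth = growth,
               growth_ratio = cl$ratio, phenotype = cl$phenotype,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "wild_type_growth") <- wt_growth
  attr(out, "method") <- method
  class(out) <- c("deletion_screen", "data.frame")
  out
}

#' Essentiality confusion statistics
#'
#' Compares in-silico deletion phenotypes with an experimental essential-gene
#' reference. Predicted growth means phenotype other than `no_growth`; a gene
#' absent from the reference list counts as inessential. Following the
#' screening convention: TP = growth predicted for an inessential gene,
#' FN = no growth predicted for an inessential gene, FP = growth predicted
#' for an essential gene, TN = no growth predicted for an essential gene.
#' Sensitivity = 100 TP/(TP+FN); positive predictive value = 100 TP/(TP+FP).
#'
#' @param results a `deletion_screen` (or data.frame with `gene` and
#'   `phenotype`).
#' @param essential_reference character vector of essential gene ids (e.g.
#'   read with one systematic name per line from a deletion-project list).
#' @return list of class `confusion_summary`: `tp`, `fn`, `fp`, `tn`,
#'   `sensitivity`, `ppv` (percentages; NA when undefined).
#' @export
confusion_vs_reference <- function(results, essential_reference) {
  if (!nrow(results)) stop("empty deletion results")
  growth <- results$phenotype != "no_growth"
  essential <- results$gene %in% essential_reference
  tp <- sum(growth & !essential)
  fn <- sum(!growth & !essential)
  fp <- sum(growth & essential)
  tn <- sum(!growth & essential)
  structure(list(
    tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  ), class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  FP %d  TN %d\n", x$tp, x$fn, x$fp, x$tn))
  cat(sprintf("sensitivity %.1f%%  PPV %.1f%%\n", x$sensitivity, x$ppv))
  invisible(x)
}

#' Read an essential-gene list
#'
#' Plain text, one systematic gene name per line; blank lines and `#`
#' comments are skipped.
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_essential_genes <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
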