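#' Read BLAST tabular homology hits
#'
#' Parses BLAST outfmt-6 tables (qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore). Species and
#' assembly-strategy annotations are supplied per file, following the
#' one-table-per-(species, strategy) convention of transcriptome searches.
#'
#' @param path tabular BLAST output file.
#' @param species species label for every hit in the file.
#' @param strategy assembly strategy label (e.g. `"genome_guided"`,
#'   `"de_novo"`).
#' @return data.frame of class `homology_hits`.
#' @export
read_blast_hits <- function(path, species, strategy) {
  cols <- c("query", "subject", "identity", "align_length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 12) stop("expected >= 12 BLAST outfmt 6 columns in ", path)
  x <- x[, 1:12]
  names(x) <- cols
  out <- x[, c("query", "subject", "identity", "align_length", "evalue", "bitscore")]
  out$species <- species
  out$strategy <- strategy
  class(out) <- c("homology_hits", "data.frame")
  out
}

#' Per-species gene presence calls from homology hits
#'
#' A gene counts as present in a (species, strategy) cell when it has at
#' least one hit with e-value at or below the threshold; merged presence is
#' the OR across strategies (a transcript found by either the genome-guided
#' or the de-novo route is evidence either way). Duplicated hits change
#' nothing.
#'
#' @param hits a `homology_hits` data.frame (rows may mix species and
#'   strategies; columns `query`, `evalue`, `species`, `strategy`).
#' @param evalue_max e-value threshold (default 1e-4, the conventional
#'   transcript-mapping cutoff).
#' @param genes,species optional universes; default to the values observed
#'   in `hits`. Genes without qualifying hits are absent everywhere.
#' @return object of class `evidence_table`: list with `merged` (logical
#'   gene x species matrix) and `by_strategy` (named list of such matrices).
#' @export
presence_calls <- function(hits, evalue_max = 1e-4, genes = NULL, species = NULL) {
  if (is.null(genes)) genes <- sort(unique(hits$query))
  if (is.null(species)) species <- sort(unique(hits$species))
  strategies <- sort(unique(hits$strategy))
  if (!length(strategies)) strategies <- "default"
  empty <- matrix(FALSE, length(genes), length(species),
                  dimnames = list(genes, species))
  by_strategy <- stats::setNames(rep(list(empty), length(strategies)), strategies)
  ok <- hits$evalue <= evalue_max & hits$query %in% genes & hits$species %in% species
  h <- hits[ok, , drop = FALSE]
  for (i in seq_len(nrow(h))) {
    by_strategy[[h$strategy[i]]][h$query[i], h$species[i]] <- TRUE
  }
  merged <- Reduce(`|`, by_strategy, empty)
  structure(list(merged = merged, by_strategy = by_strategy,
                 evalue_max = evalue_max),
            class = "evidence_table")
}

#' @export
print.evidence_table <- function(x, ...) {
  cat("Evidence table:", nrow(x$merged), "genes x", ncol(x$merged), "species;",
      "strategies:", paste(names(x$by_strategy), collapse = ", "), "\n")
  cat("present calls (merged):", sum(x$merged), "\n")
  invisible(x)
}

#' Consensus gene set across species
#'
#' Genes whose merged presence is TRUE in every listed species — the
#' intersection that defines the consensus metabolic gene set.
#'
#' @param evidence an [presence_calls()] `evidence_table`.
#' @param species species to intersect over (default: all columns).
#' @return character vector of gene ids.
#' @export
consensus_gene_set <- function(evidence, species = NULL) {
  m <- evidence$merged
  if (is.null(species)) species <- colnames(m)
  if (!length(species)) stop("need at least one species")
  missing <- setdiff(species, colnames(m))
  if (length(missing)) stop("species without evidence columns: ",
                            paste(missing, collapse = ", "))
  rownames(m)[rowSums(m[, species, drop = FALSE]) == length(species)]
}

#' Map gene expression onto reactions through GPR rules
#'
#' "and" (complex) nodes take the minimum of their children, "or"
#' (isoenzyme) nodes the maximum. Reactions without gene association, and
#' genes missing from `gene_values`, are unevidenced and score `Inf`: they
#' are never treated as poorly expressed, so extraction keeps them unless
#' flux analysis removes them.
#'
#' @param model a `metabolic_model`.
#' @param gene_values named numeric vector of per-gene expression.
#' @return named numeric vector, one score per reaction.
#' @export
map_reaction_expression <- function(model, gene_values) {
  vapply(model$gpr, gpr_value, numeric(1), values = gene_values)
}

#' Extraction configuration
#'
#' Parameters of expression-guided model extraction. The expression threshold
#' defaults to the median finite reaction score; the functionality
#' requirement keeps 90\% of the optimal biomass.
#'
#' @param expression_threshold GIMME threshold T (NULL = median of finite
#'   reaction scores at run time).
#' @param required_fraction fraction f of the optimal biomass the extracted
#'   model must sustain, in (0, 1].
#' @param imat_low,imat_high quantiles splitting reactions into
#'   low/moderate/high expression classes.
#' @param activity_epsilon minimum flux (mmol/gDW/h) for a reaction to count
#'   as active in the iMAT objective.
#' @return list of class `extraction_config`.
#' @export
extraction_config <- function(expression_threshold = NULL,
                              required_fraction = 0.9,
                              imat_low = 0.25, imat_high = 0.75,
                              activity_epsilon = 1) {
  stopifnot(required_fraction > 0, required_fraction <= 1,
            imat_low < imat_high, activity_epsilon > 0)
  structure(list(expression_threshold = expression_threshold,
                 required_fraction = required_fraction,
                 imat_low = imat_low, imat_high = imat_high,
                 activity_epsilon = activity_epsilon),
            class = "extraction_config")
}

resolve_threshold <- function(reaction_expression, config) {
  if (!is.null(config$expression_threshold)) return(config$expression_threshold)
  fin <- reaction_expression[is.finite(reaction_expression)]
  if (!length(fin)) stop("no finite reaction expression values to set a threshold")
  stats::median(fin)
}

#' GIMME-style model extraction
#'
#' Linear-programming extraction: reactions scoring below the expression
#' threshold T are penalized in proportion to their inconsistency weight
#' (T - x_i) per unit of absolute flux, subject to mass balance, bounds and
#' a functionality constraint (biomass at least `required_fraction` of the
#' full-model optimum). Below-threshold reactions carrying no flux in the
#' penalty-minimizing solution are removed; orphaned metabolites (and hence
#' genes no longer referenced by any GPR) are pruned.
#'
#' @param model a `metabolic_model` with an objective.
#' @param reaction_expression named numeric vector from
#'   [map_reaction_expression()].
#' @param config an [extraction_config()].
#' @param flux_zero_tol absolute flux below which a penalized reaction
#'   counts as unused.
#' @return the extracted sub-model.
#' @export
extract_gimme <- function(model, reaction_expression, config = extraction_config(),
                          flux_zero_tol = 1e-8) {
  stopifnot(all(model$reactions$id %in% names(reaction_expression)))
  x <- reaction_expression[model$reactions$id]
  Tthr <- resolve_threshold(x, config)
  obj_rxn <- find_objective(model)
  wt <- solve_fba(model)
  if (wt$status != "optimal") stop("full model is infeasible; cannot extract")
  mu <- wt$objective_value

  below <- which(is.finite(x) & x < Tthr)
  if (!length(below)) return(model)

  n <- nrow(model$reactions)
  k <- length(below)
  S <- stoich_matrix(model)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  lb[match(obj_rxn, model$reactions$id)] <- config$required_fraction * mu
  ## vars: v (n), a (k) with a_j >= |v_below[j]| ; minimize sum (T - x) a
  A_eq <- cbind(S, matrix(0, nrow(S), k))
  P <- matrix(0, k, n); P[cbind(seq_len(k), below)] <- 1
  A_le <- rbind(cbind(P, -diag(k)), cbind(-P, -diag(k)))
  amax <- pmax(abs(lb[below]), abs(ub[below]))
  sol <- lp_solve(c(rep(0, n), Tthr - x[below]),
                  A_eq = A_eq, b_eq = rep(0, nrow(S)),
                  A_le = A_le, b_le = rep(0, 2 * k),
                  lower = c(lb, rep(0, k)), upper = c(ub, amax),
                  maximize = FALSE)
  if (sol$status != "optimal")
    stop("functionality constraint infeasible at required_fraction = ",
         config$required_fraction)
  v <- sol$x[seq_len(n)]
  drop <- model$reactions$id[below][abs(v[below]) <= flux_zero_tol]
  subset_model(model, setdiff(model$reactions$id, drop))
}

#' iMAT-style model extraction
#'
#' Mixed-integer extraction: reactions are classed high/moderate/low by the
#' `imat_high`/`imat_low` expression quantiles (unevidenced reactions count
#' as high), and a MILP maximizes the number of high reactions carrying at
#' least `activity_epsilon` flux (in either direction) plus the number of
#' low reactions carrying none. Low reactions inactive in the optimum are
#' removed and the model pruned as in [extract_gimme()].
#'
#' @inheritParams extract_gimme
#' @param time_limit MILP time limit in seconds.
#' @return the extracted sub-model.
#' @export
extract_imat <- function(model, reaction_expression, config = extraction_config(),
                         time_limit = 300, flux_zero_tol = 1e-8) {
  stopifnot(all(model$reactions$id %in% names(reaction_expression)))
  x <- reaction_expression[model$reactions$id]
  fin <- x[is.finite(x)]
  if (!length(fin)) return(model)
  qlo <- stats::quantile(fin, config$imat_low, names = FALSE)
  qhi <- stats::quantile(fin, config$imat_high, names = FALSE)
  high <- which(x >= qhi)           # Inf (unevidenced) lands here
  low <- which(is.finite(x) & x <= qlo & x < qhi)   # classes stay disjoint under ties
  eps <- config$activity_epsilon
  if (!length(low) && !length(high)) return(model)

  n <- nrow(model$reactions)
  S <- stoich_matrix(model)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  nh <- length(high); nl <- length(low)
  ## vars: v (n), yf (nh), yr (nh), z (nl)
  nv <- n + 2 * nh + nl
  col_yf <- n + seq_len(nh); col_yr <- n + nh + seq_len(nh); col_z <- n + 2 * nh + seq_len(nl)
  rows <- list(); rhs <- numeric(0)
  add <- function(cols, vals, b) {
    r <- numeric(nv); r[cols] <- vals
    rows[[length(rows) + 1]] <<- r
    rhs[length(rhs) + 1] <<- b
  }
  for (j in seq_len(nh)) {
    i <- high[j]
    add(c(i, col_yf[j]), c(-1, eps - lb[i]), -lb[i])     # yf=1 -> v_i >= eps
    add(c(i, col_yr[j]), c(1, eps + ub[i]), ub[i])       # yr=1 -> v_i <= -eps
    add(c(col_yf[j], col_yr[j]), c(1, 1), 1)             # at most one direction
  }
  for (j in seq_len(nl)) {
    i <- low[j]
    add(c(i, col_z[j]), c(1, ub[i]), ub[i])              # z=1 -> v_i <= 0
    add(c(i, col_z[j]), c(-1, -lb[i]), -lb[i])           # z=1 -> v_i >= 0
  }
  A_le <- do.call(rbind, rows)
  obj <- numeric(nv); obj[c(col_yf, col_yr, col_z)] <- 1
  sol <- milp_solve(obj,
                    A_eq = cbind(S, matrix(0, nrow(S), nv - n)),
                    b_eq = rep(0, nrow(S)),
                    A_le = A_le, b_le = rhs,
                    lower = c(lb, rep(0, nv - n)), upper = c(ub, rep(1, nv - n)),
                    binary_idx = c(col_yf, col_yr, col_z),
                    maximize = TRUE, time_limit = time_limit)
  if (sol$status != "optimal") stop("iMAT MILP failed: ", sol$status)
  v <- sol$x[seq_len(n)]
  drop <- model$reactions$id[low][abs(v[low]) <= flux_zero_tol]
  subset_model(model, setdiff(model$reactions$id, drop))
}
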