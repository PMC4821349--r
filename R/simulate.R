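#' Toy metabolic models with known ground truth
#'
#' Builds a small branched network — substrate uptake, a transporter, and
#' `n_branches` conversion routes of differing biomass yield, each optionally
#' excreting a byproduct — whose FBA optimum and gene essentiality are known
#' in closed form: the optimum is `uptake * max(branch_yields)` and the
#' essential genes are recomputed here by exhaustive single-deletion LPs.
#' Ids follow BiGG-like conventions (`EX_` exchanges, `_c`/`_e`
#' compartment suffixes) so fixtures exercise the same id-handling paths as
#' curated models.
#'
#' @param n_branches number of parallel conversion routes (>= 1).
#' @param branch_yields biomass precursor yield per branch, each in (0, 1];
#'   the remainder `1 - yield` goes to a shared excreted byproduct.
#' @param gpr_scheme `"none"` (no gene associations), `"simple"` (one gene
#'   per reaction) or `"nested"` (branches gated by
#'   `(gA and (gB or gC))` complexes with isoenzymes).
#' @param uptake substrate supply bound (mmol/gDW/h).
#' @return list with `model` (a [metabolic_model()]), `essential_genes`
#'   (ground truth from exhaustive deletion), `fba_optimum` (closed form),
#'   and `product_exchange` (the byproduct exchange id, a natural target for
#'   strain-design examples).
#' @export
make_toy_model <- function(n_branches = 2, branch_yields = c(0.5, 0.3),
                           gpr_scheme = c("simple", "none", "nested"),
                           uptake = 10) {
  gpr_scheme <- match.arg(gpr_scheme)
  if (n_branches < 1) stop("toy model needs at least one branch")
  stopifnot(length(branch_yields) == n_branches,
            all(branch_yields > 0), all(branch_yields <= 1))

  mets <- data.frame(
    id = c("glc_e", "glc_c", "prec_c", "byp_c", "byp_e"),
    name = c("glucose (ext)", "glucose", "biomass precursor", "byproduct", "byproduct (ext)"),
    compartment = c("e", "c", "c", "c", "e"),
    boundary = FALSE, stringsAsFactors = FALSE)

  rid <- c("EX_glc(e)", "GLCt", paste0("BR", seq_len(n_branches)), "BYPt", "EX_byp(e)",
           "BIOMASS_toy")
  stoich <- c(
    list(c(glc_e = -1)),
    list(c(glc_e = -1, glc_c = 1)),
    lapply(seq_len(n_branches), function(i) {
      st <- c(glc_c = -1, prec_c = unname(branch_yields[i]))
      if (branch_yields[i] < 1) st <- c(st, byp_c = unname(1 - branch_yields[i]))
      st
    }),
    list(c(byp_c = -1, byp_e = 1)),
    list(c(byp_e = -1)),
    list(c(prec_c = -1)))
  names(stoich) <- rid
  lb <- c(-uptake, 0, rep(0, n_branches), 0, 0, 0)
  ub <- c(0, rep(1000, n_branches + 4))
  rxn <- data.frame(id = rid, name = rid, lb = lb, ub = ub, subsystem = "toy",
                    objective = c(rep(0, length(rid) - 1), 1),
                    stringsAsFactors = FALSE)

  gpr <- vector("list", length(rid)); names(gpr) <- rid
  if (gpr_scheme == "simple") {
    gpr[["GLCt"]] <- "g_t"
    for (i in seq_len(n_branches)) gpr[[paste0("BR", i)]] <- paste0("g_b", i)
  } else if (gpr_scheme == "nested") {
    gpr[["GLCt"]] <- "g_t"
    for (i in seq_len(n_branches)) {
      gpr[[paste0("BR", i)]] <- parse_gpr(
        sprintf("(g_a%d and (g_b%d or g_c%d))", i, i, i))
    }
  }

  model <- metabolic_model("toy_branched", mets, rxn, stoich, gpr)
  wt <- solve_fba(model)$objective_value
  essential <- character(0)
  for (g in model_genes(model)) {
    dis <- reactions_disabled_by(model, g)
    m <- model
    ko <- m$reactions$id %in% dis
    m$reactions$lb[ko] <- 0; m$reactions$ub[ko] <- 0
    s <- solve_fba(m)
    if (s$status != "optimal" || s$objective_value <= 1e-6) essential <- c(essential, g)
  }
  list(model = model,
       essential_genes = essential,
       fba_optimum = uptake * max(branch_yields),
       product_exchange = "EX_byp(e)")
}

#' Simulate a cross-species RNA-seq count matrix
#'
#' Negative-binomial counts (variance `mu + dispersion * mu^2`) with a
#' species-by-replicate design, per-sample library-size factors, optional
#' planted differentially expressed genes (mean multiplied by a fold change
#' in designated species) and planted coexpression modules (a shared
#' per-sample latent factor added on the log2 scale). Fully reproducible
#' from `seed`.
#'
#' @param n_genes number of genes.
#' @param species character vector of species labels (default: the four
#'   Saccharomyces labels).
#' @param replicates replicates per species.
#' @param baseline_mean NB mean shared by unperturbed genes.
#' @param dispersion NB dispersion alpha.
#' @param planted_degs NULL or data.frame with columns `gene` (index or id),
#'   `species`, `fold_change`.
#' @param planted_modules NULL or list of lists with elements `genes`
#'   (indices or ids), `loading`, `noise_sd`, and optionally `factor_sd`
#'   (spread of the shared latent factor on the log2 scale; default 1.5, i.e.
#'   moderate cross-condition swings that dominate counting noise).
#' @param library_size_range per-sample scale factors are drawn uniformly
#'   from this range.
#' @param seed integer seed.
#' @return an [expression_matrix()] with gene lengths drawn from 200-5000 bp
#'   and `sample_meta` rows `<species>_r<replicate>`.
#' @export
simulate_expression <- function(n_genes = 2000,
                                species = c("Sce", "Spa", "Smi", "Sba"),
                                replicates = 2,
                                baseline_mean = 100,
                                dispersion = 0.1,
                                planted_degs = NULL,
                                planted_modules = NULL,
                                library_size_range = c(0.7, 1.3),
                                seed = 1) {
  set.seed(seed)
  n_samp <- length(species) * replicates
  meta <- data.frame(
    sample = paste0(rep(species, each = replicates), "_r", seq_len(replicates)),
    species = rep(species, each = replicates),
    replicate = rep(seq_len(replicates), times = length(species)),
    stringsAsFactors = FALSE)
  genes <- sprintf("gene%04d", seq_len(n_genes))

  log2mu <- matrix(log2(baseline_mean), n_genes, n_samp,
                   dimnames = list(genes, meta$sample))
  if (!is.null(planted_degs)) {
    for (i in seq_len(nrow(planted_degs))) {
      g <- planted_degs$gene[i]
      gi <- if (is.numeric(g)) g else match(g, genes)
      cols <- meta$species == planted_degs$species[i]
      log2mu[gi, cols] <- log2mu[gi, cols] + log2(planted_degs$fold_change[i])
    }
  }
  if (!is.null(planted_modules)) {
    for (mod in planted_modules) {
      gi <- if (is.numeric(mod$genes)) mod$genes else match(mod$genes, genes)
      fsd <- if (is.null(mod$factor_sd)) 1.5 else mod$factor_sd
      f <- stats::rnorm(n_samp, 0, fsd)
      noise <- matrix(stats::rnorm(length(gi) * n_samp, 0, mod$noise_sd),
                      length(gi), n_samp)
      log2mu[gi, ] <- log2mu[gi, ] + mod$loading * rep(f, each = length(gi)) + noise
    }
  }
  sf <- stats::runif(n_samp, library_size_range[1], library_size_range[2])
  mu <- 2^log2mu * rep(sf, each = n_genes)
  counts <- matrix(stats::rnbinom(n_genes * n_samp, mu = mu, size = 1 / dispersion),
                   n_genes, n_samp, dimnames = dimnames(log2mu))
  lengths <- stats::setNames(sample(200:5000, n_genes, replace = TRUE), genes)
  expression_matrix(counts, lengths, meta)
}

#' Simulate homology hit tables
#'
#' Generates BLAST-style tabular hits with a planted presence/absence
#' pattern: a present (gene, species) pair receives at least one strong hit
#' (e-value <= 1e-6), an absent pair either no row or a decoy hit with
#' e-value >= 1e-2, so that [presence_calls()] at the conventional 1e-4
#' threshold recovers the planted pattern exactly.
#'
#' @param genes character vector of gene ids.
#' @param species character vector of species labels.
#' @param presence logical matrix `genes x species` (dimnames required), or
#'   NULL for all-present.
#' @param strategies assembly strategies to emulate; each present pair gets a
#'   hit under at least one strategy (chosen at random), so merged evidence
#'   (the OR over strategies) matches `presence`.
#' @param decoy_fraction fraction of absent pairs that receive a decoy hit
#'   rather than no row at all.
#' @param seed integer seed.
#' @return data.frame of class `homology_hits` with BLAST outfmt-6 style
#'   columns plus `species` and `strategy`.
#' @export
simulate_homology <- function(genes, species, presence = NULL,
                              strategies = c("genome_guided", "de_novo"),
                              decoy_fraction = 0.3, seed = 1) {
  set.seed(seed)
  if (is.null(presence)) {
    presence <- matrix(TRUE, length(genes), length(species),
                       dimnames = list(genes, species))
  }
  stopifnot(identical(rownames(presence), genes),
            identical(colnames(presence), species))
  rows <- list()
  for (g in genes) for (sp in species) {
    if (presence[g, sp]) {
      strat <- sample(strategies, 1)
      rows[[length(rows) + 1]] <- data.frame(
        query = g, subject = paste0(sp, "_tx_", g),
        identity = round(stats::runif(1, 85, 100), 2),
        align_length = sample(100:2000, 1),
        evalue = 10^stats::runif(1, -50, -6),
        bitscore = round(stats::runif(1, 100, 900), 1),
        species = sp, strategy = strat, stringsAsFactors = FALSE)
    } else if (stats::runif(1) < decoy_fraction) {
      rows[[length(rows) + 1]] <- data.frame(
        query = g, subject = paste0(sp, "_decoy_", g),
        identity = round(stats::runif(1, 60, 75), 2),
        align_length = sample(30:80, 1),
        evalue = 10^stats::runif(1, -2, 1),
        bitscore = round(stats::runif(1, 20, 40), 1),
        species = sp, strategy = sample(strategies, 1), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("homology_hits", "data.frame")
  out
}
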