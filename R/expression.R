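#' Gene-by-sample expression container
#'
#' Read counts with gene lengths and species/replicate annotation; the input
#' of RPKM quantification, differential-expression testing and coexpression
#' network construction.
#'
#' @param counts non-negative integer matrix, genes x samples (dimnames
#'   required).
#' @param gene_lengths named positive numeric vector, exon length in bp per
#'   gene.
#' @param sample_meta data.frame with columns `sample`, `species`,
#'   `replicate`, one row per count column.
#' @param library_sizes per-sample total mapped reads; defaults to column
#'   sums of `counts`.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, gene_lengths, sample_meta,
                              library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (any(counts < 0)) stop("negative counts")
  if (!all(rownames(counts) %in% names(gene_lengths)))
    stop("every gene needs a length")
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  stopifnot(all(c("sample", "species", "replicate") %in% names(sample_meta)),
            nrow(sample_meta) == ncol(counts),
            all(sample_meta$sample == colnames(counts)))
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  structure(list(counts = counts, gene_lengths = gene_lengths,
                 sample_meta = as.data.frame(sample_meta),
                 library_sizes = library_sizes),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("  species:", paste(unique(x$sample_meta$species), collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression matrix from TSV files
#'
#' `counts` is a gene x sample table (first column = gene id), `lengths` has
#' columns gene and length (bp), `samples` has columns sample, species,
#' replicate.
#'
#' @param counts,lengths,samples file paths.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(counts, lengths, samples) {
  ct <- utils::read.delim(counts, check.names = FALSE, stringsAsFactors = FALSE)
  cm <- as.matrix(ct[, -1, drop = FALSE])
  rownames(cm) <- ct[[1]]
  ln <- utils::read.delim(lengths, stringsAsFactors = FALSE)
  sm <- utils::read.delim(samples, stringsAsFactors = FALSE)
  expression_matrix(cm, stats::setNames(ln[[2]], ln[[1]]), sm)
}

#' Reads per kilobase per million mapped reads
#'
#' RPKM = 1e9 * C / (N * L) for count C, library size N and gene length L
#' (bp). Vectorized over its arguments.
#'
#' @param counts read count(s).
#' @param library_size total mapped reads of the sample (> 0).
#' @param gene_length exon length in bp (> 0).
#' @return numeric RPKM value(s).
#' @examples
#' rpkm(1000, 1e6, 1000)   # 1000
#' @export
rpkm <- function(counts, library_size, gene_length) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  if (any(gene_length <= 0)) stop("gene_length must be positive")
  1e9 * counts / (library_size * gene_length)
}

#' @rdname rpkm
#' @param x an [expression_matrix()].
#' @return `rpkm_matrix`: matrix of RPKM values, genes x samples.
#' @export
rpkm_matrix <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  sweep(sweep(x$counts * 1e9, 2, x$library_sizes, "/"), 1, x$gene_lengths, "/")
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median across genes of the ratio of
#' a sample's count to the gene's geometric mean over all samples (genes
#' with any zero count are excluded from the reference). Columns proportional
#' to each other get size factors equal to the proportionality constants up
#' to a common scale.
#'
#' @param counts genes x samples count matrix.
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  logc <- log(counts)
  ok <- rowSums(!is.finite(logc)) == 0
  if (!any(ok)) stop("no gene has all-positive counts; cannot normalize")
  logmeans <- rowMeans(logc[ok, , drop = FALSE])
  apply(logc[ok, , drop = FALSE], 2, function(col) exp(stats::median(col - logmeans)))
}

#' Simplified negative-binomial differential-expression test
#'
#' A documented stand-in for a DESeq-style analysis: counts are normalized
#' by [size_factors()], a per-gene dispersion is estimated by method of
#' moments pooled across the two groups, and the group totals are compared
#' by an exact-style conditional NB test (all ways of splitting the observed
#' total between the groups, summing the probabilities of outcomes at most
#' as likely as the observed one). No dispersion shrinkage across genes is
#' performed, so counts of significant genes are not comparable with a full
#' DESeq analysis.
#'
#' A gene is called differentially expressed when p < `p_max` and the fold
#' change (group_b over group_a, normalized means) is strictly below
#' `fc_low` or strictly above `fc_high`.
#'
#' @param x an [expression_matrix()].
#' @param group_a,group_b species labels defining the two groups.
#' @param p_max p-value cutoff (default 0.05).
#' @param fc_low,fc_high fold-change cutoffs (default 0.5 and 2; boundary
#'   values are not significant).
#' @return data.frame with columns `gene`, `mean_a`, `mean_b`,
#'   `log2_fold_change`, `p_value`, `is_deg`. All-zero genes get p = 1 and
#'   an undefined (NA) fold change.
#' @export
nb_pairwise_test <- function(x, group_a, group_b, p_max = 0.05,
                             fc_low = 0.5, fc_high = 2) {
  stopifnot(inherits(x, "expression_matrix"))
  ia <- which(x$sample_meta$species == group_a)
  ib <- which(x$sample_meta$species == group_b)
  if (!length(ia) || !length(ib)) stop("empty group: ", group_a, " / ", group_b)
  cts <- x$counts[, c(ia, ib), drop = FALSE]
  sf <- size_factors(cts)
  q <- sweep(cts, 2, sf, "/")
  na <- length(ia); nb <- length(ib)
  qa <- q[, seq_len(na), drop = FALSE]
  qb <- q[, na + seq_len(nb), drop = FALSE]
  ma <- rowMeans(qa); mb <- rowMeans(qb)
  mu0 <- rowMeans(q)

  ## pooled method-of-moments dispersion: within-group variances of
  ## normalized counts, variance model Var = mu + alpha mu^2
  va <- if (na > 1) apply(qa, 1, stats::var) else rep(NA_real_, nrow(q))
  vb <- if (nb > 1) apply(qb, 1, stats::var) else rep(NA_real_, nrow(q))
  wa <- if (na > 1) na - 1 else 0
  wb <- if (nb > 1) nb - 1 else 0
  if (wa + wb == 0) stop("need at least two replicates in one group")
  vpool <- (ifelse(is.na(va), 0, va) * wa + ifelse(is.na(vb), 0, vb) * wb) / (wa + wb)
  mpool <- (ma * na + mb * nb) / (na + nb)
  alpha <- pmax(0, (vpool - mpool) / mpool^2)
  ## with few replicates the per-gene moment estimate is noisy and its
  ## truncation at zero biases it low; share information across genes by
  ## flooring each gene at the experiment-wide median (conservative sharing)
  med <- stats::median(alpha[mpool > 0], na.rm = TRUE)
  if (is.finite(med)) alpha <- pmax(alpha, med)

  pvals <- vapply(seq_len(nrow(q)), function(g) {
    Ka <- round(sum(qa[g, ])); Kb <- round(sum(qb[g, ]))
    nb_exact_p(Ka, Kb, na, nb, mu0[g], alpha[g])
  }, numeric(1))

  fc <- ifelse(ma == 0 & mb == 0, NA_real_, mb / ma)
  lfc <- log2(fc)
  is_deg <- !is.na(fc) & pvals < p_max & (fc < fc_low | fc > fc_high)
  data.frame(gene = rownames(q), mean_a = ma, mean_b = mb,
             log2_fold_change = lfc, p_value = pvals, is_deg = is_deg,
             row.names = NULL, stringsAsFactors = FALSE)
}

## exact-style conditional test on the group totals: Ka ~ NB(na*mu, disp
## alpha/na), Kb ~ NB(nb*mu, alpha/nb) under the common-mean null; condition
## on Ka + Kb and sum probabilities of splits as or less likely than observed.
nb_exact_p <- function(Ka, Kb, na, nb, mu, alpha) {
  total <- Ka + Kb
  if (total == 0) return(1)
  ks <- 0:total
  da <- nb_dens(ks, na * mu, alpha / na)
  db <- nb_dens(total - ks, nb * mu, alpha / nb)
  joint <- da * db
  tot <- sum(joint)
  if (tot <= 0) return(1)
  obs <- joint[Ka + 1]
  min(1, sum(joint[joint <= obs * (1 + 1e-10)]) / tot)
}

nb_dens <- function(k, mu, alpha) {
  if (alpha < 1e-10) stats::dpois(k, mu) else stats::dnbinom(k, mu = mu, size = 1 / alpha)
}

#' Expression divergence relative to an outgroup
#'
#' A gene diverges in the outgroup when it is differentially expressed in
#' the outgroup-vs-species comparison for every other species, with a
#' consistent direction: all fold changes above `fc_high` (up in the
#' outgroup) or all below `fc_low` (down). Mixed directions do not qualify.
#'
#' @param deg_tables named list of [nb_pairwise_test()] results, one per
#'   non-outgroup species, each computed with the species as `group_a` and
#'   the outgroup as `group_b` (so fold changes are outgroup-relative).
#' @param species the non-outgroup species that must all be covered.
#' @param fc_low,fc_high direction thresholds (defaults 0.5 and 2).
#' @return data.frame with columns `gene` and `direction` ("up"/"down",
#'   relative to the outgroup).
#' @export
call_divergent <- function(deg_tables, species = names(deg_tables),
                           fc_low = 0.5, fc_high = 2) {
  missing <- setdiff(species, names(deg_tables))
  if (length(missing)) stop("missing outgroup comparison for: ",
                            paste(missing, collapse = ", "))
  tabs <- deg_tables[species]
  genes <- Reduce(intersect, lapply(tabs, function(t) t$gene))
  up <- rep(TRUE, length(genes)); dn <- rep(TRUE, length(genes)); deg <- rep(TRUE, length(genes))
  for (t in tabs) {
    t <- t[match(genes, t$gene), ]
    fc <- 2^t$log2_fold_change
    deg <- deg & t$is_deg
    up <- up & !is.na(fc) & fc > fc_high
    dn <- dn & !is.na(fc) & fc < fc_low
  }
  sel <- deg & (up | dn)
  data.frame(gene = genes[sel],
             direction = ifelse(up[sel], "up", "down"),
             stringsAsFactors = FALSE)
}

#' Coexpression network by correlation thresholding
#'
#' Computes Pearson correlations of log2(RPKM + 1) profiles across all
#' samples after removing the lowest-variance genes, and keeps gene pairs
#' with |r| at or above the threshold (anti-correlated pairs count). Genes
#' with zero variance after filtering are excluded with a message.
#'
#' @param x an [expression_matrix()] (needs >= 3 samples).
#' @param variance_filter_quantile fraction of genes dropped from the
#'   low-variance end (default 0.25).
#' @param r_min correlation threshold (default 0.90).
#' @return data.frame with columns `gene_a`, `gene_b` (each unordered pair
#'   once, `gene_a` < `gene_b`) and `r`.
#' @export
build_coexpression <- function(x, variance_filter_quantile = 0.25, r_min = 0.90) {
  stopifnot(inherits(x, "expression_matrix"))
  if (ncol(x$counts) < 3) stop("need at least 3 samples for coexpression")
  expr <- log2(rpkm_matrix(x) + 1)
  v <- apply(expr, 1, stats::var)
  n_drop <- floor(variance_filter_quantile * length(v))
  keep <- setdiff(seq_along(v), order(v)[seq_len(n_drop)])
  expr <- expr[keep, , drop = FALSE]
  const <- apply(expr, 1, stats::var) == 0
  if (any(const)) {
    message("excluding ", sum(const), " constant-expression gene(s) from coexpression")
    expr <- expr[!const, , drop = FALSE]
  }
  if (nrow(expr) < 2) return(data.frame(gene_a = character(0), gene_b = character(0),
                                        r = numeric(0)))
  cc <- stats::cor(t(expr))
  idx <- which(upper.tri(cc) & abs(cc) >= r_min, arr.ind = TRUE)
  out <- data.frame(gene_a = rownames(cc)[idx[, 1]],
                    gene_b = rownames(cc)[idx[, 2]],
                    r = cc[idx], stringsAsFactors = FALSE)
  swap <- out$gene_a > out$gene_b
  tmp <- out$gene_a[swap]; out$gene_a[swap] <- out$gene_b[swap]; out$gene_b[swap] <- tmp
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Assembly summary statistics
#'
#' N50 is the largest contig length L such that contigs of length >= L cover
#' at least half the total assembly length.
#'
#' @param lengths positive contig/scaffold lengths (bp).
#' @return list with `n`, `mean`, `n50`.
#' @examples
#' assembly_stats(c(4, 3, 3, 2, 2, 2))$n50   # 3
#' @export
assembly_stats <- function(lengths) {
  if (!length(lengths)) stop("empty length list")
  if (any(lengths <= 0)) stop("contig lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  n50 <- s[which(cumsum(s) >= sum(s) / 2)[1]]
  list(n = length(lengths), mean = mean(lengths), n50 = n50)
}
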