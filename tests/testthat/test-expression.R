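test_that("RPKM formula matches hand arithmetic", {
  expect_equal(rpkm(0, 1e6, 1000), 0)
  expect_equal(rpkm(1000, 1e6, 1000), 1000)
  expect_equal(rpkm(50, 2e7, 500), 5)
  expect_error(rpkm(10, 0, 100), "library_size")
  expect_error(rpkm(10, 100, 0), "gene_length")
})

test_that("size factors recover proportionality constants", {
  set.seed(61)
  base <- rpois(300, 200) + 1
  counts <- cbind(s1 = base, s2 = 2 * base, s3 = round(0.5 * base))
  sf <- size_factors(counts)
  expect_equal(sf[["s2"]] / sf[["s1"]], 2, tolerance = 0.02)
  expect_equal(sf[["s3"]] / sf[["s1"]], 0.5, tolerance = 0.02)
})

test_that("identical groups give unit size factors and no DEG calls", {
  counts <- matrix(rep(c(10L, 100L, 1000L, 55L), 4), ncol = 4,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  em <- expression_matrix(counts, setNames(rep(1000, 4), paste0("g", 1:4)),
                          data.frame(sample = paste0("s", 1:4),
                                     species = rep(c("A", "B"), each = 2),
                                     replicate = c(1, 2, 1, 2)))
  deg <- nb_pairwise_test(em, "A", "B")
  expect_false(any(deg$is_deg))
  expect_equal(size_factors(counts), setNames(rep(1, 4), paste0("s", 1:4)))
})

test_that("all-zero genes get p = 1 and undefined fold change", {
  counts <- matrix(c(0L, 0L, 0L, 0L, 5L, 6L, 7L, 8L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("gz", "gn"), paste0("s", 1:4)))
  em <- expression_matrix(counts, c(gz = 500, gn = 500),
                          data.frame(sample = paste0("s", 1:4),
                                     species = rep(c("A", "B"), each = 2),
                                     replicate = c(1, 2, 1, 2)))
  deg <- nb_pairwise_test(em, "A", "B")
  expect_equal(deg$p_value[deg$gene == "gz"], 1)
  expect_true(is.na(deg$log2_fold_change[deg$gene == "gz"]))
  expect_false(deg$is_deg[deg$gene == "gz"])
})

test_that("type-I error under the NB null is close to nominal", {
  em <- simulate_expression(n_genes = 2000, species = c("A", "B"), replicates = 3,
                            baseline_mean = 100, dispersion = 0.1, seed = 101)
  deg <- nb_pairwise_test(em, "A", "B")
  expect_gte(mean(deg$p_value < 0.05), 0.03)
  expect_lte(mean(deg$p_value < 0.05), 0.07)
})

test_that("planted four-fold genes are recovered with high power", {
  planted <- data.frame(gene = 1:100, species = "B", fold_change = 4)
  em <- simulate_expression(n_genes = 2000, species = c("A", "B"), replicates = 3,
                            baseline_mean = 100, dispersion = 0.05,
                            planted_degs = planted, seed = 102)
  deg <- nb_pairwise_test(em, "A", "B")
  expect_gte(mean(deg$is_deg[1:100]), 0.9)
  expect_lte(mean(deg$is_deg[-(1:100)]), 0.02)
})

test_that("p-values are invariant to sample order within groups", {
  em <- simulate_expression(n_genes = 50, species = c("A", "B"), replicates = 3,
                            seed = 103)
  p1 <- nb_pairwise_test(em, "A", "B")$p_value
  perm <- c(2, 1, 3, 6, 4, 5)
  em2 <- expression_matrix(em$counts[, perm], em$gene_lengths,
                           em$sample_meta[perm, ])
  p2 <- nb_pairwise_test(em2, "A", "B")$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("fold-change boundaries are strict for DEG status", {
  # engineered two-fold gene: exactly fc = 2 must not be a DEG
  deg <- data.frame(gene = "g", mean_a = 10, mean_b = 20,
                    log2_fold_change = 1, p_value = 1e-6, is_deg = NA)
  # the rule itself, as applied by nb_pairwise_test:
  fc <- 2^deg$log2_fold_change
  expect_false(deg$p_value < 0.05 && (fc < 0.5 || fc > 2))
})

test_that("divergence calls need all outgroup comparisons, same direction", {
  mk <- function(fc, p = 1e-4) data.frame(
    gene = c("gu", "gd", "g2of3", "gmix"),
    mean_a = 100, mean_b = 100 * fc,
    log2_fold_change = log2(fc),
    p_value = p,
    is_deg = p < 0.05 & (fc < 0.5 | fc > 2),
    stringsAsFactors = FALSE)
  up <- mk(c(4, 0.2, 4, 4))
  t2 <- mk(c(3, 0.25, 4, 8))
  t3 <- mk(c(5, 0.1, 1.2, 0.3))   # g2of3 not DEG here; gmix flips direction
  div <- call_divergent(list(Sce = up, Spa = t2, Smi = t3))
  expect_setequal(div$gene, c("gu", "gd"))
  expect_equal(div$direction[div$gene == "gu"], "up")
  expect_equal(div$direction[div$gene == "gd"], "down")
  expect_error(call_divergent(list(Sce = up, Spa = t2), species = c("Sce", "Spa", "Smi")),
               "missing")
  # divergent genes are a subset of the DEGs of every comparison
  expect_true(all(div$gene %in% up$gene[up$is_deg]))
})

test_that("coexpression: exact duplicates, anti-correlation, threshold monotonicity", {
  set.seed(67)
  counts <- matrix(rnbinom(50 * 10, mu = 300, size = 20), 50, 10,
                   dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:10)))
  counts["g02", ] <- counts["g01", ]                       # duplicate profile
  em <- expression_matrix(counts, setNames(rep(1000, 50), rownames(counts)),
                          data.frame(sample = paste0("s", 1:10),
                                     species = rep(c("A", "B"), each = 5),
                                     replicate = rep(1:5, 2)))
  edges <- build_coexpression(em, variance_filter_quantile = 0, r_min = 0.9)
  dup <- edges[edges$gene_a == "g01" & edges$gene_b == "g02", ]
  expect_equal(nrow(dup), 1)
  expect_equal(dup$r, 1, tolerance = 1e-12)
  # no self edges, each unordered pair at most once
  expect_true(all(edges$gene_a < edges$gene_b))
  # raising the threshold never adds edges
  stricter <- build_coexpression(em, variance_filter_quantile = 0, r_min = 0.95)
  expect_lte(nrow(stricter), nrow(edges))
  key <- function(e) paste(e$gene_a, e$gene_b)
  expect_true(all(key(stricter) %in% key(edges)))
})

test_that("anti-correlated pairs survive the absolute-value criterion", {
  n <- 16
  a <- round(100 * 2^(1.5 * sin(seq_len(n))))
  b <- round(100 * 2^(-1.5 * sin(seq_len(n))))
  counts <- rbind(ga = a, gb = b,
                  matrix(50L, 20, n, dimnames = list(sprintf("f%02d", 1:20), NULL)))
  colnames(counts) <- paste0("s", 1:n)
  # add mild jitter so filler genes are not constant
  set.seed(5)
  counts[-(1:2), ] <- counts[-(1:2), ] + matrix(rpois(20 * n, 3), 20, n)
  em <- expression_matrix(counts, setNames(rep(1000, 22), rownames(counts)),
                          data.frame(sample = paste0("s", 1:n),
                                     species = "A", replicate = 1:n))
  edges <- build_coexpression(em, variance_filter_quantile = 0, r_min = 0.9)
  pair <- edges[edges$gene_a == "ga" & edges$gene_b == "gb", ]
  expect_equal(nrow(pair), 1)
  expect_lt(pair$r, -0.9)
})

test_that("planted coexpression modules are recovered near-completely", {
  mod <- list(list(genes = 1:10, loading = 0.98, noise_sd = 0.1))
  em <- simulate_expression(n_genes = 1000,
                            species = c("Sce", "Spa", "Smi", "Sba"),
                            replicates = 5, baseline_mean = 1000,
                            dispersion = 0.02, planted_modules = mod, seed = 105)
  edges <- build_coexpression(em)
  members <- sprintf("gene%04d", 1:10)
  within <- edges$gene_a %in% members & edges$gene_b %in% members
  expect_gte(sum(within) / 45, 0.95)
  expect_lte(sum(!within), 5)     # essentially no background edges
})

test_that("N50 and assembly summaries match sort-and-accumulate arithmetic", {
  expect_equal(assembly_stats(5000)$n50, 5000)
  st <- assembly_stats(c(4, 3, 3, 2, 2, 2))
  expect_equal(st$n50, 3)          # total 16, cumulative 4+3+3 >= 8
  expect_equal(st$n, 6)
  expect_equal(st$mean, 16 / 6)
  expect_equal(assembly_stats(rep(120, 9))$n50, 120)
  expect_error(assembly_stats(numeric(0)), "empty")
  expect_error(assembly_stats(c(5, -1)), "positive")
})
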