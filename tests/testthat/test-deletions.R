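test_that("GPR-aware disabling follows the boolean rules", {
  toy <- make_toy_model(gpr_scheme = "nested")$model
  # isoenzymes: deleting one member of an 'or' leaves the reaction active
  m <- toy
  m$gpr[["BR1"]] <- parse_gpr("g1 or g2")
  expect_identical(reactions_disabled_by(m, "g1"), character(0))
  expect_identical(reactions_disabled_by(m, c("g1", "g2")), "BR1")
  # empty GPR is never disabled
  expect_false("BIOMASS_toy" %in% reactions_disabled_by(toy, model_genes(toy)))
  # nested rule versus the R-parser truth-table oracle
  rule <- "(g1 and (g2 or g3))"
  m$gpr[["BR1"]] <- parse_gpr(rule)
  for (del in list("g2", "g1", c("g2", "g3"), "g3", c("g1", "g2"))) {
    state <- setNames(!(c("g1", "g2", "g3") %in% del), c("g1", "g2", "g3"))
    expect_identical("BR1" %in% reactions_disabled_by(m, del),
                     !gpr_truth_oracle(rule, state),
                     info = paste(del, collapse = "+"))
  }
  # unknown genes are ignored
  expect_identical(reactions_disabled_by(toy, "not_a_gene"), character(0))
})

test_that("single-gene deletion screen matches exhaustive per-deletion LP oracle", {
  toy <- make_toy_model(gpr_scheme = "nested")
  m <- toy$model
  screen <- single_gene_deletion_screen(m)
  expect_setequal(screen$gene, model_genes(m))
  # phenotype partition covers the gene set exactly
  expect_equal(sum(table(screen$phenotype)), length(model_genes(m)))
  # oracle: re-derive each growth value by enumeration over the deleted model
  S <- stoich_matrix(m)
  obj <- as.numeric(m$reactions$id == "BIOMASS_toy")
  for (i in seq_len(nrow(screen))) {
    dis <- reactions_disabled_by(m, screen$gene[i])
    lb <- m$reactions$lb; ub <- m$reactions$ub
    ko <- m$reactions$id %in% dis
    lb[ko] <- 0; ub[ko] <- 0
    oracle <- enum_lp_max(obj, S, lb, ub)
    expect_equal(screen$growth[i], oracle, tolerance = 1e-7, info = screen$gene[i])
  }
  # ground truth essentials from the generator agree with the screen
  expect_setequal(screen$gene[screen$phenotype == "no_growth"], toy$essential_genes)
})

test_that("a gene whose reactions carry no optimal flux is 'unchanged'", {
  m <- make_toy_model(gpr_scheme = "simple")$model
  screen <- single_gene_deletion_screen(m)
  row <- screen[screen$gene == "g_b2", ]   # gene of the unused 0.3-yield branch
  expect_equal(row$phenotype, "unchanged")
  expect_equal(row$growth_ratio, 1, tolerance = 1e-9)
})

test_that("deleting a superset of genes never increases growth", {
  m <- make_toy_model(gpr_scheme = "nested")$model
  genes <- model_genes(m)
  obj_rxn <- find_objective(m)
  grow <- function(del) {
    dis <- reactions_disabled_by(m, del)
    m2 <- m
    ko <- m2$reactions$id %in% dis
    m2$reactions$lb[ko] <- 0; m2$reactions$ub[ko] <- 0
    s <- solve_fba(m2, objective = obj_rxn)
    if (s$status == "optimal") s$objective_value else 0
  }
  set.seed(47)
  for (i in 1:8) {
    a <- sample(genes, sample(1:3, 1))
    b <- union(a, sample(genes, sample(1:2, 1)))
    expect_lte(grow(b), grow(a) + 1e-9)
  }
})

test_that("FBA and lMOMA agree on the lethal gene set", {
  for (scheme in c("simple", "nested")) {
    toy <- make_toy_model(gpr_scheme = scheme)
    fba <- single_gene_deletion_screen(toy$model, method = "fba")
    lmo <- single_gene_deletion_screen(toy$model, method = "lmoma")
    expect_setequal(fba$gene[fba$phenotype == "no_growth"],
                    lmo$gene[lmo$phenotype == "no_growth"])
    # lMOMA mutants grow at most as fast as re-optimized FBA mutants
    expect_true(all(lmo$growth <= fba$growth + 1e-6))
  }
})

test_that("confusion summary reproduces hand arithmetic and is order-invariant", {
  fake_screen <- function(n_grow_iness, n_nogrow_iness, n_grow_ess, n_nogrow_ess) {
    n <- n_grow_iness + n_nogrow_iness + n_grow_ess + n_nogrow_ess
    data.frame(
      gene = sprintf("y%04d", seq_len(n)),
      phenotype = rep(c("unchanged", "no_growth", "reduced", "no_growth"),
                      c(n_grow_iness, n_nogrow_iness, n_grow_ess, n_nogrow_ess)),
      stringsAsFactors = FALSE)
  }
  scr <- fake_screen(9, 1, 1, 9)
  ess <- scr$gene[11:20]
  cs <- confusion_vs_reference(scr, ess)
  expect_equal(c(cs$tp, cs$fn, cs$fp, cs$tn), c(9, 1, 1, 9))
  expect_equal(cs$sensitivity, 90)
  expect_equal(cs$ppv, 90)
  # permutation invariance
  perm <- scr[sample(nrow(scr)), ]
  cs2 <- confusion_vs_reference(perm, ess)
  expect_identical(unclass(cs), unclass(cs2))
  # no false positives -> perfect PPV
  scr3 <- fake_screen(5, 0, 0, 5)
  cs3 <- confusion_vs_reference(scr3, scr3$gene[6:10])
  expect_equal(cs3$ppv, 100)
  # reference genes absent from the screen simply do not contribute
  cs4 <- confusion_vs_reference(scr, c(ess, "unseen_gene"))
  expect_identical(unclass(cs), unclass(cs4))
  expect_error(confusion_vs_reference(scr[0, ], ess), "empty")
})
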