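write_tsv_fixture <- function(dir, reactions, metabolites) {
  dir.create(dir, showWarnings = FALSE)
  writeLines(reactions, file.path(dir, "reactions.tsv"))
  writeLines(metabolites, file.path(dir, "metabolites.tsv"))
  dir
}

test_that("TSV model with empty GPRs parses with an empty gene set", {
  d <- write_tsv_fixture(
    tempfile("tsv"),
    c("id\tname\tequation\tlb\tub\tsubsystem\tgpr\tobjective",
      "EX_A\tA exchange\tA_e ->\t-10\t0\t\t\t0",
      "T1\ttransport\tA_e -> A_c\t0\t1000\t\t\t0",
      "BIO_biomass\tgrowth\t2 A_c ->\t0\t1000\t\t\t1"),
    c("id\tname\tcompartment",
      "A_e\tA external\te",
      "A_c\tA internal\tc"))
  m <- read_model(d)
  expect_s3_class(m, "metabolic_model")
  expect_equal(nrow(m$metabolites), 2)
  expect_equal(nrow(m$reactions), 3)
  expect_identical(model_genes(m), character(0))
  expect_equal(solve_fba(m)$objective_value, 5)
})

test_that("read/write round trip is the structural identity for both formats", {
  toy <- make_toy_model(gpr_scheme = "nested")$model
  d <- tempfile("rt_tsv")
  write_model(toy, d, format = "tsv")
  expect_true(model_diff_is_empty(compare_models(toy, read_model(d))))
  f <- tempfile("rt_sbml", fileext = ".xml")
  write_model(toy, f, format = "sbml")
  expect_true(model_diff_is_empty(compare_models(toy, read_model(f))))
})

test_that("nested GPR strings survive a round trip up to whitespace", {
  toy <- make_toy_model(gpr_scheme = "nested")$model
  f <- tempfile(fileext = ".xml")
  write_model(toy, f, "sbml")
  back <- read_model(f)
  norm <- function(s) gsub("\\s+", " ", s)
  expect_identical(norm(gpr_to_string(back$gpr[["BR1"]])),
                   norm(gpr_to_string(toy$gpr[["BR1"]])))
})

test_that("round trip preserves reaction counts on a larger generated model", {
  big <- make_toy_model(n_branches = 8, branch_yields = seq(0.2, 0.9, length.out = 8),
                        gpr_scheme = "nested")$model
  d <- tempfile("big")
  write_model(big, d, "tsv")
  expect_equal(nrow(read_model(d)$reactions), nrow(big$reactions))
})

test_that("SBML level 3 with fbc: bounds from parameters, GPR from geneProductAssociation", {
  f <- system.file("extdata", "mini_fbc.xml", package = "metnet")
  m <- read_model(f)
  expect_equal(nrow(m$metabolites), 3)
  expect_true(m$metabolites$boundary[m$metabolites$id == "x_b"])
  expect_equal(m$reactions$lb[m$reactions$id == "EX_glc_e"], -10)
  expect_equal(m$reactions$ub[m$reactions$id == "GLCt"], 1000)
  expect_equal(m$reactions$objective[m$reactions$id == "BIOMASS_mini"], 1)
  expect_setequal(model_genes(m), c("YAL001C", "YBR002W", "YCL003A"))
  expect_true(gpr_equivalent(m$gpr[["GLCt"]],
                             parse_gpr("YAL001C and (YBR002W or YCL003A)")))
  # boundary species excluded from mass balance: biomass can drain into x_b
  expect_equal(solve_fba(m)$objective_value, 5)
})

test_that("parsing is insensitive to reaction order in the file", {
  d <- tempfile("ord")
  toy <- make_toy_model(gpr_scheme = "simple")$model
  write_model(toy, d, "tsv")
  r <- readLines(file.path(d, "reactions.tsv"))
  writeLines(c(r[1], rev(r[-1])), file.path(d, "reactions.tsv"))
  m2 <- read_model(d)
  expect_true(model_diff_is_empty(compare_models(toy, m2)))
  expect_equal(solve_fba(m2)$objective_value, solve_fba(toy)$objective_value)
})

test_that("validation reports violations by entity without throwing", {
  toy <- make_toy_model()$model
  expect_identical(validate_model(toy), character(0))
  bad <- toy
  bad$reactions$lb[2] <- 5; bad$reactions$ub[2] <- 1
  v <- validate_model(bad)
  expect_length(v, 1)
  expect_match(v, bad$reactions$id[2], fixed = TRUE)
  bad2 <- toy
  bad2$stoichiometry[["GLCt"]]["X_missing"] <- 1
  v2 <- validate_model(bad2)
  expect_length(v2, 1)
  expect_match(v2, "GLCt")
  expect_match(v2, "X_missing")
})

test_that("read_model rejects malformed input with informative errors", {
  f <- tempfile(fileext = ".xml")
  writeLines("<sbml><model><listOfSpecies></sbml>", f)
  expect_error(read_model(f), "parse error")
  expect_error(read_model(tempfile()), "no such file")
  # duplicate reaction ids are a validation error
  d <- write_tsv_fixture(
    tempfile("dup"),
    c("id\tname\tequation\tlb\tub\tsubsystem\tgpr\tobjective",
      "R1\tx\tA_e ->\t-10\t0\t\t\t1",
      "R1\tx\tA_e ->\t0\t10\t\t\t0"),
    c("id\tname\tcompartment", "A_e\tA\te"))
  expect_error(read_model(d), "duplicate reaction id")
})

test_that("model diff pinpoints a removed reaction and nothing else", {
  toy <- make_toy_model()$model
  expect_true(model_diff_is_empty(compare_models(toy, toy)))
  sub <- subset_model(toy, setdiff(toy$reactions$id, "BR2"))
  d <- compare_models(toy, sub)
  expect_identical(d$reactions_only_in_a, "BR2")
  expect_identical(d$reactions_only_in_b, character(0))
})
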