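toy2 <- make_toy_model(n_branches = 2, branch_yields = c(0.5, 0.3),
                       gpr_scheme = "simple")

test_that("FBA optimum on the branched toy matches the vertex-enumeration oracle", {
  m <- toy2$model
  sol <- solve_fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 5)        # uptake 10 x best yield 0.5
  S <- stoich_matrix(m)
  obj <- as.numeric(m$reactions$id == "BIOMASS_toy")
  expect_equal(sol$objective_value,
               enum_lp_max(obj, S, m$reactions$lb, m$reactions$ub),
               tolerance = 1e-8)
  # mass balance of the returned distribution
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
  expect_true(all(sol$fluxes >= m$reactions$lb - 1e-9))
  expect_true(all(sol$fluxes <= m$reactions$ub + 1e-9))
})

test_that("closing the objective reaction forces a zero optimum", {
  m <- toy2$model
  m$reactions$ub[m$reactions$id == "BIOMASS_toy"] <- 0
  expect_equal(solve_fba(m)$objective_value, 0)
})

test_that("tightening any bound never increases the FBA optimum", {
  m <- toy2$model
  base <- solve_fba(m)$objective_value
  set.seed(41)
  for (i in 1:10) {
    m2 <- m
    j <- sample(nrow(m2$reactions), 1)
    shrink <- runif(1, 0.2, 0.9)
    m2$reactions$lb[j] <- m2$reactions$lb[j] * shrink
    m2$reactions$ub[j] <- m2$reactions$ub[j] * shrink
    s <- solve_fba(m2)
    val <- if (s$status == "optimal") s$objective_value else 0
    expect_lte(val, base + 1e-9)
  }
})

test_that("FBA optimum is invariant under reaction-order permutation", {
  m <- toy2$model
  set.seed(42)
  p <- sample(nrow(m$reactions))
  m2 <- m
  m2$reactions <- m2$reactions[p, ]
  m2$stoichiometry <- m2$stoichiometry[m2$reactions$id]
  m2$gpr <- m2$gpr[m2$reactions$id]
  expect_equal(solve_fba(m2)$objective_value, solve_fba(m)$objective_value,
               tolerance = 1e-9)
})

test_that("medium overrides rescale the optimum and unknown ids are rejected", {
  m <- toy2$model
  med <- medium_spec(data.frame(reaction = "EX_glc(e)", lb = -4, ub = NA))
  expect_equal(solve_fba(m, medium = med)$objective_value, 2)
  expect_error(solve_fba(m, medium = medium_spec(
    data.frame(reaction = "EX_nope", lb = -1, ub = NA))), "absent from model")
})

test_that("lexicographic product optimization: self-product and competing product", {
  m <- toy2$model
  self <- lex_maximize_product(m, product_reaction = "BIOMASS_toy")
  expect_equal(self$product, self$biomass)
  expect_equal(self$biomass, 5)
  # byproduct at fixed optimal biomass: biomass 5 forces all flux through
  # BR1 (yield 0.5), whose byproduct coefficient is 0.5 -> product 5
  comp <- lex_maximize_product(m, product_reaction = "EX_byp(e)")
  expect_equal(comp$biomass, 5, tolerance = 1e-9)
  expect_equal(comp$product, 5, tolerance = 1e-9)
  # with a growth floor at 60% of optimum, glucose can be diverted to the
  # 0.3-yield branch, whose byproduct yield is 0.7:
  # biomass 0.5 a + 0.3 b = 3 at a + b = 10 -> a = 0, b = 10 -> product 7
  fl <- lex_maximize_product(m, product_reaction = "EX_byp(e)", growth_floor = 0.6)
  expect_equal(fl$product, 7, tolerance = 1e-9)
})

test_that("lMOMA: identity without knockouts, hand-checked rerouting, lethality", {
  m <- toy2$model
  wt <- wildtype_reference(m)
  same <- solve_lmoma(m, wt, character(0))
  expect_equal(same$distance, 0, tolerance = 1e-8)
  expect_equal(unname(same$fluxes), unname(wt$fluxes), tolerance = 1e-8)

  # knock out the flux-carrying branch; the 1-parameter mutant space
  # (uptake u through BR2) gives distance d(u) minimized on a grid oracle
  mut <- solve_lmoma(m, wt, "BR1")
  d_of_u <- function(u) {
    v <- c(-u, u, 0, u, 0.7 * u, 0.7 * u, 0.3 * u)
    wtv <- c(-10, 10, 10, 0, 5, 5, 5)
    sum(abs(v - wtv))
  }
  us <- seq(0, 10, by = 1e-4)
  expect_equal(mut$distance, min(vapply(us, d_of_u, numeric(1))), tolerance = 1e-4)
  expect_equal(mut$distance, 180 / 7, tolerance = 1e-6)
  expect_equal(mut$growth, 15 / 7, tolerance = 1e-6)

  # L1 optimality: no random feasible mutant flux is closer to the wild type
  set.seed(43)
  for (i in 1:10) {
    u <- runif(1, 0, 10)
    expect_gte(d_of_u(u), mut$distance - 1e-6)
  }

  # genes lethal under FBA are lethal under lMOMA
  mut2 <- solve_lmoma(m, wt, c("BR1", "BR2"))
  expect_lt(mut2$growth, 1e-6)
})

test_that("robustness scan: linear pathway profile and forced-zero lethality", {
  lin <- hand_linear_model(uptake = 10, yield = 0.5)
  rb <- robustness_scan(lin, "At", n_points = 6)
  expect_equal(nrow(rb), 6)
  # biomass = yield * forced transport flux, checked per point against
  # the closed-form line
  expect_equal(rb$biomass, 0.5 * rb$forced_flux, tolerance = 1e-8)

  m <- toy2$model
  # forcing the sole transporter to zero abolishes growth...
  rb2 <- robustness_scan(m, "GLCt", n_points = 5)
  expect_equal(rb2$biomass[rb2$forced_flux == 0], 0, tolerance = 1e-9)
  # ...while forcing the redundant branch to zero leaves the optimum intact
  rb3 <- robustness_scan(m, "BR2", n_points = 5)
  expect_equal(rb3$biomass[rb3$forced_flux == 0], 5, tolerance = 1e-9)
})
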