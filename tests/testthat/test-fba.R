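test_that("chain toy attains the closed-form yield optimum with certificate", {
  toy <- make_toy_model(toy_model_spec("chain", uptake = 10, yields = 0.5))
  sol <- fba(toy$model)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, toy$truth$objective, tolerance = 1e-9)
  expect_lt(sol$max_sv_residual, 1e-7)
  S <- stoich_matrix(toy$model)
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-7)
  expect_true(all(sol$fluxes >= toy$model$reactions$lower_bound - 1e-7))
  expect_true(all(sol$fluxes <= toy$model$reactions$upper_bound + 1e-7))
})

test_that("nothing to eat means zero growth; no objective is an error", {
  toy <- make_toy_model(toy_model_spec("chain"))$model
  starved <- apply_medium(toy, tibble::tibble(
    reaction = character(), lower_bound = numeric(), upper_bound = numeric()))
  expect_equal(fba(starved)$objective_value, 0)
  toy$objective <- stats::setNames(numeric(), character())
  expect_error(fba(toy), "objective")
})

test_that("objective is invariant to column order and loop bounds", {
  toy <- make_toy_model(toy_model_spec("cycle"))
  z0 <- fba(toy$model)$objective_value
  perm <- toy$model
  idx <- rev(seq_len(nrow(perm$reactions)))
  perm$reactions <- perm$reactions[idx, ]
  expect_equal(fba(perm)$objective_value, z0, tolerance = 1e-9)
  tight <- set_bounds(toy$model, c("CYC1", "CYC2"), lower = -1, upper = 1)
  expect_equal(fba(tight)$objective_value, z0, tolerance = 1e-9)
})

test_that("splitting a reversible reaction into halves leaves the optimum", {
  m <- make_toy_model(toy_model_spec("chain"))$model
  # make the conversion reversible, then split it
  m <- set_bounds(m, "CONV", lower = -1000)
  z0 <- fba(m)$objective_value
  st <- m$stoichiometry[m$stoichiometry$reaction == "CONV", ]
  fwd <- st; fwd$reaction <- "CONV_f"
  bwd <- st; bwd$reaction <- "CONV_b"; bwd$coefficient <- -bwd$coefficient
  split <- metabolic_model(
    reactions = dplyr::bind_rows(
      m$reactions[m$reactions$id != "CONV", ],
      tibble::tibble(id = c("CONV_f", "CONV_b"), lower_bound = 0,
                     upper_bound = 1000)),
    metabolites = m$metabolites,
    stoichiometry = dplyr::bind_rows(
      m$stoichiometry[m$stoichiometry$reaction != "CONV", ], fwd, bwd),
    objective = m$objective, biomass_id = m$biomass_id)
  expect_equal(fba(split)$objective_value, z0, tolerance = 1e-9)
})

test_that("simplex matches brute-force enumeration on seeded random models", {
  for (seed in 1:60) {
    m <- make_random_model(n_mets = sample(4:6, 1), n_rxns = sample(4:6, 1),
                           seed = seed)
    a <- fba(m)
    b <- fba_brute_force(m)
    expect_identical(a$status, b$status, info = seed)
    if (a$status == "optimal") {
      expect_equal(a$objective_value, b$objective, tolerance = 1e-8,
                   info = seed)
    }
  }
})

test_that("pFBA keeps the optimum, kills cycles, and never exceeds FBA's norm", {
  cyc <- make_toy_model(toy_model_spec("cycle"))
  first <- fba(cyc$model)
  par <- pfba(cyc$model)
  expect_equal(par$objective_value, first$objective_value,
               tolerance = 1e-6 * max(1, abs(first$objective_value)))
  expect_equal(unname(par$fluxes[c("CYC1", "CYC2")]), c(0, 0),
               tolerance = 1e-8)
  expect_lte(attr(par, "sum_abs_flux"), sum(abs(first$fluxes)) + 1e-8)
})

test_that("pFBA on parallel paths matches the enumerated single-path norm", {
  toy <- make_toy_model(toy_model_spec("parallel", uptake = 10, yields = 0.5))
  par <- pfba(toy$model)
  expect_equal(par$objective_value, toy$truth$objective, tolerance = 1e-6)
  # enumerate the two pure-path optima by shutting one route at a time
  norms <- vapply(c("R_p1", "R_p2"), function(shut) {
    m <- set_bounds(toy$model, shut, lower = 0, upper = 0)
    sum(abs(pfba(m)$fluxes))
  }, numeric(1))
  expect_lte(attr(par, "sum_abs_flux"), min(norms) + 1e-6)
})

test_that("unique optimum: pFBA reproduces the FBA flux vector", {
  toy <- make_toy_model(toy_model_spec("chain"))
  a <- fba(toy$model)
  b <- pfba(toy$model)
  expect_equal(b$fluxes, a$fluxes, tolerance = 1e-7)
})

test_that("ATP turnover maximisation does stoichiometric bookkeeping", {
  em <- make_energy_model(atp_yield = 2, biomass_glc_cost = 1)
  # uptake 1, no growth: all carbon burns, r_ATP = 2
  expect_equal(maximize_atp_turnover(em, c(EX_glc = -1, BIOMASS = 0)), 2,
               tolerance = 1e-9)
  # nothing in, nothing out
  expect_equal(maximize_atp_turnover(em, c(EX_glc = 0, BIOMASS = 0)), 0,
               tolerance = 1e-9)
  # growth at the carbon-limited maximum leaves no ATP slack
  expect_equal(maximize_atp_turnover(em, c(EX_glc = -1, BIOMASS = 1)), 0,
               tolerance = 1e-9)
  # impossible growth on the supplied carbon is reported, not zeroed
  expect_error(maximize_atp_turnover(em, c(EX_glc = -1, BIOMASS = 2)),
               "infeasible")
  expect_error(maximize_atp_turnover(em, c(EX_nope = -1), ),
               "unknown reactions")
})

test_that("gene deletion follows the Boolean rules exactly", {
  toy <- make_toy_model(toy_model_spec("chain", gpr_pattern = "single"))$model
  ko <- apply_gene_deletion(toy, "g1")
  expect_equal(ko$reactions$upper_bound[ko$reactions$id == "CONV"], 0)

  iso <- make_toy_model(toy_model_spec("chain", gpr_pattern = "isozyme_or"))$model
  ko2 <- apply_gene_deletion(iso, "gA")
  expect_equal(ko2$reactions$upper_bound[ko2$reactions$id == "CONV"], 1000)

  nest <- make_toy_model(toy_model_spec("chain", gpr_pattern = "nested"))$model
  ko3 <- apply_gene_deletion(nest, c("g1", "g3"))
  expect_equal(ko3$reactions$upper_bound[ko3$reactions$id == "CONV"], 0)
  ko4 <- apply_gene_deletion(nest, "g1")
  expect_equal(ko4$reactions$upper_bound[ko4$reactions$id == "CONV"], 1000)

  expect_error(apply_gene_deletion(toy, "ghost"), "unknown genes")
})

test_that("flux solutions tidy and glance into well-formed tibbles", {
  toy <- make_toy_model(toy_model_spec("chain"))
  sol <- fba(toy$model)
  td <- tidy(sol)
  expect_named(td, c("reaction", "flux"))
  expect_equal(nrow(td), nrow(toy$model$reactions))
  gl <- glance(sol)
  expect_equal(gl$status, "optimal")
  expect_equal(gl$objective_value, 5)
})
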