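test_that("branched testbed recovers the analytic essentiality classes", {
  toy <- make_toy_model(toy_model_spec("branched", uptake = 10,
                                       yields = c(1, 0.5)))
  res <- classify_essentiality(toy$model)
  truth <- toy$truth$essentiality
  merged <- dplyr::inner_join(res, truth, by = "gene",
                              suffix = c("", "_truth"))
  expect_equal(nrow(merged), nrow(truth))
  expect_identical(merged$class, merged$class_truth)
  expect_equal(merged$ratio[merged$gene == "gH"], 0.5, tolerance = 1e-9)
})

test_that("single/isozyme/complex/nested patterns classify as generated", {
  for (pattern in c("single", "isozyme_or", "complex_and", "nested")) {
    toy <- make_toy_model(toy_model_spec("chain", gpr_pattern = pattern))
    res <- classify_essentiality(toy$model)
    truth <- toy$truth$essentiality
    merged <- dplyr::inner_join(res, truth, by = "gene",
                                suffix = c("", "_truth"))
    expect_identical(merged$class, merged$class_truth, info = pattern)
  }
})

test_that("classification matches the exhaustive truth-table + enumeration oracle", {
  specs <- list(
    toy_model_spec("branched", yields = c(1, 0.25)),
    toy_model_spec("chain", gpr_pattern = "nested"),
    toy_model_spec("parallel", gpr_pattern = "isozyme_or"))
  for (spec in specs) {
    toy <- make_toy_model(spec)
    got <- classify_essentiality(toy$model)
    want <- essentiality_oracle(toy$model)
    merged <- dplyr::inner_join(got, want, by = "gene",
                                suffix = c("", "_oracle"))
    expect_identical(merged$class, merged$class_oracle,
                     info = spec$topology)
    expect_equal(merged$mu_ko, merged$mu_ko_oracle, tolerance = 1e-7)
  }
})

test_that("deletions never help, and orphan genes are never essential", {
  toy <- make_toy_model(toy_model_spec("branched"))
  m <- toy$model
  m$genes <- c(m$genes, "g_orphan")
  res <- classify_essentiality(m)
  expect_true(all(res$mu_ko <= res$mu_wt + 1e-7))
  expect_identical(res$class[res$gene == "g_orphan"], "non_essential")
})

test_that("a non-growing wild type is an explicit error", {
  toy <- make_toy_model(toy_model_spec("chain"))$model
  starved <- apply_medium(toy, tibble::tibble(
    reaction = "EX_A", lower_bound = 0, upper_bound = 0))
  expect_error(classify_essentiality(starved),
               "wild type does not grow")
})

# two-substrate screening testbed: glucose or glycerol as carbon, ammonium
# or alanine as nitrogen, one biomass precursor needing C and N
screen_model <- function() {
  mets <- tibble::tibble(
    id = c("glc", "glyc", "nh4", "ala", "prec", "x"),
    name = NA_character_, compartment = "c",
    formula = c("C6H12O6", "C3H8O3", "H4N", "C3H7NO2", "", "X"),
    charge = 0L)
  rxn <- tibble::tibble(
    id = c("EX_glc", "EX_glyc", "EX_nh4", "EX_ala", "EX_x",
           "A_glc", "A_glyc", "N_ala", "biomass"),
    lower_bound = c(-10, 0, -10, 0, 0, 0, 0, 0, 0),
    upper_bound = 1000)
  st <- dplyr::bind_rows(
    tibble::tibble(reaction = "EX_glc", metabolite = "glc", coefficient = -1),
    tibble::tibble(reaction = "EX_glyc", metabolite = "glyc", coefficient = -1),
    tibble::tibble(reaction = "EX_nh4", metabolite = "nh4", coefficient = -1),
    tibble::tibble(reaction = "EX_ala", metabolite = "ala", coefficient = -1),
    tibble::tibble(reaction = "EX_x", metabolite = "x", coefficient = -1),
    tibble::tibble(reaction = "A_glc", metabolite = c("glc", "nh4", "prec"),
                   coefficient = c(-1, -1, 6)),
    tibble::tibble(reaction = "A_glyc", metabolite = c("glyc", "nh4", "prec"),
                   coefficient = c(-1, -1, 3)),
    tibble::tibble(reaction = "N_ala", metabolite = c("ala", "nh4", "prec"),
                   coefficient = c(-1, 1, 3)),
    tibble::tibble(reaction = "biomass", metabolite = "prec",
                   coefficient = -1))
  metabolic_model(reactions = rxn, metabolites = mets, stoichiometry = st,
                  biomass_id = "biomass")
}

test_that("source screen opens one candidate at a time on a carbon-mole basis", {
  m <- screen_model()
  base <- tibble::tibble(reaction = c("EX_glc", "EX_nh4"),
                         lower_bound = c(-10, -1000), upper_bound = 1000)
  res <- screen_growth_sources(
    m, base,
    tibble::tibble(reaction = c("EX_glc", "EX_glyc"), role = "carbon"),
    uptake_rate = 10)
  expect_true(all(res$growth_supporting))
  # per-C-mol normalisation: glycerol (3 C) is allowed twice the molar rate
  # and its pathway yields half the precursor per mole, so growth matches
  expect_equal(res$mu[res$source == "EX_glyc"],
               res$mu[res$source == "EX_glc"], tolerance = 1e-6)

  nres <- screen_growth_sources(
    m, base,
    tibble::tibble(reaction = c("EX_nh4", "EX_ala"), role = "nitrogen"),
    uptake_rate = 10)
  expect_true(all(nres$growth_supporting))

  # a candidate with no route to biomass fails the screen
  xres <- screen_growth_sources(
    m, base, tibble::tibble(reaction = "EX_x", role = "carbon"))
  expect_identical(xres$note, "unscreenable")
  expect_true(is.na(xres$growth_supporting))
})

test_that("closing the competing sources is what makes the screen selective", {
  m <- screen_model()
  base <- tibble::tibble(reaction = c("EX_glc", "EX_nh4"),
                         lower_bound = c(-10, -1000), upper_bound = 1000)
  # glycerol-only growth must not be fed by leftover glucose: shut the
  # glycerol pathway gene-lessly and the screen must go negative
  m2 <- set_bounds(m, "A_glyc", lower = 0, upper = 0)
  res <- screen_growth_sources(
    m2, base, tibble::tibble(reaction = "EX_glyc", role = "carbon"))
  expect_false(res$growth_supporting)
})
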