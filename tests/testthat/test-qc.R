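test_that("formula parsing matches the character-walk oracle", {
  expect_equal(parse_formula("H2O"), c(H = 2L, O = 1L),
               ignore_attr = TRUE)
  expect_equal(parse_formula("C6H12O6"), c(C = 6L, H = 12L, O = 6L),
               ignore_attr = TRUE)
  cases <- c("C10H12N5O13P3", "C6H11O9P", "C10H12N5O10P2", "H", "Fe2O3",
             "CuSO4", "C27H44O", "NaCl")
  for (f in cases) {
    got <- parse_formula(f)
    want <- formula_oracle(f)
    expect_equal(got[sort(names(got))], want[sort(names(want))],
                 ignore_attr = TRUE, info = f)
  }
  expect_true(attr(parse_formula("C5H8NO4R"), "generic"))
  expect_false(attr(parse_formula("C5H8NO4"), "generic"))
  expect_error(parse_formula("C6H12-O6"), "cannot parse")
  expect_length(parse_formula(""), 0)
})

# hexokinase testbed: glc + atp -> g6p + adp + h, balanced at pH 7.2 charges
hexokinase_model <- function(drop_proton = FALSE) {
  mets <- tibble::tibble(
    id = c("glc", "atp", "g6p", "adp", "h"),
    name = NA_character_, compartment = "c",
    formula = c("C6H12O6", "C10H12N5O13P3", "C6H11O9P", "C10H12N5O10P2", "H"),
    charge = c(0L, -4L, -2L, -3L, 1L))
  st <- tibble::tibble(
    reaction = "HEX",
    metabolite = c("glc", "atp", "g6p", "adp", "h"),
    coefficient = c(-1, -1, 1, 1, 1))
  if (drop_proton) st <- st[st$metabolite != "h", ]
  metabolic_model(
    reactions = tibble::tibble(id = "HEX", lower_bound = 0, upper_bound = 1000),
    metabolites = mets, stoichiometry = st,
    objective = c(HEX = 1), biomass_id = NA_character_)
}

test_that("balance checker: balanced phosphorylation, planted proton loss", {
  ok <- check_reaction_balance(hexokinase_model())
  expect_equal(ok$status, "balanced")
  expect_equal(ok$charge_residual, 0)
  expect_length(ok$residuals[[1]], 0)

  bad <- check_reaction_balance(hexokinase_model(drop_proton = TRUE))
  expect_equal(bad$status, "imbalanced")
  expect_equal(bad$charge_residual, -1)
  expect_equal(bad$residuals[[1]], c(H = -1))
})

test_that("empty or generic formulas and exchanges are undeterminable", {
  m <- hexokinase_model()
  m$metabolites$formula[m$metabolites$id == "g6p"] <- ""
  expect_equal(check_reaction_balance(m)$status, "undeterminable")

  toy <- make_toy_model(toy_model_spec("chain"))$model
  rep <- check_reaction_balance(toy)
  expect_equal(rep$status[rep$reaction == "EX_A"], "undeterminable")
  expect_equal(rep$status[rep$reaction == "CONV"], "balanced")
})

test_that("planted defects are flagged exactly, nothing else", {
  toy <- make_toy_model(toy_model_spec("chain", planted_gap = TRUE,
                                       planted_imbalance = TRUE))
  rep <- check_reaction_balance(toy$model)
  flagged <- rep$reaction[rep$status == "imbalanced"]
  expect_identical(flagged, toy$truth$imbalanced_reactions)
  gaps <- find_dead_end_metabolites(toy$model)
  expect_identical(gaps$dead_end, toy$truth$dead_end)
  expect_identical(gaps$no_consumption, "orphan")
  expect_identical(gaps$no_production, character())

  clean <- make_toy_model(toy_model_spec("chain"))
  expect_identical(find_dead_end_metabolites(clean$model)$dead_end,
                   character())
})

test_that("reversibility makes both directions admissible in gap finding", {
  # A exchange open, A <-> B reversible: B is producible and consumable
  m <- metabolic_model(
    reactions = tibble::tibble(
      id = c("EX_A", "RAB"),
      lower_bound = c(-10, -1000), upper_bound = c(1000, 1000)),
    metabolites = tibble::tibble(
      id = c("A", "B"), compartment = "c", formula = "", charge = 0L),
    stoichiometry = tibble::tibble(
      reaction = c("EX_A", "RAB", "RAB"),
      metabolite = c("A", "A", "B"), coefficient = c(-1, -1, 1)),
    objective = c(RAB = 1), biomass_id = NA_character_)
  expect_identical(find_dead_end_metabolites(m)$dead_end, character())

  # same network with the conversion frozen: B can never carry flux
  frozen <- set_bounds(m, "RAB", lower = 0, upper = 0)
  gaps <- find_dead_end_metabolites(frozen)
  expect_true("B" %in% gaps$no_production)
  expect_true("B" %in% gaps$no_consumption)
})

test_that("gap finder agrees with the LP admissible-direction oracle", {
  for (seed in 1:60) {
    m <- make_random_model(n_mets = sample(4:8, 1), n_rxns = sample(5:15, 1),
                           seed = seed)
    got <- find_dead_end_metabolites(m)
    want <- lp_gap_oracle(m)
    expect_identical(got$no_production, want$no_production, info = seed)
    expect_identical(got$no_consumption, want$no_consumption, info = seed)
  }
})

test_that("transitive mode exposes downstream blockage the root scan hides", {
  # A_ex -> A -> B -> C -> (nothing): C is a root dead end; with transitive
  # propagation B and then A..., reactions consuming blocked mets freeze
  m <- metabolic_model(
    reactions = tibble::tibble(
      id = c("EX_A", "R1", "R2"),
      lower_bound = c(-10, 0, 0), upper_bound = c(1000, 1000, 1000)),
    metabolites = tibble::tibble(
      id = c("A", "B", "C"), compartment = "c", formula = "", charge = 0L),
    stoichiometry = tibble::tibble(
      reaction = c("EX_A", "R1", "R1", "R2", "R2"),
      metabolite = c("A", "A", "B", "B", "C"),
      coefficient = c(-1, -1, 1, -1, 1)),
    objective = c(R2 = 1), biomass_id = NA_character_)
  root <- find_dead_end_metabolites(m)
  expect_identical(root$no_consumption, "C")
  trans <- find_dead_end_metabolites(m, transitive = TRUE)
  expect_true(all(c("B", "C") %in% trans$dead_end))
})

test_that("model summary counts partition reactions across compartments", {
  m <- metabolic_model(
    reactions = tibble::tibble(
      id = c("R_c", "T_cm", "R_m"),
      lower_bound = 0, upper_bound = 1000,
      gpr = c("g1", "", "g2")),
    metabolites = tibble::tibble(
      id = c("x_c", "y_c", "x_m", "y_m"),
      compartment = c("c", "c", "m", "m"), formula = "", charge = 0L),
    stoichiometry = tibble::tibble(
      reaction = c("R_c", "R_c", "T_cm", "T_cm", "R_m", "R_m"),
      metabolite = c("x_c", "y_c", "x_c", "x_m", "x_m", "y_m"),
      coefficient = c(-1, 1, -1, 1, -1, 1)),
    objective = c(R_m = 1), biomass_id = NA_character_)
  s <- summarize_model(m)
  cnt <- stats::setNames(s$counts$value, s$counts$quantity)
  expect_equal(cnt[["genes"]], 2)
  expect_equal(cnt[["reactions"]], 3)
  expect_equal(cnt[["metabolites_total"]], 4)
  expect_equal(cnt[["metabolites_unique"]], 2)  # x_c and x_m collapse to x
  expect_equal(sum(s$reactions_by_compartment$n), nrow(m$reactions))
  expect_equal(
    s$reactions_by_compartment$n[
      s$reactions_by_compartment$compartment == "intercompartmental/transport"],
    1)

  empty <- metabolic_model(
    reactions = tibble::tibble(id = character(), lower_bound = numeric(),
                               upper_bound = numeric()),
    metabolites = tibble::tibble(id = character(), compartment = character(),
                                 formula = character(), charge = integer()),
    stoichiometry = tibble::tibble(reaction = character(),
                                   metabolite = character(),
                                   coefficient = numeric()),
    objective = stats::setNames(numeric(), character()),
    biomass_id = NA_character_)
  se <- summarize_model(empty)
  expect_true(all(se$counts$value == 0))
})
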