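# Seeded generators for every input class the pipeline consumes: toy
# stoichiometric networks with known optima, essentiality classes and
# planted defects; chemostat series from the maintenance line
# r_ATP = GAM * mu + NGAM; perturbed flux vectors; expression calls.
# All generators are pure functions of (spec, seed): randomness is isolated
# so the global RNG stream is left untouched.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify a toy metabolic network
#'
#' @param topology One of `"chain"` (substrate -> product -> biomass),
#'   `"branched"` (two routes of different yield to the biomass precursor
#'   plus a shared step), `"parallel"` (two stoichiometrically identical
#'   routes), `"cycle"` (chain plus a free internal 2-reaction loop).
#' @param n_internal Extra pass-through intermediates spliced into the chain.
#' @param yields Carbon yield per route: one value for chain/parallel/cycle,
#'   two (high, low) for branched. A yield `y < 1` emits a balanced waste
#'   by-product so every generated reaction is mass-balanced.
#' @param gpr_pattern GPR placed on the conversion step: `"single"`,
#'   `"isozyme_or"`, `"complex_and"`, or `"nested"`
#'   (`"(g1 or g2) and g3"`). Ignored for branched, which carries its own
#'   route genes.
#' @param uptake Substrate uptake bound (mmol/gDCW/h, magnitude).
#' @param planted_gap Plant an orphan metabolite (producible, never
#'   consumed) recorded in the ground truth dead-end set.
#' @param planted_imbalance Plant a mass-imbalanced reaction (`R_bad`).
#' @param seed Integer seed (toy construction is deterministic; kept for the
#'   spec record).
#' @return A `toy_model_spec` list.
#' @export
toy_model_spec <- function(topology = c("chain", "branched", "parallel", "cycle"),
                           n_internal = 0, yields = NULL,
                           gpr_pattern = c("single", "isozyme_or",
                                           "complex_and", "nested", "none"),
                           uptake = 10, planted_gap = FALSE,
                           planted_imbalance = FALSE, seed = 1L) {
  topology <- match.arg(topology)
  gpr_pattern <- match.arg(gpr_pattern)
  if (is.null(yields)) {
    yields <- if (topology == "branched") c(1, 0.5) else 0.5
  }
  n_needed <- if (topology == "branched") 2L else 1L
  if (length(yields) != n_needed) {
    stop(sprintf("contradictory spec: topology '%s' needs %d yield(s), got %d",
                 topology, n_needed, length(yields)), call. = FALSE)
  }
  if (any(yields <= 0 | yields > 1)) {
    stop("yields must lie in (0, 1]", call. = FALSE)
  }
  structure(list(topology = topology, n_internal = as.integer(n_internal),
                 yields = yields, gpr_pattern = gpr_pattern, uptake = uptake,
                 planted_gap = planted_gap,
                 planted_imbalance = planted_imbalance,
                 seed = as.integer(seed)),
            class = "toy_model_spec")
}

toy_gpr <- function(pattern) {
  switch(pattern,
         single = "g1",
         isozyme_or = "gA or gB",
         complex_and = "gA and gB",
         nested = "(g1 or g2) and g3",
         none = "")
}

toy_gpr_truth <- function(pattern) {
  # analytic essentiality of genes on the single conversion step
  switch(pattern,
    single = tibble::tibble(gene = "g1", class = "essential", ratio = 0),
    isozyme_or = tibble::tibble(gene = c("gA", "gB"),
                                class = "non_essential", ratio = 1),
    complex_and = tibble::tibble(gene = c("gA", "gB"),
                                 class = "essential", ratio = 0),
    nested = tibble::tibble(gene = c("g1", "g2", "g3"),
                            class = c("non_essential", "non_essential",
                                      "essential"),
                            ratio = c(1, 1, 0)),
    none = tibble::tibble(gene = character(), class = character(),
                          ratio = numeric()))
}

#' Generate a toy metabolic model with known ground truth
#'
#' Builds a small, fully mass-balanced network (element alphabet C/H/O so
#' every balance is hand-checkable) together with the analytic record of what
#' the pipeline must find on it: the FBA optimum, per-gene essentiality
#' classes, and the planted dead-end and imbalance sets.
#'
#' Substrate A is a hexose (C6H12O6); a conversion of yield `y` produces
#' `y` biomass precursor B (same formula) plus `2(1-y)` waste W (C3H6O3),
#' which balances carbon exactly for any yield.
#'
#' @param spec A [toy_model_spec()].
#' @return List with `model` (a `metabolic_model`) and `truth` (list:
#'   `objective`, `essentiality` tibble, `dead_end`, `imbalanced_reactions`).
#' @examples
#' toy <- make_toy_model(toy_model_spec("chain", uptake = 10, yields = 0.5))
#' toy$truth$objective  # 5
#' @export
make_toy_model <- function(spec) {
  stopifnot(inherits(spec, "toy_model_spec"))
  y <- spec$yields
  mets <- tibble::tibble(
    id = c("A", "B", "W"),
    name = c("substrate", "biomass precursor", "waste"),
    compartment = "c",
    formula = c("C6H12O6", "C6H12O6", "C3H6O3"),
    charge = 0L)
  rxn <- list(); st <- list()
  add_rxn <- function(id, stoich, lb, ub, gpr = "", name = NA_character_) {
    rxn[[id]] <<- tibble::tibble(id = id, name = name, lower_bound = lb,
                                 upper_bound = ub, gpr = gpr,
                                 subsystem = NA_character_)
    st[[id]] <<- tibble::tibble(reaction = id, metabolite = names(stoich),
                                coefficient = unname(stoich))
  }
  conv_stoich <- function(yld, from = "A", to = "B") {
    s <- c(-1, yld)
    names(s) <- c(from, to)
    if (yld < 1) s <- c(s, W = 2 * (1 - yld))
    s
  }
  add_rxn("EX_A", c(A = -1), -spec$uptake, 1000)
  add_rxn("EX_W", c(W = -1), 0, 1000)
  chain_in <- "A"
  if (spec$n_internal > 0) {
    for (k in seq_len(spec$n_internal)) {
      mid <- sprintf("I%d", k)
      mets <- dplyr::bind_rows(mets, tibble::tibble(
        id = mid, name = sprintf("intermediate %d", k), compartment = "c",
        formula = "C6H12O6", charge = 0L))
      add_rxn(sprintf("CHAIN%d", k), stats::setNames(c(-1, 1), c(chain_in, mid)),
              0, 1000)
      chain_in <- mid
    }
  }
  truth_ess <- NULL
  if (spec$topology == "branched") {
    add_rxn("R_hi", conv_stoich(y[1], from = chain_in), 0, 1000, gpr = "gH")
    add_rxn("R_lo", conv_stoich(y[2], from = chain_in), 0, 1000, gpr = "gL")
    mets <- dplyr::bind_rows(mets, tibble::tibble(
      id = "P", name = "late precursor", compartment = "c",
      formula = "C6H12O6", charge = 0L))
    add_rxn("R_shared", c(B = -1, P = 1), 0, 1000, gpr = "gS")
    add_rxn("biomass", c(P = -1), 0, 1000)
    ratio_lo <- y[2] / y[1]
    truth_ess <- tibble::tibble(
      gene = c("gH", "gL", "gS"),
      class = c(if (ratio_lo < 1) "partially_essential" else "non_essential",
                "non_essential", "essential"),
      ratio = c(ratio_lo, 1, 0))
  } else {
    g <- toy_gpr(spec$gpr_pattern)
    if (spec$topology == "parallel") {
      gprs <- if (spec$gpr_pattern == "isozyme_or") c("gA", "gB") else c(g, g)
      add_rxn("R_p1", conv_stoich(y, from = chain_in), 0, 1000, gpr = gprs[1])
      add_rxn("R_p2", conv_stoich(y, from = chain_in), 0, 1000, gpr = gprs[2])
      truth_ess <- if (spec$gpr_pattern == "isozyme_or") {
        tibble::tibble(gene = c("gA", "gB"), class = "non_essential", ratio = 1)
      } else {
        toy_gpr_truth(spec$gpr_pattern)
      }
    } else {
      add_rxn("CONV", conv_stoich(y, from = chain_in), 0, 1000, gpr = g)
      truth_ess <- toy_gpr_truth(spec$gpr_pattern)
    }
    add_rxn("biomass", c(B = -1), 0, 1000)
    if (spec$topology == "cycle") {
      mets <- dplyr::bind_rows(mets, tibble::tibble(
        id = "Acyc", name = "cycle twin of A", compartment = "c",
        formula = "C6H12O6", charge = 0L))
      add_rxn("CYC1", c(A = -1, Acyc = 1), -1000, 1000)
      add_rxn("CYC2", c(Acyc = -1, A = 1), -1000, 1000)
    }
  }
  dead_end <- character()
  if (spec$planted_gap) {
    mets <- dplyr::bind_rows(mets, tibble::tibble(
      id = "orphan", name = "planted orphan", compartment = "c",
      formula = "C6H12O6", charge = 0L))
    add_rxn("R_orphan", c(A = -1, orphan = 1), 0, 1000)
    dead_end <- "orphan"
  }
  imbalanced <- character()
  if (spec$planted_imbalance) {
    add_rxn("R_bad", c(A = -1, W = 1), 0, 1000)
    imbalanced <- "R_bad"
  }
  model <- metabolic_model(
    reactions = dplyr::bind_rows(rxn),
    metabolites = mets,
    stoichiometry = dplyr::bind_rows(st),
    biomass_id = "biomass")
  z <- spec$uptake * max(y)
  list(model = model,
       truth = list(objective = z, essentiality = truth_ess,
                    dead_end = dead_end, imbalanced_reactions = imbalanced))
}

#' Generate a random small metabolic model
#'
#' Random sparse stoichiometry over a handful of metabolites, each reaction
#' reversible with probability 1/2 (bounds contain 0, so the zero flux vector
#' is always feasible and the LP is never unbounded), with a few exchange
#' reactions and a random single-reaction objective. Used to stress the LP
#' core and the gap finder against their brute-force oracles.
#'
#' @param n_mets,n_rxns Network size (internal reactions; exchanges added on
#'   top for `n_exchanges` random metabolites).
#' @param n_exchanges Number of exchange reactions.
#' @param seed Integer seed; the generator is a pure function of it.
#' @return A `metabolic_model`.
#' @export
make_random_model <- function(n_mets = 6, n_rxns = 8, n_exchanges = 2,
                              seed = 1L) {
  with_seed(seed, {
    mets <- tibble::tibble(
      id = sprintf("m%d", seq_len(n_mets)), name = NA_character_,
      compartment = "c", formula = "", charge = 0L)
    rxn <- list(); st <- list()
    for (j in seq_len(n_rxns)) {
      k <- sample(2:min(4, n_mets), 1)
      who <- sample(mets$id, k)
      coef <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
      if (all(coef > 0)) coef[1] <- -coef[1]
      if (all(coef < 0)) coef[1] <- -coef[1]
      rev <- stats::runif(1) < 0.5
      rid <- sprintf("r%d", j)
      rxn[[rid]] <- tibble::tibble(
        id = rid, name = NA_character_, lower_bound = if (rev) -10 else 0,
        upper_bound = 10, gpr = "", subsystem = NA_character_)
      st[[rid]] <- tibble::tibble(reaction = rid, metabolite = who,
                                  coefficient = coef)
    }
    for (mid in sample(mets$id, min(n_exchanges, n_mets))) {
      rid <- paste0("EX_", mid)
      rev <- stats::runif(1) < 0.7
      rxn[[rid]] <- tibble::tibble(
        id = rid, name = NA_character_, lower_bound = if (rev) -10 else 0,
        upper_bound = 10, gpr = "", subsystem = NA_character_)
      st[[rid]] <- tibble::tibble(reaction = rid, metabolite = mid,
                                  coefficient = -1)
    }
    all_rxn <- dplyr::bind_rows(rxn)
    objective <- stats::setNames(1, sample(all_rxn$id, 1))
    metabolic_model(reactions = all_rxn, metabolites = mets,
                    stoichiometry = dplyr::bind_rows(st),
                    objective = objective, biomass_id = NA_character_)
  })
}

#' Minimal energy model for maintenance fitting
#'
#' A stylised aerobic network in which one glucose yields exactly
#' `atp_yield` ATP and one unit of growth drains `biomass_glc_cost` glucose
#' with no ATP term (growth-associated ATP is deliberately excluded so that
#' maximising the ATP maintenance flux at pinned rates measures the total
#' maintenance-available ATP, the quantity the maintenance line is fitted
#' to).
#'
#' @param atp_yield mmol ATP per mmol glucose through catabolism.
#' @param biomass_glc_cost mmol glucose drained per gDCW of biomass.
#' @return A `metabolic_model` with reactions `EX_glc`, `EX_o2`, `EX_co2`,
#'   `CAT`, `ATPM`, `BIOMASS`, `EX_biomass`.
#' @export
make_energy_model <- function(atp_yield = 16, biomass_glc_cost = 10) {
  mets <- tibble::tibble(
    id = c("glc", "o2", "co2", "atp", "adp", "biomass_m"),
    name = c("glucose", "oxygen", "carbon dioxide", "ATP", "ADP", "biomass"),
    compartment = "c",
    formula = c("C6H12O6", "O2", "CO2", "", "", ""),
    charge = 0L)
  rxn <- tibble::tibble(
    id = c("EX_glc", "EX_o2", "EX_co2", "CAT", "ATPM", "BIOMASS", "EX_biomass"),
    name = NA_character_,
    lower_bound = c(-10, -1000, 0, 0, 0, 0, 0),
    upper_bound = c(0, 0, 1000, 1000, 1000, 1000, 1000),
    gpr = "", subsystem = NA_character_)
  st <- dplyr::bind_rows(
    tibble::tibble(reaction = "EX_glc", metabolite = "glc", coefficient = -1),
    tibble::tibble(reaction = "EX_o2", metabolite = "o2", coefficient = -1),
    tibble::tibble(reaction = "EX_co2", metabolite = "co2", coefficient = -1),
    tibble::tibble(reaction = "CAT",
                   metabolite = c("glc", "o2", "adp", "atp", "co2"),
                   coefficient = c(-1, -6, -atp_yield, atp_yield, 6)),
    tibble::tibble(reaction = "ATPM", metabolite = c("atp", "adp"),
                   coefficient = c(-1, 1)),
    tibble::tibble(reaction = "BIOMASS",
                   metabolite = c("glc", "biomass_m"),
                   coefficient = c(-biomass_glc_cost, 1)),
    tibble::tibble(reaction = "EX_biomass", metabolite = "biomass_m",
                   coefficient = -1))
  metabolic_model(reactions = rxn, metabolites = mets, stoichiometry = st,
                  biomass_id = "BIOMASS")
}

#' Simulate chemostat observations from the maintenance line
#'
#' Generates per-dilution-rate observations whose maximal ATP turnover obeys
#' `r_ATP = gam * mu + ngam` exactly (plus optional Gaussian noise), with
#' glucose uptake back-calculated through the companion
#' [make_energy_model()] stoichiometry:
#' `q_glc = -(r_ATP / atp_yield + biomass_glc_cost * mu)`.
#'
#' @param mu Vector of dilution rates (= steady-state growth rates, 1/h).
#' @param gam Growth-associated maintenance, mmol ATP/gDCW (slope).
#' @param ngam Non-growth-associated maintenance, mmol ATP/gDCW/h
#'   (intercept).
#' @param noise_sd Gaussian noise s.d. on `r_ATP`; 0 gives the exact line.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param atp_yield,biomass_glc_cost Must match the companion energy model.
#' @return Tibble with `mu`, `EX_glc` (measured uptake, negative),
#'   `r_atp_true` (noise-free line) and `r_atp` (noisy).
#' @examples
#' simulate_chemostat(c(0.05, 0.10))  # r_ATP 3.54 and 4.56
#' @export
simulate_chemostat <- function(mu, gam = 20.4, ngam = 2.52, noise_sd = 0,
                               seed = NULL, atp_yield = 16,
                               biomass_glc_cost = 10) {
  if (any(mu <= 0)) stop("dilution rates must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  r_true <- gam * mu + ngam
  eps <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(mu), 0, noise_sd))
  } else {
    rep(0, length(mu))
  }
  r_obs <- r_true + eps
  tibble::tibble(
    mu = mu,
    EX_glc = -(r_obs / atp_yield + biomass_glc_cost * mu),
    r_atp_true = r_true,
    r_atp = r_obs)
}

#' Perturb a flux vector with Gaussian noise
#'
#' @param fluxes Named numeric vector.
#' @param sd Noise standard deviation (>= 0; 0 returns the input unchanged).
#' @param seed Integer seed.
#' @return Named numeric vector with the same names.
#' @export
perturb_fluxes <- function(fluxes, sd, seed = NULL) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (sd == 0) return(fluxes)
  fluxes + with_seed(seed, stats::rnorm(length(fluxes), 0, sd))
}

#' Simulate an expression call set
#'
#' Each model gene is called expressed independently with probability
#' `p_expressed`.
#'
#' @param model A `metabolic_model`.
#' @param p_expressed Probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Character vector of expressed gene ids.
#' @export
simulate_expression <- function(model, p_expressed, seed = NULL) {
  if (p_expressed < 0 || p_expressed > 1) {
    stop("p_expressed must lie in [0, 1]", call. = FALSE)
  }
  keep <- with_seed(seed,
                    stats::runif(length(model$genes)) < p_expressed)
  model$genes[keep]
}
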