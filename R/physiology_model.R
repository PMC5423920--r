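#' Biomass macromolecular composition
#'
#' Mass fractions (g per gDCW) of the six biomass pools, plus the
#' growth-associated (GAM, mmol ATP/gDCW) and non-growth-associated (NGAM,
#' mmol ATP/gDCW/h) maintenance. Defaults are the midpoints of the
#' physiological ranges scanned by [sensitivity_scan()] (protein 37-47%,
#' lipid 6.2-16.2%, RNA 6.6-16.6%, DNA 0.1-1.0%, carbohydrate 26.9-36.9%),
#' with the small-molecule pool absorbing the remainder so the fractions sum
#' to 1.
#'
#' @param protein,lipid,rna,dna,carbohydrate,pool Mass fractions (g/gDCW).
#' @param gam,ngam Maintenance parameters (>= 0).
#' @return A `biomass_composition` object.
#' @export
biomass_composition <- function(protein = 0.42, lipid = 0.112, rna = 0.116,
                                dna = 0.0055, carbohydrate = 0.319,
                                pool = NULL, gam = 20.4, ngam = 2.52) {
  named <- c(protein = protein, lipid = lipid, rna = rna, dna = dna,
             carbohydrate = carbohydrate)
  if (is.null(pool)) pool <- 1 - sum(named)
  fractions <- c(named, pool = pool)
  if (any(fractions < 0)) {
    stop("biomass fractions must be non-negative; got pool = ",
         signif(pool, 4), call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("biomass fractions must sum to 1 (got ", signif(sum(fractions), 6),
         ")", call. = FALSE)
  }
  if (gam < 0 || ngam < 0) stop("GAM and NGAM must be >= 0", call. = FALSE)
  structure(list(fractions = fractions, gam = gam, ngam = ngam),
            class = "biomass_composition")
}

#' @export
print.biomass_composition <- function(x, ...) {
  cat("<biomass_composition> ",
      paste(sprintf("%s %.3g", names(x$fractions), x$fractions),
            collapse = ", "),
      sprintf("; GAM %.4g mmol ATP/gDCW, NGAM %.4g mmol ATP/gDCW/h\n",
              x$gam, x$ngam), sep = "")
  invisible(x)
}

default_macromolecule_costs <- function() {
  # per gram of pool: precursor and ATP demand (mmol/g); lipid is the
  # ATP-expensive pool, protein/RNA/DNA additionally draw ammonium
  list(
    protein      = c(pyr = 11.8, atp = 18, nh4 = 1),
    lipid        = c(pyr = 20,   atp = 40),
    rna          = c(pyr = 11,   atp = 12, nh4 = 0.5),
    dna          = c(pyr = 11,   atp = 12, nh4 = 0.5),
    carbohydrate = c(glc = 5.55, atp = 8),
    pool         = c(pyr = 10,   atp = 10))
}

#' Stylised aerobic growth model with a tunable biomass equation
#'
#' A compact respiratory network (glycolysis, pyruvate oxidation, oxidative
#' phosphorylation at P/O = 2) feeding six macromolecule pools whose
#' per-gram precursor and ATP costs are configurable. The biomass reaction
#' drains the pools in their mass fractions plus the GAM ATP; a dedicated
#' `ATPM` hydrolysis reaction with lower bound NGAM enforces maintenance.
#' Used as the full-pathway fixture for chemostat prediction and the
#' biomass/NGAM sensitivity scans.
#'
#' @param composition A [biomass_composition()].
#' @param costs Named list of per-gram cost vectors (`pyr`/`glc`/`atp`/
#'   `nh4`) per pool; see `default_macromolecule_costs()`.
#' @return A `metabolic_model` carrying the composition and cost metadata in
#'   `$biomass_meta`, as required by [set_biomass_composition()] and
#'   [sensitivity_scan()].
#' @export
make_physiology_model <- function(composition = biomass_composition(),
                                  costs = default_macromolecule_costs()) {
  pools <- names(composition$fractions)
  stopifnot(setequal(names(costs), pools))
  mets <- tibble::tibble(
    id = c("glc", "o2", "co2", "nh4", "pyr", "atp", "adp", "nadh",
           pools, "biomass_m"),
    name = NA_character_, compartment = "c", formula = "", charge = 0L)
  mets$formula[mets$id == "glc"] <- "C6H12O6"
  mets$formula[mets$id == "o2"] <- "O2"
  mets$formula[mets$id == "co2"] <- "CO2"
  mets$formula[mets$id == "nh4"] <- "H4N"
  rxn <- list(); st <- list()
  add <- function(id, stoich, lb, ub) {
    rxn[[id]] <<- tibble::tibble(id = id, name = NA_character_,
                                 lower_bound = lb, upper_bound = ub,
                                 gpr = "", subsystem = NA_character_)
    st[[id]] <<- tibble::tibble(reaction = id, metabolite = names(stoich),
                                coefficient = unname(stoich))
  }
  add("EX_glc", c(glc = -1), 0, 1000)
  add("EX_o2", c(o2 = -1), -1000, 0)
  add("EX_nh4", c(nh4 = -1), -1000, 0)
  add("EX_co2", c(co2 = -1), 0, 1000)
  add("GLYC", c(glc = -1, adp = -2, pyr = 2, atp = 2, nadh = 2), 0, 1000)
  add("TCA", c(pyr = -1, co2 = 3, nadh = 5), 0, 1000)
  add("OXP", c(nadh = -1, o2 = -0.5, adp = -2, atp = 2), 0, 1000)
  for (p in pools) {
    cost <- costs[[p]]
    stoich <- -cost
    names(stoich) <- names(cost)
    atp_used <- if ("atp" %in% names(cost)) cost[["atp"]] else 0
    stoich <- c(stoich, stats::setNames(1, p))
    if (atp_used > 0) stoich <- c(stoich, adp = atp_used)
    add(paste0("SYN_", p), stoich, 0, 1000)
  }
  add("ATPM", c(atp = -1, adp = 1), composition$ngam, 1000)
  bio <- c(stats::setNames(-composition$fractions, pools),
           atp = -composition$gam, adp = composition$gam, biomass_m = 1)
  add("biomass", bio, 0, 1000)
  add("EX_biomass", c(biomass_m = -1), 0, 1000)
  model <- metabolic_model(reactions = dplyr::bind_rows(rxn),
                           metabolites = mets,
                           stoichiometry = dplyr::bind_rows(st),
                           biomass_id = "biomass")
  model$biomass_meta <- list(composition = composition, costs = costs,
                             maintenance_id = "ATPM", pool_mets = pools)
  model
}

#' Rebuild the biomass reaction from a composition
#'
#' Replaces the biomass stoichiometry with the given mass fractions and GAM,
#' and sets the maintenance reaction's lower bound to the NGAM. The model
#' must carry `$biomass_meta` (as built by [make_physiology_model()]).
#'
#' @param model A `metabolic_model` with biomass metadata.
#' @param composition A [biomass_composition()].
#' @return A modified copy of the model.
#' @export
set_biomass_composition <- function(model, composition) {
  meta <- model$biomass_meta
  if (is.null(meta)) {
    stop("model carries no biomass metadata; build it with make_physiology_model()",
         call. = FALSE)
  }
  bid <- model$biomass_id
  keep <- model$stoichiometry$reaction != bid
  bio <- c(stats::setNames(-composition$fractions, meta$pool_mets),
           atp = -composition$gam, adp = composition$gam, biomass_m = 1)
  bio <- bio[bio != 0]
  model$stoichiometry <- dplyr::bind_rows(
    model$stoichiometry[keep, , drop = FALSE],
    tibble::tibble(reaction = bid, metabolite = names(bio),
                   coefficient = unname(bio)))
  model <- set_bounds(model, meta$maintenance_id, lower = composition$ngam)
  model$biomass_meta$composition <- composition
  validate_model(model)
  model
}
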