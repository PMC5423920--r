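#' Construct a metabolic model
#'
#' A `metabolic_model` bundles the three tables that define a constraint-based
#' model — metabolites, bounded reactions, and the sparse stoichiometry in
#' long (reaction, metabolite, coefficient) form — together with the gene set,
#' the objective row and the biomass reaction id. The stoichiometric matrix S
#' (one row per metabolite, one column per reaction) is assembled on demand by
#' [stoich_matrix()].
#'
#' Exchange reactions (reactions touching exactly one metabolite, i.e.
#' crossing the system boundary) are auto-detected. By convention a negative
#' exchange flux is uptake and a positive one secretion. Default bounds are
#' (-1000, 1000) for reversible reactions; irreversible reactions have a
#' non-negative lower bound.
#'
#' @param reactions Tibble with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gpr` (rule text, `""`/`NA` for none), `subsystem`.
#'   Missing optional columns are filled with defaults.
#' @param metabolites Tibble with columns `id`, `name`, `compartment`,
#'   `formula` (empty string when unknown), `charge`.
#' @param stoichiometry Long tibble with columns `reaction`, `metabolite`,
#'   `coefficient` (nonzero; negative = consumed, positive = produced).
#' @param genes Character vector of gene ids; when `NULL`, derived from the
#'   GPR rules.
#' @param objective Named numeric vector of objective coefficients keyed by
#'   reaction id; default: coefficient 1 on the biomass reaction.
#' @param biomass_id Id of the biomass reaction; default: the unique reaction
#'   whose id contains "biomass" (case-insensitive), if any.
#' @param compartments Declared compartment tokens; default: those used by
#'   the metabolite table.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(reactions, metabolites, stoichiometry,
                            genes = NULL, objective = NULL,
                            biomass_id = NULL, compartments = NULL) {
  reactions <- tibble::as_tibble(reactions)
  metabolites <- tibble::as_tibble(metabolites)
  stoichiometry <- tibble::as_tibble(stoichiometry)

  if (!all(c("id") %in% names(reactions))) {
    stop("`reactions` needs at least an `id` column", call. = FALSE)
  }
  if (!all(c("id") %in% names(metabolites))) {
    stop("`metabolites` needs at least an `id` column", call. = FALSE)
  }
  reactions <- fill_defaults(reactions, list(
    name = NA_character_, lower_bound = -1000, upper_bound = 1000,
    gpr = "", subsystem = NA_character_))
  metabolites <- fill_defaults(metabolites, list(
    name = NA_character_, compartment = "c", formula = "",
    charge = 0L))
  metabolites$formula[is.na(metabolites$formula)] <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  stoichiometry <- stoichiometry[stoichiometry$coefficient != 0, , drop = FALSE]

  counts <- table(stoichiometry$reaction)
  reactions$is_exchange <- unname(counts[reactions$id] == 1L)
  reactions$is_exchange[is.na(reactions$is_exchange)] <- FALSE

  gpr_parsed <- lapply(stats::setNames(reactions$gpr, reactions$id), function(g) {
    if (!nzchar(g)) NULL else parse_gpr(g)
  })
  if (is.null(genes)) {
    genes <- unique(unlist(lapply(gpr_parsed, function(g) {
      if (is.null(g)) character() else gpr_genes(g)
    })))
  }
  if (is.null(compartments)) {
    compartments <- unique(metabolites$compartment)
  }
  if (is.null(biomass_id)) {
    hits <- grep("biomass", reactions$id, ignore.case = TRUE, value = TRUE)
    if (length(hits) > 1L) {
      hits <- grep("^EX_", hits, value = TRUE, invert = TRUE)
    }
    biomass_id <- if (length(hits) == 1L) hits else NA_character_
  }
  if (is.null(objective)) {
    objective <- if (!is.na(biomass_id)) {
      stats::setNames(1, biomass_id)
    } else {
      stats::setNames(numeric(), character())
    }
  }

  model <- structure(list(
    reactions = reactions,
    metabolites = metabolites,
    stoichiometry = stoichiometry,
    genes = as.character(genes),
    compartments = as.character(compartments),
    objective = objective,
    biomass_id = biomass_id,
    gpr_parsed = gpr_parsed
  ), class = "metabolic_model")
  validate_model(model)
  model
}

fill_defaults <- function(tbl, defaults) {
  for (nm in names(defaults)) {
    if (!nm %in% names(tbl)) tbl[[nm]] <- defaults[[nm]]
  }
  tbl
}

#' Validate a metabolic model
#'
#' Enforces the structural invariants: unique reaction and metabolite ids,
#' every stoichiometry entry resolving to a declared reaction and metabolite,
#' `lower_bound <= upper_bound`, declared compartments, GPR genes inside the
#' model gene set, and a nonempty objective keyed by reaction ids (when set).
#' All violations are collected and reported together.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly; errors with the full list of offenders
#'   otherwise.
#' @export
validate_model <- function(model) {
  problems <- character()
  rxn <- model$reactions
  met <- model$metabolites
  dup_r <- rxn$id[duplicated(rxn$id)]
  if (length(dup_r)) {
    problems <- c(problems, paste0("duplicate reaction ids: ",
                                   paste(unique(dup_r), collapse = ", ")))
  }
  dup_m <- met$id[duplicated(met$id)]
  if (length(dup_m)) {
    problems <- c(problems, paste0("duplicate metabolite ids: ",
                                   paste(unique(dup_m), collapse = ", ")))
  }
  bad_bounds <- rxn$id[rxn$lower_bound > rxn$upper_bound]
  if (length(bad_bounds)) {
    problems <- c(problems, paste0("lower_bound > upper_bound for: ",
                                   paste(bad_bounds, collapse = ", ")))
  }
  dangling_m <- setdiff(model$stoichiometry$metabolite, met$id)
  if (length(dangling_m)) {
    problems <- c(problems, paste0("stoichiometry references undeclared metabolites: ",
                                   paste(dangling_m, collapse = ", ")))
  }
  dangling_r <- setdiff(model$stoichiometry$reaction, rxn$id)
  if (length(dangling_r)) {
    problems <- c(problems, paste0("stoichiometry references undeclared reactions: ",
                                   paste(dangling_r, collapse = ", ")))
  }
  bad_comp <- setdiff(met$compartment, model$compartments)
  if (length(bad_comp)) {
    problems <- c(problems, paste0("undeclared compartments: ",
                                   paste(bad_comp, collapse = ", ")))
  }
  gpr_gene <- unique(unlist(lapply(model$gpr_parsed, function(g) {
    if (is.null(g)) character() else gpr_genes(g)
  })))
  missing_genes <- setdiff(gpr_gene, model$genes)
  if (length(missing_genes)) {
    problems <- c(problems, paste0("GPR genes not in model gene set: ",
                                   paste(missing_genes, collapse = ", ")))
  }
  if (length(model$objective)) {
    bad_obj <- setdiff(names(model$objective), rxn$id)
    if (length(bad_obj)) {
      problems <- c(problems, paste0("objective keys are not reaction ids: ",
                                     paste(bad_obj, collapse = ", ")))
    }
    if (all(model$objective == 0)) {
      problems <- c(problems, "objective has no nonzero coefficient")
    }
  }
  if (length(problems)) {
    stop("invalid metabolic model:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(model)
}

#' Assemble the stoichiometric matrix S
#'
#' @param model A `metabolic_model`.
#' @return A dense numeric matrix of shape m x n (metabolites x reactions)
#'   with dimnames, such that steady state reads `S %*% v = 0`.
#' @export
stoich_matrix <- function(model) {
  m <- nrow(model$metabolites)
  n <- nrow(model$reactions)
  S <- matrix(0, m, n, dimnames = list(model$metabolites$id, model$reactions$id))
  st <- model$stoichiometry
  S[cbind(match(st$metabolite, model$metabolites$id),
          match(st$reaction, model$reactions$id))] <- st$coefficient
  S
}

#' Exchange reactions of a model
#'
#' @param model A `metabolic_model`.
#' @return Tibble of the single-metabolite boundary reactions with their
#'   metabolite id joined on.
#' @export
exchange_reactions <- function(model) {
  ex <- dplyr::filter(model$reactions, .data$is_exchange)
  st <- dplyr::distinct(model$stoichiometry, .data$reaction, .keep_all = TRUE)
  dplyr::left_join(ex, dplyr::select(st, reaction = "reaction", metabolite = "metabolite"),
                   by = c(id = "reaction"))
}

#' Set flux bounds on named reactions
#'
#' @param model A `metabolic_model`.
#' @param reaction_ids Character vector of reaction ids.
#' @param lower,upper Replacement bounds, recycled along `reaction_ids`;
#'   `NA` leaves the existing bound in place.
#' @return A modified copy of the model.
#' @export
set_bounds <- function(model, reaction_ids, lower = NA, upper = NA) {
  idx <- match(reaction_ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction ids: ",
         paste(reaction_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  lower <- rep_len(lower, length(idx))
  upper <- rep_len(upper, length(idx))
  keep <- !is.na(lower)
  model$reactions$lower_bound[idx[keep]] <- lower[keep]
  keep <- !is.na(upper)
  model$reactions$upper_bound[idx[keep]] <- upper[keep]
  validate_model(model)
  model
}

#' Apply a medium specification to a model
#'
#' A medium is the set of exchange-reaction bounds that define what the cell
#' may take up and secrete: uptake is a negative lower bound, secretion a
#' positive upper bound. Exchange reactions not listed in the medium have
#' their lower bound set to 0 (no uptake), so the medium fully determines the
#' nutrients available. Stoichiometry is never touched.
#'
#' @param model A `metabolic_model`.
#' @param medium Tibble (or data frame) with columns `reaction`,
#'   `lower_bound`, `upper_bound`, keyed by exchange-reaction id.
#' @return A modified copy of the model; the input model is unchanged.
#' @examples
#' m <- make_toy_model(toy_model_spec("chain"))$model
#' grown <- apply_medium(m, tibble::tibble(
#'   reaction = "EX_A", lower_bound = -10, upper_bound = 0))
#' @export
apply_medium <- function(model, medium) {
  medium <- tibble::as_tibble(medium)
  stopifnot(all(c("reaction", "lower_bound", "upper_bound") %in% names(medium)))
  ex_ids <- model$reactions$id[model$reactions$is_exchange]
  bad <- setdiff(medium$reaction, ex_ids)
  if (length(bad)) {
    stop("medium keys are not exchange reactions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  closed <- setdiff(ex_ids, medium$reaction)
  model$reactions$lower_bound[match(closed, model$reactions$id)] <-
    pmax(0, model$reactions$lower_bound[match(closed, model$reactions$id)])
  idx <- match(medium$reaction, model$reactions$id)
  model$reactions$lower_bound[idx] <- medium$lower_bound
  model$reactions$upper_bound[idx] <- medium$upper_bound
  validate_model(model)
  model
}

#' Read a medium specification from YAML
#'
#' The YAML maps exchange-reaction ids to `[lower, upper]` pairs.
#'
#' @param path Path to the YAML file.
#' @return A medium tibble for [apply_medium()].
#' @export
read_medium_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  tibble::tibble(
    reaction = names(raw),
    lower_bound = vapply(raw, function(x) as.numeric(x[[1]]), numeric(1)),
    upper_bound = vapply(raw, function(x) as.numeric(x[[2]]), numeric(1))
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d metabolites x %d reactions, %d genes, %d compartments\n",
              nrow(x$metabolites), nrow(x$reactions), length(x$genes),
              length(x$compartments)))
  if (!is.na(x$biomass_id)) cat("  biomass: ", x$biomass_id, "\n", sep = "")
  if (length(x$objective)) {
    cat("  objective: ",
        paste(sprintf("%g*%s", unname(x$objective), names(x$objective)),
              collapse = " + "), "\n", sep = "")
  }
  invisible(x)
}
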