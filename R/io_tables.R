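# Tabular model dialect: three UTF-8 TSV/CSV files.
#   reactions:   id, name, equation, lower_bound, upper_bound, gpr, subsystem
#   metabolites: id, name, compartment, formula, charge
#   genes:       gene (one id per row; optional file)
# Equation grammar: "2 A_c + B_c -> C_c" (irreversible) or "<=>" (reversible);
# an empty side marks a boundary/exchange reaction, e.g. "A_e <=>".

#' Parse a reaction equation string
#'
#' @param equation Equation text, e.g. `"glc_c + atp_c -> g6p_c + adp_c"`.
#'   The arrow `->` (irreversible) or `<=>`/`<->` (reversible) separates
#'   substrates from products; coefficients default to 1.
#' @return List with `stoichiometry` (tibble of metabolite, coefficient) and
#'   `reversible` (logical).
#' @export
parse_reaction_equation <- function(equation) {
  if (!is.character(equation) || length(equation) != 1L || is.na(equation)) {
    stop("`equation` must be a single string", call. = FALSE)
  }
  arrow <- regmatches(equation, regexpr("<=>|<->|-->|->", equation))
  if (length(arrow) == 0L) {
    stop("equation has no arrow ('->' or '<=>'): ", equation, call. = FALSE)
  }
  reversible <- arrow %in% c("<=>", "<->")
  sides <- strsplit(equation, "<=>|<->|-->|->")[[1]]
  lhs <- if (length(sides) >= 1) sides[1] else ""
  rhs <- if (length(sides) >= 2) sides[2] else ""
  parse_side <- function(text, sign) {
    text <- trimws(text)
    if (!nzchar(text)) {
      return(tibble::tibble(metabolite = character(), coefficient = numeric()))
    }
    terms <- trimws(strsplit(text, "\\+")[[1]])
    terms <- terms[nzchar(terms)]
    parsed <- lapply(terms, function(tm) {
      parts <- strsplit(tm, "\\s+")[[1]]
      if (length(parts) == 2L && !is.na(suppressWarnings(as.numeric(parts[1])))) {
        c(parts[2], parts[1])
      } else if (length(parts) == 1L) {
        c(parts[1], "1")
      } else {
        stop("cannot parse equation term: '", tm, "'", call. = FALSE)
      }
    })
    tibble::tibble(
      metabolite = vapply(parsed, `[`, character(1), 1),
      coefficient = sign * as.numeric(vapply(parsed, `[`, character(1), 2))
    )
  }
  st <- dplyr::bind_rows(parse_side(lhs, -1), parse_side(rhs, +1))
  st <- st |>
    dplyr::summarise(coefficient = sum(.data$coefficient), .by = "metabolite") |>
    dplyr::filter(.data$coefficient != 0)
  list(stoichiometry = st, reversible = reversible)
}

#' Serialise a reaction's stoichiometry to an equation string
#'
#' @param stoichiometry Tibble with `metabolite`, `coefficient`.
#' @param reversible Use `<=>` instead of `->`.
#' @return Equation string; [parse_reaction_equation()] inverts it exactly.
#' @export
format_reaction_equation <- function(stoichiometry, reversible = FALSE) {
  side <- function(rows) {
    if (nrow(rows) == 0L) return("")
    paste(ifelse(abs(rows$coefficient) == 1, rows$metabolite,
                 paste(fmt_num(abs(rows$coefficient)), rows$metabolite)),
          collapse = " + ")
  }
  lhs <- side(stoichiometry[stoichiometry$coefficient < 0, , drop = FALSE])
  rhs <- side(stoichiometry[stoichiometry$coefficient > 0, , drop = FALSE])
  arrow <- if (reversible) "<=>" else "->"
  trimws(paste(lhs, arrow, rhs))
}

# shortest fixed-notation decimal that reparses to the identical double
# (never scientific: "+"/"-" inside numbers would collide with the equation
# grammar)
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    for (d in 1:17) {
      s <- trimws(formatC(v, digits = d, format = "fg", flag = "#"))
      s <- sub("\\.?0*$", "", s)
      if (nzchar(s) && as.numeric(s) == v) return(s)
    }
    sprintf("%.17f", v)
  }, character(1))
}

read_table_auto <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Read a model from tabular files
#'
#' @param reactions_path,metabolites_path TSV/CSV files in the tabular
#'   dialect (see the README for column names).
#' @param genes_path Optional genes file (column `gene` or `id`); when
#'   omitted, the gene set is derived from the GPR rules.
#' @param biomass_id,objective Passed to [metabolic_model()].
#' @return A validated `metabolic_model`. Duplicate ids, dangling metabolite
#'   references, and `lower_bound > upper_bound` all abort with a message
#'   listing the offenders.
#' @export
read_model_tables <- function(reactions_path, metabolites_path,
                              genes_path = NULL, biomass_id = NULL,
                              objective = NULL) {
  rxn_raw <- read_table_auto(reactions_path)
  met_raw <- read_table_auto(metabolites_path)
  if (!"equation" %in% names(rxn_raw)) {
    stop("reactions file lacks an `equation` column: ", reactions_path,
         call. = FALSE)
  }
  parsed <- lapply(rxn_raw$equation, parse_reaction_equation)
  rev <- vapply(parsed, `[[`, logical(1), "reversible")
  if (!"lower_bound" %in% names(rxn_raw)) {
    rxn_raw$lower_bound <- ifelse(rev, -1000, 0)
  }
  if (!"upper_bound" %in% names(rxn_raw)) rxn_raw$upper_bound <- 1000
  rxn_raw$lower_bound[is.na(rxn_raw$lower_bound)] <- ifelse(
    rev[is.na(rxn_raw$lower_bound)], -1000, 0)
  rxn_raw$upper_bound[is.na(rxn_raw$upper_bound)] <- 1000
  st <- dplyr::bind_rows(stats::setNames(
    lapply(parsed, `[[`, "stoichiometry"), rxn_raw$id), .id = "reaction")
  genes <- NULL
  if (!is.null(genes_path)) {
    g <- read_table_auto(genes_path)
    col <- intersect(c("gene", "id"), names(g))[1]
    if (is.na(col)) stop("genes file needs a `gene` or `id` column", call. = FALSE)
    genes <- as.character(g[[col]])
  }
  metabolic_model(
    reactions = dplyr::select(rxn_raw, -"equation"),
    metabolites = met_raw,
    stoichiometry = st,
    genes = genes, biomass_id = biomass_id, objective = objective
  )
}

#' Write a model to tabular files
#'
#' Numeric bounds and coefficients are serialised with the shortest decimal
#' representation that reparses to the identical double, so a write/read
#' round-trip preserves every number bit-for-bit.
#'
#' @param model A `metabolic_model`.
#' @param dir Output directory (created if needed).
#' @param basename Stem for `<stem>_reactions.tsv`, `<stem>_metabolites.tsv`,
#'   `<stem>_genes.tsv`.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_model_tables <- function(model, dir, basename = "model") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rxn <- model$reactions
  eqs <- vapply(rxn$id, function(rid) {
    st <- model$stoichiometry[model$stoichiometry$reaction == rid, , drop = FALSE]
    format_reaction_equation(st, reversible = rxn$lower_bound[rxn$id == rid] < 0)
  }, character(1))
  rxn_out <- tibble::tibble(
    id = rxn$id, name = rxn$name, equation = eqs,
    lower_bound = fmt_num(rxn$lower_bound),
    upper_bound = fmt_num(rxn$upper_bound),
    gpr = rxn$gpr, subsystem = rxn$subsystem)
  met_out <- dplyr::select(model$metabolites,
                           "id", "name", "compartment", "formula", "charge")
  paths <- c(
    reactions = file.path(dir, paste0(basename, "_reactions.tsv")),
    metabolites = file.path(dir, paste0(basename, "_metabolites.tsv")),
    genes = file.path(dir, paste0(basename, "_genes.tsv")))
  readr::write_tsv(rxn_out, paths[["reactions"]], progress = FALSE)
  readr::write_tsv(met_out, paths[["metabolites"]], progress = FALSE)
  readr::write_tsv(tibble::tibble(gene = model$genes), paths[["genes"]],
                   progress = FALSE)
  invisible(paths)
}
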