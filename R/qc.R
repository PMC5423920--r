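#' Parse a Hill-style elemental formula
#'
#' Accepts sequences of element symbols (uppercase letter, optional lowercase
#' letter) each followed by an optional nonnegative integer count, e.g.
#' `"C6H12O6"`. The pseudo-elements `R` and `X` (generic side groups) are
#' accepted but flag the formula as generic, which makes any balance check
#' involving it undeterminable.
#'
#' @param formula Formula string; `""` is allowed and yields an empty map.
#' @return Named integer vector of element counts with attribute `generic`
#'   (logical). Illegal characters abort.
#' @examples
#' parse_formula("H2O")
#' parse_formula("C10H12N5O13P3")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula)) {
    stop("`formula` must be a single string", call. = FALSE)
  }
  if (!nzchar(formula)) {
    out <- stats::setNames(integer(), character())
    attr(out, "generic") <- FALSE
    return(out)
  }
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula)) {
    stop("cannot parse formula: '", formula, "'", call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  elem <- sub("[0-9]*$", "", parts)
  count <- as.integer(ifelse(grepl("[0-9]+$", parts),
                             sub("^[A-Za-z]+", "", parts), "1"))
  counts <- tapply(count, elem, sum)
  out <- stats::setNames(as.integer(counts), names(counts))
  out <- out[out != 0L]
  attr(out, "generic") <- any(names(out) %in% c("R", "X"))
  out
}

#' Check mass and charge balance of reactions
#'
#' For each reaction, sums coefficient-weighted element counts (products
#' minus substrates) and the charge residual, treating charge as one more
#' conserved quantity. A reaction is `balanced` iff every residual is exactly
#' zero, `imbalanced` if some residual is nonzero, and `undeterminable` when
#' it is an exchange reaction (boundary by construction) or any participating
#' metabolite has an empty, unparseable or generic (`R`/`X`) formula —
#' biomass-style lumped reactions fall in this class rather than being
#' force-fitted.
#'
#' @param model A `metabolic_model`.
#' @param reaction_ids Reactions to check; default all.
#' @return Tibble with columns `reaction`, `status`, `charge_residual`, and
#'   `residuals` (list-column of named numeric element residuals).
#' @export
check_reaction_balance <- function(model, reaction_ids = NULL) {
  if (is.null(reaction_ids)) reaction_ids <- model$reactions$id
  missing <- setdiff(reaction_ids, model$reactions$id)
  if (length(missing)) {
    stop("unknown reactions: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  met <- model$metabolites
  parsed <- lapply(stats::setNames(met$formula, met$id), function(f) {
    tryCatch(parse_formula(f), error = function(e) NULL)
  })
  usable <- vapply(met$id, function(mid) {
    p <- parsed[[mid]]
    !is.null(p) && length(p) > 0L && !attr(p, "generic")
  }, logical(1))
  names(usable) <- met$id
  charge <- stats::setNames(as.numeric(met$charge), met$id)

  rows <- lapply(reaction_ids, function(rid) {
    st <- model$stoichiometry[model$stoichiometry$reaction == rid, , drop = FALSE]
    is_ex <- isTRUE(model$reactions$is_exchange[model$reactions$id == rid])
    if (is_ex || nrow(st) == 0L || !all(usable[st$metabolite])) {
      return(tibble::tibble(reaction = rid, status = "undeterminable",
                            charge_residual = NA_real_, residuals = list(NULL)))
    }
    res <- numeric()
    for (i in seq_len(nrow(st))) {
      p <- parsed[[st$metabolite[i]]]
      for (el in names(p)) {
        res[el] <- (if (el %in% names(res)) res[[el]] else 0) +
          st$coefficient[i] * p[[el]]
      }
    }
    cres <- sum(st$coefficient * charge[st$metabolite])
    status <- if (all(res == 0) && cres == 0) "balanced" else "imbalanced"
    tibble::tibble(reaction = rid, status = status, charge_residual = cres,
                   residuals = list(res[res != 0]))
  })
  dplyr::bind_rows(rows)
}

#' Find dead-end metabolites
#'
#' A metabolite is in `no_production` when no reaction can produce it under
#' any admissible flux direction — i.e. no reaction carries it with a
#' positive coefficient and `upper_bound > 0`, nor with a negative
#' coefficient and `lower_bound < 0` — and symmetrically for
#' `no_consumption`. `dead_end` is the union. Metabolites that participate in
#' an exchange reaction sit on the system boundary and are excluded.
#'
#' With `transitive = TRUE` the scan is iterated: reactions that must carry
#' zero flux because they consume an unproducible (or produce an
#' unconsumable) metabolite are removed and the scan repeated to a fixed
#' point, exposing metabolites blocked only through the network.
#'
#' @param model A `metabolic_model`.
#' @param transitive Propagate blockage through the network (default FALSE:
#'   root dead-ends only).
#' @return Object of class `gap_report`: list with character vectors
#'   `no_production`, `no_consumption`, `dead_end`.
#' @export
find_dead_end_metabolites <- function(model, transitive = FALSE) {
  st <- model$stoichiometry
  rxn <- model$reactions
  boundary <- unique(st$metabolite[st$reaction %in% rxn$id[rxn$is_exchange]])
  active <- stats::setNames(rep(TRUE, nrow(rxn)), rxn$id)
  scan <- function() {
    lb <- stats::setNames(rxn$lower_bound, rxn$id)
    ub <- stats::setNames(rxn$upper_bound, rxn$id)
    keep <- active[st$reaction]
    s <- st[keep, , drop = FALSE]
    producible <- unique(s$metabolite[
      (s$coefficient > 0 & ub[s$reaction] > 0) |
      (s$coefficient < 0 & lb[s$reaction] < 0)])
    consumable <- unique(s$metabolite[
      (s$coefficient < 0 & ub[s$reaction] > 0) |
      (s$coefficient > 0 & lb[s$reaction] < 0)])
    list(no_prod = setdiff(model$metabolites$id, producible),
         no_cons = setdiff(model$metabolites$id, consumable))
  }
  res <- scan()
  if (transitive) {
    repeat {
      blocked_mets <- union(res$no_prod, res$no_cons)
      newly_blocked <- vapply(rxn$id, function(rid) {
        active[[rid]] && any(st$metabolite[st$reaction == rid] %in% blocked_mets)
      }, logical(1))
      # a reaction touching a dead metabolite cannot carry steady-state flux
      if (!any(newly_blocked & active[rxn$id])) break
      active[rxn$id[newly_blocked]] <- FALSE
      res2 <- scan()
      if (setequal(res2$no_prod, res$no_prod) &&
          setequal(res2$no_cons, res$no_cons)) break
      res <- res2
    }
  }
  structure(list(
    no_production = sort(setdiff(res$no_prod, boundary)),
    no_consumption = sort(setdiff(res$no_cons, boundary)),
    dead_end = sort(setdiff(union(res$no_prod, res$no_cons), boundary))
  ), class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("<gap_report> %d dead-end metabolites (%d never produced, %d never consumed)\n",
              length(x$dead_end), length(x$no_production), length(x$no_consumption)))
  if (length(x$dead_end)) cat("  ", paste(x$dead_end, collapse = ", "), "\n")
  invisible(x)
}

#' Summarise model content
#'
#' Counts genes, reactions, metabolites (both total compartmented entries and
#' unique species after stripping a trailing `_<compartment>` suffix), and
#' reactions per compartment class. A reaction whose metabolites span more
#' than one compartment is classed `intercompartmental/transport`; exchange
#' reactions are classed by their single metabolite's compartment. The
#' compartment classes partition the reaction set, so their counts sum to the
#' reaction total.
#'
#' @param model A `metabolic_model`.
#' @return A list with `counts` (tibble quantity/value) and
#'   `reactions_by_compartment` (tibble compartment/n).
#' @export
summarize_model <- function(model) {
  met <- model$metabolites
  suffix_re <- paste0("_(", paste(model$compartments, collapse = "|"), ")$")
  base_ids <- if (nrow(met)) sub(suffix_re, "", met$id) else character()
  rxn_comp <- vapply(model$reactions$id, function(rid) {
    mets <- model$stoichiometry$metabolite[model$stoichiometry$reaction == rid]
    comps <- unique(met$compartment[met$id %in% mets])
    if (length(comps) == 0L) "(empty)"
    else if (length(comps) > 1L) "intercompartmental/transport"
    else comps
  }, character(1))
  by_comp <- if (nrow(model$reactions)) {
    tibble::tibble(compartment = rxn_comp) |>
      dplyr::count(.data$compartment, name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n))
  } else {
    tibble::tibble(compartment = character(), n = integer())
  }
  counts <- tibble::tibble(
    quantity = c("genes", "reactions", "metabolites_total",
                 "metabolites_unique", "compartments"),
    value = c(length(model$genes), nrow(model$reactions), nrow(met),
              length(unique(base_ids)), length(model$compartments)))
  list(counts = counts, reactions_by_compartment = by_comp)
}
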