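#' Classify single-gene essentiality
#'
#' Deletes each gene in turn ([apply_gene_deletion()]), re-solves the growth
#' FBA, and classifies by the knockout/wild-type growth ratio:
#' `essential` when the knockout growth rate falls below `eps_zero`
#' (numerically "zero" growth), `non_essential` when it is at least
#' `(1 - delta)` of the wild-type rate, and `partially_essential` in
#' between — growth strictly between zero and wild type. Infeasible
#' knockouts count as zero growth.
#'
#' @param model A `metabolic_model`.
#' @param medium Optional medium tibble applied first ([apply_medium()]).
#' @param genes Subset of genes to test; default all model genes.
#' @param eps_zero Growth threshold treated as zero (1/h).
#' @param delta Relative tolerance for "same as wild type".
#' @return Tibble with `gene`, `mu_ko`, `mu_wt`, `ratio`, `class`. Errors
#'   when the wild type itself does not grow on the medium.
#' @export
classify_essentiality <- function(model, medium = NULL, genes = NULL,
                                  eps_zero = 1e-6, delta = 1e-3) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  if (is.null(genes)) genes <- model$genes
  bad <- setdiff(genes, model$genes)
  if (length(bad)) {
    stop("unknown genes: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  wt <- fba(model)
  mu_wt <- if (wt$status == "optimal") wt$objective_value else 0
  if (mu_wt < eps_zero) {
    stop("wild type does not grow on this medium (mu = ",
         signif(mu_wt, 4), " 1/h)", call. = FALSE)
  }
  rows <- lapply(genes, function(g) {
    ko <- apply_gene_deletion(model, g)
    sol <- fba(ko)
    mu_ko <- if (sol$status == "optimal") max(0, sol$objective_value) else 0
    cls <- if (mu_ko < eps_zero) {
      "essential"
    } else if (mu_ko >= (1 - delta) * mu_wt) {
      "non_essential"
    } else {
      "partially_essential"
    }
    tibble::tibble(gene = g, mu_ko = mu_ko, mu_wt = mu_wt,
                   ratio = mu_ko / mu_wt, class = cls)
  })
  dplyr::bind_rows(rows)
}

#' Screen carbon and nitrogen sources for growth support
#'
#' For each candidate exchange reaction, builds a medium in which the
#' candidate is the sole source of its element class and asks whether FBA
#' predicts growth. For a carbon screen every carbon-containing exchange
#' except the candidate is closed (ammonium remains the nitrogen source);
#' for a nitrogen screen every nitrogen-containing exchange except the
#' candidate is closed (glucose, or whatever carbon source the base medium
#' opens, remains). Element content is read from the parsed metabolite
#' formulas; a candidate whose metabolite formula cannot be parsed is
#' flagged `unscreenable` rather than guessed.
#'
#' Carbon-source uptake is normalised per carbon mole by default: the
#' candidate bound supplies the same carbon flux as `uptake_rate` mmol/h of
#' glucose (6 C), so sources are compared on equal carbon supply. Nitrogen
#' candidates use the molar `uptake_rate` directly.
#'
#' @param model A `metabolic_model`.
#' @param base_medium Medium tibble defining the reference condition
#'   (glucose + ammonium + minerals).
#' @param candidates Tibble with columns `reaction` (exchange id) and `role`
#'   (`"carbon"` or `"nitrogen"`).
#' @param uptake_rate Reference uptake magnitude (mmol/gDCW/h).
#' @param normalize `"per_cmol"` (default) or `"molar"` for carbon sources.
#' @param growth_threshold Growth rate above which a source is called
#'   growth-supporting (1/h).
#' @return Tibble with `source`, `role`, `mu`, `growth_supporting`, `note`.
#' @export
screen_growth_sources <- function(model, base_medium, candidates,
                                  uptake_rate = 10,
                                  normalize = c("per_cmol", "molar"),
                                  growth_threshold = 1e-6) {
  normalize <- match.arg(normalize)
  candidates <- tibble::as_tibble(candidates)
  stopifnot(all(c("reaction", "role") %in% names(candidates)))
  if (!all(candidates$role %in% c("carbon", "nitrogen"))) {
    stop("candidate roles must be 'carbon' or 'nitrogen'", call. = FALSE)
  }
  ex <- exchange_reactions(model)
  bad <- setdiff(candidates$reaction, ex$id)
  if (length(bad)) {
    stop("candidates are not exchange reactions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  met <- model$metabolites
  elem_count <- function(mid, element) {
    f <- met$formula[met$id == mid]
    p <- tryCatch(parse_formula(f), error = function(e) NULL)
    if (is.null(p) || length(p) == 0L || attr(p, "generic")) return(NA_integer_)
    if (element %in% names(p)) p[[element]] else 0L
  }
  ex_carbon <- vapply(ex$metabolite, elem_count, integer(1), element = "C")
  ex_nitrogen <- vapply(ex$metabolite, elem_count, integer(1), element = "N")
  names(ex_carbon) <- names(ex_nitrogen) <- ex$id

  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates$reaction[i]
    role <- candidates$role[i]
    count <- if (role == "carbon") ex_carbon[[cand]] else ex_nitrogen[[cand]]
    if (is.na(count) || count == 0L) {
      return(tibble::tibble(source = cand, role = role, mu = NA_real_,
                            growth_supporting = NA,
                            note = if (is.na(count)) "unscreenable" else
                              paste0("metabolite contains no ", role)))
    }
    class_counts <- if (role == "carbon") ex_carbon else ex_nitrogen
    closed <- names(class_counts)[!is.na(class_counts) & class_counts > 0 &
                                  names(class_counts) != cand]
    uptake <- if (role == "carbon" && normalize == "per_cmol") {
      uptake_rate * 6 / count
    } else {
      uptake_rate
    }
    medium <- base_medium[!base_medium$reaction %in% c(closed, cand), ,
                          drop = FALSE]
    medium <- dplyr::bind_rows(medium, tibble::tibble(
      reaction = cand, lower_bound = -uptake, upper_bound = 1000))
    sol <- fba(apply_medium(model, medium))
    mu <- if (sol$status == "optimal") sol$objective_value else 0
    tibble::tibble(source = cand, role = role, mu = mu,
                   growth_supporting = mu > growth_threshold,
                   note = NA_character_)
  })
  dplyr::bind_rows(rows)
}
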