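#' Fit maintenance-energy parameters from chemostat observations
#'
#' For each observation the measured exchange rates and the growth rate are
#' pinned and the flux through the ATP maintenance reaction is maximised
#' ([maximize_atp_turnover()]), giving the condition's total
#' maintenance-available ATP `r_ATP`. Ordinary least squares of `r_ATP` on
#' the growth rate then yields the maintenance line
#' `r_ATP = Y_xATP * mu + m_ATP`: the slope is the growth-associated
#' maintenance (GAM, mmol ATP/gDCW) and the intercept the
#' non-growth-associated maintenance (NGAM, mmol ATP/gDCW/h).
#'
#' @param observations Tibble with a `mu` column (dilution rate, 1/h) and
#'   one column per pinned exchange reaction (id as column name, measured
#'   rate in mmol/gDCW/h, uptake negative). Extra columns starting with
#'   `r_atp` are ignored.
#' @param model A `metabolic_model` with a maintenance reaction.
#' @param maintenance_id Maintenance reaction id.
#' @param rate_tolerance Relative band around pinned rates (0 = exact).
#' @return A `maintenance_fit` object; see [tidy.maintenance_fit()].
#'   A negative fitted NGAM triggers a warning but is returned as-is.
#' @examples
#' obs <- simulate_chemostat(seq(0.05, 0.2, by = 0.05))
#' fit_maintenance(obs, make_energy_model())
#' @export
fit_maintenance <- function(observations, model, maintenance_id = "ATPM",
                            rate_tolerance = 0) {
  observations <- tibble::as_tibble(observations)
  if (!"mu" %in% names(observations)) {
    stop("observations need a `mu` column", call. = FALSE)
  }
  if (nrow(observations) < 2) {
    stop("need at least 2 observations", call. = FALSE)
  }
  if (length(unique(observations$mu)) < 2) {
    stop("all dilution rates are equal: the design is singular", call. = FALSE)
  }
  rate_cols <- setdiff(names(observations),
                       c("mu", grep("^r_atp", names(observations), value = TRUE)))
  if (!length(rate_cols)) {
    stop("observations carry no exchange-rate columns", call. = FALSE)
  }
  r_atp <- vapply(seq_len(nrow(observations)), function(i) {
    fixed <- stats::setNames(as.numeric(observations[i, rate_cols]), rate_cols)
    fixed[model$biomass_id] <- observations$mu[i]
    maximize_atp_turnover(model, fixed, maintenance_id = maintenance_id,
                          rate_tolerance = rate_tolerance)
  }, numeric(1))
  data <- tibble::tibble(mu = observations$mu, r_atp = r_atp)
  ols <- stats::lm(r_atp ~ mu, data = data)
  gam <- unname(stats::coef(ols)[["mu"]])
  ngam <- unname(stats::coef(ols)[["(Intercept)"]])
  if (ngam < 0) {
    warning("fitted NGAM is negative (", signif(ngam, 4),
            " mmol ATP/gDCW/h)", call. = FALSE)
  }
  structure(list(gam = gam, ngam = ngam, model = ols, data = data,
                 n_points = nrow(data)), class = "maintenance_fit")
}

#' @export
print.maintenance_fit <- function(x, ...) {
  cat(sprintf(
    "<maintenance_fit> r_ATP = %.6g * mu + %.6g  (GAM mmol ATP/gDCW, NGAM mmol ATP/gDCW/h; n = %d)\n",
    x$gam, x$ngam, x$n_points))
  invisible(x)
}

#' Tidy a maintenance fit
#'
#' @param x A `maintenance_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (GAM, NGAM) with estimate and
#'   standard error. `glance()`: one-row model summary.
#' @export
tidy.maintenance_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("NGAM", "GAM"),
    estimate = c(x$ngam, x$gam),
    std_error = unname(s[, "Std. Error"]),
    unit = c("mmol ATP/gDCW/h", "mmol ATP/gDCW"))
}

#' @rdname tidy.maintenance_fit
#' @export
glance.maintenance_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(gam = x$gam, ngam = x$ngam, r_squared = s$r.squared,
                 sigma = s$sigma, n_points = x$n_points)
}

#' Predict chemostat phenotypes across glucose uptake rates
#'
#' For each glucose uptake rate, fixes the glucose exchange, maximises
#' growth, and reads the oxygen and carbon-dioxide exchange rates from the
#' parsimonious (pFBA) solution, since FBA flux vectors are non-unique.
#' Infeasible points (e.g. maintenance cannot be paid at very low uptake)
#' are reported per-row, not as an error.
#'
#' @param model A `metabolic_model` (e.g. [make_physiology_model()]).
#' @param q_glc Vector of glucose uptake magnitudes (mmol/gDCW/h, positive).
#' @param glc_id,o2_id,co2_id Exchange reaction ids.
#' @return Tibble with `q_glc`, `status`, `mu` (1/h), `q_o2`, `q_co2`
#'   (positive consumption/production rates) and `rq` (`q_co2 / q_o2`,
#'   `NA` when `q_o2` is 0).
#' @export
predict_chemostat <- function(model, q_glc, glc_id = "EX_glc",
                              o2_id = "EX_o2", co2_id = "EX_co2") {
  rows <- lapply(q_glc, function(q) {
    m <- set_bounds(model, glc_id, lower = -abs(q), upper = 0)
    sol <- fba(m)
    if (sol$status != "optimal") {
      return(tibble::tibble(q_glc = q, status = sol$status, mu = NA_real_,
                            q_o2 = NA_real_, q_co2 = NA_real_, rq = NA_real_))
    }
    psol <- pfba(m)
    v <- psol$fluxes
    q_o2 <- -unname(v[o2_id])
    q_co2 <- unname(v[co2_id])
    tibble::tibble(q_glc = q, status = "optimal",
                   mu = unname(v[model$biomass_id]),
                   q_o2 = q_o2, q_co2 = q_co2,
                   rq = ifelse(q_o2 > 0, q_co2 / q_o2, NA_real_))
  })
  dplyr::bind_rows(rows)
}

#' Sensitivity of predicted growth to biomass composition and NGAM
#'
#' Varies one parameter at a time — a macromolecule mass fraction or the
#' NGAM — over a grid, rebuilds the biomass reaction for each value, and
#' records the FBA-predicted growth and oxygen uptake across a glucose
#' uptake grid. When one fraction is varied the remaining fractions are
#' rescaled proportionally so the composition still sums to 1 g/gDCW.
#' Infeasible points are reported with `status = "infeasible"` and `mu = 0`
#' (washout: the maintenance demand cannot be met).
#'
#' @param model A model with biomass metadata ([make_physiology_model()]).
#' @param parameter One of `"protein"`, `"lipid"`, `"rna"`, `"dna"`,
#'   `"carbohydrate"`, `"pool"`, `"ngam"`.
#' @param values Grid of parameter values (fractions in \[0, 1) for
#'   composition parameters; mmol ATP/gDCW/h for NGAM).
#' @param q_glc Glucose uptake grid (positive magnitudes).
#' @return Tidy tibble: `parameter`, `value`, `q_glc`, `status`, `mu`,
#'   `q_o2`.
#' @export
sensitivity_scan <- function(model, parameter, values,
                             q_glc = seq(0.2, 2, by = 0.2)) {
  meta <- model$biomass_meta
  if (is.null(meta)) {
    stop("model carries no biomass metadata; build it with make_physiology_model()",
         call. = FALSE)
  }
  parameter <- match.arg(parameter,
                         c(names(meta$composition$fractions), "ngam"))
  base <- meta$composition
  rows <- lapply(values, function(val) {
    comp <- if (parameter == "ngam") {
      if (val < 0) stop("NGAM must be >= 0", call. = FALSE)
      biomass_composition(
        protein = base$fractions[["protein"]], lipid = base$fractions[["lipid"]],
        rna = base$fractions[["rna"]], dna = base$fractions[["dna"]],
        carbohydrate = base$fractions[["carbohydrate"]],
        pool = base$fractions[["pool"]], gam = base$gam, ngam = val)
    } else {
      reallocate_fraction(base, parameter, val)
    }
    m <- set_biomass_composition(model, comp)
    res <- predict_chemostat(m, q_glc)
    tibble::tibble(parameter = parameter, value = val, q_glc = res$q_glc,
                   status = res$status,
                   mu = ifelse(res$status == "optimal", res$mu, 0),
                   q_o2 = ifelse(res$status == "optimal", res$q_o2, NA_real_))
  })
  dplyr::bind_rows(rows)
}

reallocate_fraction <- function(base, parameter, val) {
  f <- base$fractions
  if (val < 0 || val >= 1) {
    stop("fraction for ", parameter,
         " must lie in [0, 1): cannot renormalise the rest", call. = FALSE)
  }
  rest <- f[setdiff(names(f), parameter)]
  if (sum(rest) <= 0) {
    stop("no other fraction to renormalise against", call. = FALSE)
  }
  rest <- rest * (1 - val) / sum(rest)
  f[parameter] <- val
  f[names(rest)] <- rest
  biomass_composition(protein = f[["protein"]], lipid = f[["lipid"]],
                      rna = f[["rna"]], dna = f[["dna"]],
                      carbohydrate = f[["carbohydrate"]], pool = f[["pool"]],
                      gam = base$gam, ngam = base$ngam)
}

#' Pearson correlation between two flux vectors
#'
#' Pairs fluxes by shared reaction id (or through an explicit id mapping)
#' and reports the Pearson correlation. Unmatched ids are returned, never
#' silently dropped.
#'
#' @param fluxes_a,fluxes_b Named numeric vectors (reaction id -> flux).
#' @param mapping Optional tibble with columns `a`, `b` mapping ids of
#'   `fluxes_a` to ids of `fluxes_b`.
#' @return List with `r`, `n`, `pairs` (tibble id_a, id_b, flux_a, flux_b),
#'   `unmatched_a`, `unmatched_b`. Fewer than 3 pairs or a zero-variance
#'   vector is an error.
#' @export
flux_correlation <- function(fluxes_a, fluxes_b, mapping = NULL) {
  if (is.null(mapping)) {
    shared <- intersect(names(fluxes_a), names(fluxes_b))
    mapping <- tibble::tibble(a = shared, b = shared)
  } else {
    mapping <- tibble::as_tibble(mapping)
    stopifnot(all(c("a", "b") %in% names(mapping)))
    mapping <- mapping[mapping$a %in% names(fluxes_a) &
                       mapping$b %in% names(fluxes_b), , drop = FALSE]
  }
  if (nrow(mapping) < 3) {
    stop("need at least 3 paired fluxes, got ", nrow(mapping), call. = FALSE)
  }
  xa <- unname(fluxes_a[mapping$a])
  xb <- unname(fluxes_b[mapping$b])
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
    stop("zero variance in a flux vector: correlation undefined", call. = FALSE)
  }
  list(r = stats::cor(xa, xb),
       n = nrow(mapping),
       pairs = tibble::tibble(id_a = mapping$a, id_b = mapping$b,
                              flux_a = xa, flux_b = xb),
       unmatched_a = setdiff(names(fluxes_a), mapping$a),
       unmatched_b = setdiff(names(fluxes_b), mapping$b))
}

#' Score model support by expression calls
#'
#' Reports (a) the fraction of model genes called expressed, and (b) after
#' removing exchange reactions, the fraction of single-gene and multi-gene
#' reactions whose presence is supported by the expression data. A reaction
#' is `verified` when its GPR evaluates TRUE with expressed genes present
#' and unexpressed genes absent (`criterion = "gpr"`, the default: an intact
#' isozyme or complete complex suffices), or when any of its genes is
#' expressed (`criterion = "any"`). Reactions without a GPR are counted
#' separately; verified / unverified / no-GPR partition the non-exchange
#' reactions exactly.
#'
#' @param model A `metabolic_model`.
#' @param expressed_genes Character vector of expressed gene ids (supersets
#'   of the model gene set are fine).
#' @param criterion `"gpr"` or `"any"`.
#' @return List with `gene_coverage`, `summary` (tibble per reaction class)
#'   and `reactions` (per-reaction tibble: reaction, n_genes, class).
#' @export
expression_coverage <- function(model, expressed_genes,
                                criterion = c("gpr", "any")) {
  criterion <- match.arg(criterion)
  gene_coverage <- if (length(model$genes)) {
    mean(model$genes %in% expressed_genes)
  } else NA_real_
  unexpressed <- setdiff(model$genes, expressed_genes)
  rxn <- model$reactions[!model$reactions$is_exchange, , drop = FALSE]
  rows <- lapply(rxn$id, function(rid) {
    g <- model$gpr_parsed[[rid]]
    if (is.null(g)) {
      return(tibble::tibble(reaction = rid, n_genes = 0L, class = "no_gpr"))
    }
    genes <- gpr_genes(g)
    ok <- if (criterion == "gpr") {
      evaluate_gpr(g, unexpressed)
    } else {
      any(genes %in% expressed_genes)
    }
    tibble::tibble(reaction = rid, n_genes = length(genes),
                   class = if (ok) "verified" else "unverified")
  })
  per_rxn <- dplyr::bind_rows(rows)
  summarise_group <- function(tbl, label) {
    tibble::tibble(group = label, n = nrow(tbl),
                   verified_fraction = if (nrow(tbl)) {
                     mean(tbl$class == "verified")
                   } else NA_real_)
  }
  with_gpr <- per_rxn[per_rxn$class != "no_gpr", , drop = FALSE]
  summary <- dplyr::bind_rows(
    summarise_group(with_gpr[with_gpr$n_genes == 1L, , drop = FALSE],
                    "single_gene"),
    summarise_group(with_gpr[with_gpr$n_genes > 1L, , drop = FALSE],
                    "multi_gene"),
    tibble::tibble(group = "no_gpr",
                   n = sum(per_rxn$class == "no_gpr"),
                   verified_fraction = NA_real_))
  list(gene_coverage = gene_coverage, summary = summary,
       reactions = per_rxn)
}
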