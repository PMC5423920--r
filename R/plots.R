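#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a maintenance fit
#'
#' ATP turnover against growth rate with the fitted maintenance line; the
#' intercept is the NGAM, the slope the GAM.
#'
#' @param object A `maintenance_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.maintenance_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mu, y = .data$r_atp)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$ngam, slope = object$gam,
                         colour = "steelblue") +
    ggplot2::labs(
      x = expression(mu ~ "(1/h)"),
      y = expression(r[ATP] ~ "(mmol ATP/gDCW/h)"),
      title = sprintf("GAM = %.3g mmol ATP/gDCW, NGAM = %.3g mmol ATP/gDCW/h",
                      object$gam, object$ngam))
}

#' Plot a sensitivity scan
#'
#' Predicted growth rate against glucose uptake, one curve per parameter
#' value.
#'
#' @param scan Output of [sensitivity_scan()].
#' @param y Column to plot (`"mu"` or `"q_o2"`).
#' @return A ggplot.
#' @export
plot_sensitivity <- function(scan, y = "mu") {
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$q_glc, y = .data[[y]],
                                     colour = factor(.data$value),
                                     group = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "glucose uptake (mmol/gDCW/h)", y = y,
                  colour = unique(scan$parameter))
}

#' Plot chemostat phenotype predictions
#'
#' @param predictions Output of [predict_chemostat()].
#' @return A ggplot of mu, q_O2, q_CO2 and RQ against glucose uptake.
#' @export
plot_chemostat <- function(predictions) {
  long <- tidyr::pivot_longer(
    dplyr::filter(predictions, .data$status == "optimal"),
    cols = c("mu", "q_o2", "q_co2", "rq"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$q_glc, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "glucose uptake (mmol/gDCW/h)", y = NULL)
}

#' Plot essentiality classes
#'
#' Bar chart of gene counts per essentiality class; with a model supplied,
#' essential genes are broken down by the subsystems of the reactions they
#' participate in.
#'
#' @param results Output of [classify_essentiality()].
#' @param model Optional `metabolic_model` for the subsystem breakdown.
#' @return A ggplot.
#' @export
plot_essentiality <- function(results, model = NULL) {
  if (is.null(model)) {
    return(ggplot2::ggplot(results, ggplot2::aes(x = .data$class)) +
             ggplot2::geom_bar() +
             ggplot2::labs(x = NULL, y = "genes"))
  }
  gene_subsystem <- purrr::map_dfr(model$reactions$id, function(rid) {
    g <- model$gpr_parsed[[rid]]
    if (is.null(g)) return(NULL)
    tibble::tibble(gene = gpr_genes(g),
                   subsystem = model$reactions$subsystem[
                     model$reactions$id == rid])
  })
  ess <- dplyr::inner_join(
    dplyr::filter(results, .data$class == "essential"),
    dplyr::distinct(gene_subsystem), by = "gene")
  ess$subsystem[is.na(ess$subsystem)] <- "(none)"
  ggplot2::ggplot(ess, ggplot2::aes(x = .data$subsystem)) +
    ggplot2::geom_bar() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "essential genes")
}
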