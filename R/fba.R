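#' Flux balance analysis
#'
#' Solves the FBA linear program: optimise the objective `Z = c' v` subject
#' to the steady-state constraint `S v = 0` and the box bounds
#' `lb <= v <= ub`. The returned solution carries a feasibility certificate:
#' for an optimal status, `max |S v|` and the worst bound violation are both
#' checked against `tolerance` and stored.
#'
#' @param model A validated `metabolic_model` with at least one nonzero
#'   objective coefficient.
#' @param sense `"max"` (default) or `"min"`.
#' @param tolerance Post-hoc feasibility tolerance for the certificate.
#' @return A `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"`, or a solver failure status), `objective_value`,
#'   `fluxes` (named vector, mmol/gDCW/h; the biomass flux is in 1/h),
#'   `max_sv_residual`, `tolerance_used`.
#' @examples
#' toy <- make_toy_model(toy_model_spec("chain", uptake = 10, yields = 0.5))
#' fba(toy$model)$objective_value  # 5
#' @export
fba <- function(model, sense = c("max", "min"), tolerance = 1e-7) {
  sense <- match.arg(sense)
  if (!length(model$objective) || all(model$objective == 0)) {
    stop("model has no nonzero objective coefficient", call. = FALSE)
  }
  S <- stoich_matrix(model)
  n <- ncol(S)
  obj <- numeric(n)
  obj[match(names(model$objective), colnames(S))] <- unname(model$objective)
  res <- solve_lp(obj, lb = model$reactions$lower_bound,
                  ub = model$reactions$upper_bound,
                  Aeq = S, beq = rep(0, nrow(S)),
                  maximize = sense == "max")
  if (res$status != "optimal") {
    if (res$status == "maxiter") {
      stop("LP solver failed to converge (status maxiter)", call. = FALSE)
    }
    return(new_flux_solution(res$status, NA_real_,
                             stats::setNames(rep(NA_real_, n), colnames(S)),
                             NA_real_, tolerance))
  }
  v <- stats::setNames(res$x, colnames(S))
  resid <- max(abs(S %*% v))
  bound_viol <- max(0, model$reactions$lower_bound - v,
                    v - model$reactions$upper_bound)
  if (resid > tolerance || bound_viol > tolerance) {
    stop(sprintf("solver returned an infeasible vertex (|Sv|=%.3g, bound violation %.3g)",
                 resid, bound_viol), call. = FALSE)
  }
  new_flux_solution("optimal", res$objective, v, resid, tolerance)
}

new_flux_solution <- function(status, objective_value, fluxes, resid, tol) {
  structure(list(status = status, objective_value = objective_value,
                 fluxes = fluxes, max_sv_residual = resid,
                 tolerance_used = tol), class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status: %s", x$status))
  if (x$status == "optimal") {
    cat(sprintf(", Z = %.6g, max|Sv| = %.2g", x$objective_value,
                x$max_sv_residual))
  }
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fba
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @export
tidy.flux_solution <- function(x, ...) {
  tibble::tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' @rdname fba
#' @export
glance.flux_solution <- function(x, ...) {
  tibble::tibble(status = x$status, objective_value = x$objective_value,
                 n_reactions = length(x$fluxes),
                 sum_abs_flux = sum(abs(x$fluxes)),
                 max_sv_residual = x$max_sv_residual)
}

#' Parsimonious FBA
#'
#' Among flux vectors attaining the FBA optimum, returns one minimising the
#' total absolute flux `sum |v_j|`. The optimum is fixed by the one-sided
#' constraint `c' v >= Z* - |Z*| * rel_tol - rel_tol` (numerically more
#' robust than an equality), and each flux is split into non-negative
#' forward/reverse parts so the second stage is again a plain LP. Because any
#' flux around a closed internal cycle strictly increases `sum |v|`, pFBA
#' solutions carry zero cycle flux.
#'
#' @param model A `metabolic_model` (objective maximised).
#' @param rel_tol Relative slack used to fix the first-stage optimum.
#' @param tolerance Feasibility tolerance for the certificate.
#' @return A `flux_solution` whose `objective_value` is the recomputed
#'   `c' v` of the parsimonious vector; attribute `sum_abs_flux` holds
#'   `sum |v|`.
#' @export
pfba <- function(model, rel_tol = 1e-9, tolerance = 1e-7) {
  first <- fba(model, "max", tolerance = tolerance)
  if (first$status != "optimal") {
    stop("pFBA requires an optimal FBA solution; status was ", first$status,
         call. = FALSE)
  }
  zstar <- first$objective_value
  z_lb <- zstar - abs(zstar) * rel_tol - rel_tol
  S <- stoich_matrix(model)
  n <- ncol(S)
  obj_row <- numeric(n)
  obj_row[match(names(model$objective), colnames(S))] <- unname(model$objective)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  # variables: z = c(p, n) with v = p - n, p, n >= 0
  p_max <- pmax(0, ub)
  n_max <- pmax(0, -lb)
  Aeq <- cbind(S, -S)
  A_ge <- matrix(c(obj_row, -obj_row), nrow = 1)
  b_ge <- z_lb
  A_le <- NULL; b_le <- NULL
  strict <- which(lb > 0 | ub < 0)
  for (j in strict) {
    row <- numeric(2 * n); row[j] <- 1; row[n + j] <- -1
    A_ge <- rbind(A_ge, row); b_ge <- c(b_ge, lb[j])
    A_le <- rbind(A_le, row); b_le <- c(b_le, ub[j])
  }
  res <- solve_lp(rep(1, 2 * n), lb = rep(0, 2 * n), ub = c(p_max, n_max),
                  Aeq = Aeq, beq = rep(0, nrow(S)),
                  A_ge = A_ge, b_ge = b_ge, A_le = A_le, b_le = b_le,
                  maximize = FALSE)
  if (res$status != "optimal") {
    stop("pFBA second stage failed with status ", res$status, call. = FALSE)
  }
  v <- stats::setNames(res$x[1:n] - res$x[(n + 1):(2 * n)], colnames(S))
  resid <- max(abs(S %*% v))
  out <- new_flux_solution("optimal", sum(obj_row * v), v, resid, tolerance)
  attr(out, "sum_abs_flux") <- sum(abs(v))
  out
}

#' Maximise flux through the ATP maintenance reaction
#'
#' The non-growth-associated maintenance (NGAM) demand is represented by a
#' dedicated ATP hydrolysis reaction. Pinning the measured exchange rates and
#' the growth rate to their chemostat values and maximising the maintenance
#' flux yields `r_ATP`, the total ATP the network can still hydrolyse at that
#' condition — the quantity regressed on the growth rate by
#' [fit_maintenance()].
#'
#' @param model A `metabolic_model` containing the maintenance reaction.
#' @param fixed_rates Named numeric vector: reaction id -> measured flux
#'   (uptake negative; include the biomass reaction pinned to the dilution
#'   rate).
#' @param maintenance_id Id of the ATP maintenance reaction.
#' @param rate_tolerance Relative half-width of the band around each pinned
#'   rate (0 = exact equality).
#' @return `r_ATP`, the maximal maintenance flux (mmol ATP/gDCW/h).
#' @export
maximize_atp_turnover <- function(model, fixed_rates,
                                  maintenance_id = "ATPM",
                                  rate_tolerance = 0) {
  if (!maintenance_id %in% model$reactions$id) {
    stop("maintenance reaction not in model: ", maintenance_id, call. = FALSE)
  }
  bad <- setdiff(names(fixed_rates), model$reactions$id)
  if (length(bad)) {
    stop("fixed rates reference unknown reactions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  half <- abs(fixed_rates) * rate_tolerance
  model <- set_bounds(model, names(fixed_rates),
                      lower = fixed_rates - half, upper = fixed_rates + half)
  model <- set_bounds(model, maintenance_id, lower = 0, upper = 1000)
  model$objective <- stats::setNames(1, maintenance_id)
  sol <- fba(model, "max")
  if (sol$status != "optimal") {
    stop("ATP maximisation ", sol$status, " with pinned rates: ",
         paste(sprintf("%s=%g", names(fixed_rates), fixed_rates),
               collapse = ", "), call. = FALSE)
  }
  unname(sol$fluxes[maintenance_id])
}

#' Apply single- or multi-gene deletions to a model
#'
#' Every reaction whose GPR rule evaluates to `FALSE` under the deletion
#' (deleted genes absent, all others present) has its flux forced to zero
#' (`lb = ub = 0`); all other bounds are untouched. Reactions without a GPR
#' are spontaneous/orphan reactions and are never disabled.
#'
#' @param model A `metabolic_model`.
#' @param genes Character vector of gene ids to delete (must be model genes).
#' @return A modified copy of the model.
#' @export
apply_gene_deletion <- function(model, genes) {
  bad <- setdiff(genes, model$genes)
  if (length(bad)) {
    stop("unknown genes: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dead <- vapply(model$reactions$id, function(rid) {
    g <- model$gpr_parsed[[rid]]
    !is.null(g) && !evaluate_gpr(g, genes)
  }, logical(1))
  if (any(dead)) {
    model$reactions$lower_bound[dead] <- 0
    model$reactions$upper_bound[dead] <- 0
  }
  model
}
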