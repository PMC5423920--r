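#' Brute-force FBA by basic-solution enumeration
#'
#' Independent reference implementation of the FBA optimum used to check the
#' simplex path: enumerates every basic solution of
#' `{S v = 0, lb <= v <= ub}` (all choices of a basis among the reaction
#' columns, all nonbasic variables pinned to a bound), keeps the feasible
#' ones, and returns the best objective value. Exponential in the number of
#' reactions — intended for networks of at most ~10 reactions.
#'
#' @param model A `metabolic_model` with an objective.
#' @param sense `"max"` or `"min"`.
#' @param tol Feasibility tolerance for accepting an enumerated vertex.
#' @return List with `status` (`"optimal"`/`"infeasible"`), `objective`,
#'   and `v` (best vertex found).
#' @export
fba_brute_force <- function(model, sense = c("max", "min"), tol = 1e-9) {
  sense <- match.arg(sense)
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- ncol(S)
  obj <- numeric(n)
  obj[match(names(model$objective), colnames(S))] <- unname(model$objective)
  # reduce to an independent set of steady-state rows
  qr_rows <- qr(t(S))
  r <- qr_rows$rank
  Sr <- if (r == 0L) {
    matrix(0, 0, n)
  } else {
    S[qr_rows$pivot[seq_len(r)], , drop = FALSE]
  }
  best <- NULL
  best_z <- if (sense == "max") -Inf else Inf
  better <- function(z) if (sense == "max") z > best_z else z < best_z
  check_point <- function(v) {
    if (any(v < lb - tol) || any(v > ub + tol)) return()
    if (nrow(S) && max(abs(S %*% v)) > 1e-7) return()
    z <- sum(obj * v)
    if (better(z)) { best_z <<- z; best <<- v }
  }
  if (r == 0L) {
    # box-only LP: optimum at a bound per coordinate
    v <- ifelse((sense == "max") == (obj >= 0), ub, lb)
    check_point(v)
  } else {
    bases <- utils::combn(n, r)
    n_free <- n - r
    bound_grid <- if (n_free == 0L) {
      matrix(logical(), nrow = 1, ncol = 0)   # unique basic solution
    } else {
      as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n_free)))
    }
    for (k in seq_len(ncol(bases))) {
      basis <- bases[, k]
      B <- Sr[, basis, drop = FALSE]
      if (abs(det(B)) < 1e-12) next
      nonbasis <- setdiff(seq_len(n), basis)
      for (g in seq_len(nrow(bound_grid))) {
        v <- numeric(n)
        v[nonbasis] <- ifelse(bound_grid[g, ], ub[nonbasis], lb[nonbasis])
        rhs <- -Sr[, nonbasis, drop = FALSE] %*% v[nonbasis]
        v[basis] <- solve(B, rhs)
        check_point(v)
      }
    }
  }
  if (is.null(best)) {
    list(status = "infeasible", objective = NA_real_, v = NULL)
  } else {
    list(status = "optimal", objective = best_z,
         v = stats::setNames(best, colnames(S)))
  }
}
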