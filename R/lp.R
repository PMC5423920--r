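# solve_lp(): the package's LP front door. Inequalities are converted to
# equalities with non-negative slack columns and the whole system is handed
# to the bounded-variable simplex (simplex.R). With finite box bounds on
# every structural variable the FBA LPs can never be unbounded; the
# "unbounded" status is still propagated defensively.

#' Solve a bounded linear program
#'
#' Optimises `objective %*% x` subject to `Aeq x = beq`, `A_le x <= b_le`,
#' `A_ge x >= b_ge` and finite box bounds `lb <= x <= ub`.
#'
#' @param objective Numeric coefficient vector.
#' @param lb,ub Finite bound vectors (use the +/-1000 convention for
#'   "unlimited" fluxes).
#' @param Aeq,beq Equality constraints (may be `NULL`).
#' @param A_le,b_le,A_ge,b_ge Optional inequality constraints.
#' @param maximize Maximise instead of minimise.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"maxiter"`,
#'   `"unbounded"`, `"numeric"`), `objective` and the primal vector `x`
#'   (NA-filled unless optimal).
#' @keywords internal
solve_lp <- function(objective, lb, ub, Aeq = NULL, beq = NULL,
                     A_le = NULL, b_le = NULL, A_ge = NULL, b_ge = NULL,
                     maximize = TRUE) {
  n <- length(objective)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("solve_lp requires finite bounds (use +/-1000 sentinels)", call. = FALSE)
  }
  rows <- list(); rhs <- numeric(); slack_sign <- numeric()
  add_rows <- function(A, b, sign) {
    if (is.null(A)) return()
    A <- matrix(A, ncol = n)
    for (i in seq_len(nrow(A))) {
      rows[[length(rows) + 1L]] <<- A[i, ]
      rhs[length(rhs) + 1L] <<- b[i]
      slack_sign[length(slack_sign) + 1L] <<- sign
    }
  }
  add_rows(Aeq, beq, 0)
  add_rows(A_le, b_le, 1)
  add_rows(A_ge, b_ge, -1)
  m <- length(rows)
  n_slack <- sum(slack_sign != 0)
  A <- matrix(0, m, n + n_slack)
  if (m) A[, seq_len(n)] <- do.call(rbind, rows)
  k <- 0L
  for (i in seq_len(m)) {
    if (slack_sign[i] != 0) {
      k <- k + 1L
      A[i, n + k] <- slack_sign[i]
    }
  }
  res <- simplex_bounded(
    cc = c(objective, rep(0, n_slack)),
    A = A, b = rhs,
    l = c(lb, rep(0, n_slack)),
    u = c(ub, rep(Inf, n_slack)),
    maximize = maximize)
  list(status = res$status,
       objective = if (res$status == "optimal") {
         sum(objective * res$x[seq_len(n)])
       } else NA_real_,
       x = res$x[seq_len(n)])
}
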