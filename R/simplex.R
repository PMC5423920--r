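# Bounded-variable primal simplex, written for the degenerate, heavily
# bound-constrained LPs that flux balance analysis produces (knockouts fix
# lb = ub = 0 on many columns; steady-state rows are often linearly
# dependent). Two-phase with explicit artificial variables; Bland's rule
# throughout, which guarantees termination on degenerate problems at the
# price of speed — acceptable at the network sizes this package targets.
#
# Solves: optimise c'x  s.t.  A x = b,  l <= x <= u
# (l finite; u may be +Inf on slack columns added by solve_lp()).

simplex_bounded <- function(cc, A, b, l, u, maximize = FALSE,
                            tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cc) == n, length(b) == m, length(l) == n, length(u) == n)
  if (any(!is.finite(l))) stop("lower bounds must be finite", call. = FALSE)
  if (any(l > u + tol)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  obj <- if (maximize) -cc else cc
  fail <- function(status) list(status = status, objective = NA_real_,
                                x = rep(NA_real_, n))
  if (m == 0L) {
    x <- ifelse(obj <= 0, u, l)
    x[!is.finite(x)] <- l[!is.finite(x)]
    return(list(status = "optimal", objective = sum(cc * x), x = x))
  }

  # phase-1 basis: one artificial per row, signed so its value is >= 0 when
  # every original column sits at its lower bound
  N <- n + m
  resid <- as.numeric(b - A %*% l)
  sgn <- ifelse(resid >= 0, 1, -1)
  M <- cbind(A, diag(m)) * sgn            # row i scaled by sgn[i]
  M[, (n + 1):N] <- diag(m)               # artificial block back to identity
  rhs0 <- sgn * b
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, N)
  lo <- c(l, rep(0, m))
  hi <- c(u, rep(Inf, m))

  basic_values <- function() {
    nb <- setdiff(seq_len(N), basis)
    xn <- ifelse(at_upper[nb], hi[nb], lo[nb])
    as.numeric(rhs0 - M[, nb, drop = FALSE] %*% xn)
  }

  run_phase <- function(cost) {
    iter <- 0L
    in_basis <- logical(N); in_basis[basis] <- TRUE
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return("maxiter")
      xb <- basic_values()
      d <- cost - as.numeric(crossprod(cost[basis], M))
      enter <- 0L
      for (j in seq_len(N)) {             # Bland: lowest eligible index enters
        if (in_basis[j] || hi[j] - lo[j] < tol) next
        if ((!at_upper[j] && d[j] < -tol) || (at_upper[j] && d[j] > tol)) {
          enter <- j
          break
        }
      }
      if (enter == 0L) return("optimal")
      delta <- if (at_upper[enter]) -1 else 1
      w <- M[, enter]
      ratios <- rep(Inf, m)
      to_upper <- logical(m)
      for (i in seq_len(m)) {
        dw <- delta * w[i]
        if (dw > tol) {
          ratios[i] <- max(0, (xb[i] - lo[basis[i]]) / dw)
        } else if (dw < -tol && is.finite(hi[basis[i]])) {
          ratios[i] <- max(0, (hi[basis[i]] - xb[i]) / (-dw))
          to_upper[i] <- TRUE
        }
      }
      t_basic <- min(ratios)
      t_flip <- hi[enter] - lo[enter]
      if (!is.finite(t_basic) && !is.finite(t_flip)) return("unbounded")
      if (t_flip <= t_basic) {            # entering column flips bound
        at_upper[enter] <<- !at_upper[enter]
        next
      }
      tie <- which(ratios <= t_basic + tol)
      leave <- tie[which.min(basis[tie])] # Bland: lowest leaving index
      piv <- M[leave, enter]
      if (abs(piv) < 1e-11) return("numeric")
      out_col <- basis[leave]
      M[leave, ] <<- M[leave, ] / piv
      rhs0[leave] <<- rhs0[leave] / piv
      upd <- which(abs(M[, enter]) > 0)
      for (i in setdiff(upd, leave)) {
        f <- M[i, enter]
        M[i, ] <<- M[i, ] - f * M[leave, ]
        rhs0[i] <<- rhs0[i] - f * rhs0[leave]
      }
      basis[leave] <<- enter
      in_basis[enter] <- TRUE
      in_basis[out_col] <- FALSE
      at_upper[out_col] <<- to_upper[leave]
    }
  }

  st1 <- run_phase(c(rep(0, n), rep(1, m)))
  if (st1 != "optimal") return(fail(st1))
  xb <- basic_values()
  art_mass <- sum(pmax(0, xb[basis > n]))
  if (art_mass > 1e-7) return(fail("infeasible"))
  hi[(n + 1):N] <- 0                      # artificials frozen at zero

  st2 <- run_phase(c(obj, rep(0, m)))
  if (st2 != "optimal") return(fail(st2))
  x_full <- numeric(N)
  nb <- setdiff(seq_len(N), basis)
  x_full[nb] <- ifelse(at_upper[nb], hi[nb], lo[nb])
  x_full[basis] <- basic_values()
  x <- x_full[seq_len(n)]
  list(status = "optimal", objective = sum(cc * x), x = x)
}
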