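#' Bounded-variable linear programming by the primal simplex method
#'
#' Solves `max/min c'x` subject to `A x = b` and `lb <= x <= ub` using a
#' two-phase primal simplex with explicit variable bounds (nonbasic variables
#' rest at either bound, bound flips handled without a pivot).  This is the
#' numerical engine behind [solve_lp()] and [fva()]; metabolic steady-state
#' problems are exactly this shape, with `A` the stoichiometric matrix and
#' `b = 0`.
#'
#' Infeasibility is a status, not an error: the extraction loop and the
#' perturbation protocols routinely probe configurations with no feasible
#' flux.  Anti-cycling uses Bland's rule after a run of degenerate steps.
#'
#' @param A constraint matrix (m x n), dense numeric.
#' @param b right-hand side, length m.
#' @param obj objective coefficients, length n.
#' @param lb,ub finite variable bounds, length n.
#' @param sense `"max"` or `"min"`.
#' @param tol pivot/feasibility tolerance.
#' @param max_iter iteration cap; the default scales with problem size.
#'
#' @return A list with elements `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`, or `"iteration_limit"`), `x` (solution, `NA` unless
#'   optimal) and `objective`.
#' @keywords internal
lp_bounded <- function(A, b, obj, lb, ub, sense = "max",
                       tol = 1e-9, max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_bounded requires finite variable bounds")
  if (any(lb > ub + tol))
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  sgn_obj <- if (identical(sense, "min")) -1 else 1
  if (is.null(max_iter)) max_iter <- 100L * (n + m) + 500L

  # start nonbasic variables at the bound nearer zero
  x0 <- ifelse(abs(lb) <= abs(ub), lb, ub)
  at_ub0 <- abs(lb) > abs(ub)
  resid <- as.numeric(b - A %*% x0)
  art_sign <- ifelse(resid >= 0, 1, -1)

  # extended problem: n structural + m artificial columns
  Aext <- cbind(A, diag(art_sign, m, m))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))
  x <- c(x0, abs(resid))
  status <- integer(n + m)          # 0 at lb, 1 at ub, 2 basic
  status[seq_len(n)] <- ifelse(at_ub0, 1L, 0L)
  status[n + seq_len(m)] <- 2L
  basis <- n + seq_len(m)

  run_simplex <- function(cvec, x, status, basis, phase) {
    degen <- 0L
    for (it in seq_len(max_iter)) {
      AB <- Aext[, basis, drop = FALSE]
      qrB <- qr(AB)
      if (qrB$rank < m) return(list(status = "singular"))
      y <- qr.coef(qrB, diag(m))          # B^{-1}
      # recompute basic values for numerical hygiene
      nonb <- which(status != 2L)
      rhs <- b - Aext[, nonb, drop = FALSE] %*% x[nonb]
      x[basis] <- as.numeric(y %*% rhs)
      d <- cvec - as.numeric(crossprod(Aext, as.numeric(t(y) %*% cvec[basis])))
      free <- ube > lbe + tol
      cand <- which(status != 2L & free &
                      ((status == 0L & d > tol) | (status == 1L & d < -tol)))
      if (!length(cand))
        return(list(status = "optimal", x = x, status_vec = status, basis = basis))
      j <- if (degen > 2L * m) min(cand) else cand[which.max(abs(d[cand]))]
      s <- if (status[j] == 0L) 1 else -1
      w <- as.numeric(y %*% Aext[, j])
      step_basic <- -s * w
      ratios <- rep(Inf, m)
      up <- step_basic > tol
      dn <- step_basic < -tol
      ratios[up] <- (ube[basis[up]] - x[basis[up]]) / step_basic[up]
      ratios[dn] <- (lbe[basis[dn]] - x[basis[dn]]) / step_basic[dn]
      ratios <- pmax(ratios, 0)
      t_basic <- min(ratios)
      t_own <- ube[j] - lbe[j]
      tmax <- min(t_own, t_basic)
      if (!is.finite(tmax)) return(list(status = "unbounded"))
      leave <- 0L
      if (t_basic <= t_own) {
        ties <- which(ratios <= t_basic + tol * max(1, t_basic))
        leave <- ties[which.max(abs(step_basic[ties]))]
      }
      degen <- if (tmax < tol) degen + 1L else 0L
      x[j] <- x[j] + s * tmax
      x[basis] <- x[basis] + step_basic * tmax
      if (leave == 0L) {
        status[j] <- if (status[j] == 0L) 1L else 0L   # bound flip
      } else {
        bl <- basis[leave]
        status[bl] <- if (step_basic[leave] > 0) 1L else 0L
        x[bl] <- if (status[bl] == 1L) ube[bl] else lbe[bl]
        basis[leave] <- j
        status[j] <- 2L
      }
    }
    list(status = "iteration_limit")
  }

  # phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  r1 <- run_simplex(c1, x, status, basis, 1L)
  if (r1$status != "optimal") {
    st <- if (r1$status == "unbounded") "infeasible" else r1$status
    return(list(status = st, x = rep(NA_real_, n), objective = NA_real_))
  }
  art_val <- sum(r1$x[n + seq_len(m)])
  if (art_val > 1e-7)
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))

  # phase 2: real objective, artificials pinned at zero
  ube[n + seq_len(m)] <- 0
  x <- r1$x; x[n + seq_len(m)] <- pmin(x[n + seq_len(m)], 0 + 1e-12)
  c2 <- c(sgn_obj * obj, rep(0, m))
  r2 <- run_simplex(c2, x, r1$status_vec, r1$basis, 2L)
  if (r2$status != "optimal")
    return(list(status = r2$status, x = rep(NA_real_, n), objective = NA_real_))
  xr <- r2$x[seq_len(n)]
  # snap to bounds within tolerance
  xr <- pmin(pmax(xr, lb), ub)
  list(status = "optimal", x = xr, objective = sum(obj * xr))
}
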