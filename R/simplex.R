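# Dense bounded-variable primal simplex (two-phase, Bland's rule).
#
# Solves  min/max  obj' x   s.t.  A x = b,  lb <= x <= ub.
# Written for the small, highly degenerate LPs that arise from
# stoichiometric steady-state balances (tens of variables, many zero
# right-hand sides, many alternate optima). Bland's rule guarantees
# termination under degeneracy; basis systems are re-factorised every
# iteration, which is cheap at these sizes and avoids drift.

# Finite stand-in for infinite bounds. Solutions touching it are treated
# as unbounded in that direction by callers (see lp_solve()).
LP_BIG <- 1e6

#' @noRd
simplex_solve <- function(obj, A, b, lb, ub,
                          maximize = FALSE,
                          tol = 1e-9,
                          max_iter = 10000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective = NA_real_, duals = rep(NA_real_, m),
                reduced_costs = rep(NA_real_, n)))
  }
  lo <- pmax(lb, -LP_BIG)
  hi <- pmin(ub, LP_BIG)
  lo <- pmin(lo, hi)  # guard lb > LP_BIG edge cases
  cc <- if (maximize) -obj else obj

  # start every structural variable at its bound of smallest magnitude
  x0 <- ifelse(abs(lo) <= abs(hi), lo, hi)
  at_lower <- abs(lo) <= abs(hi)
  r <- b - as.vector(A %*% x0)

  # artificial variables, one per row, bounds [0, inf); basis = artificials
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, m))
  lo_f <- c(lo, rep(0, m))
  hi_f <- c(hi, rep(LP_BIG, m))
  x <- c(x0, abs(r))
  basis <- n + seq_len(m)
  at_lower <- c(at_lower, rep(TRUE, m))  # only meaningful for nonbasic

  nv <- ncol(Afull)
  run_phase <- function(cost, x, basis, at_lower, allowed) {
    it <- 0L
    stalled <- 0L
    bland <- FALSE  # Dantzig pricing until degeneracy stalls, then Bland
    last_obj <- Inf
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "maxit"))
      AB <- Afull[, basis, drop = FALSE]
      Binv <- tryCatch(solve(AB), error = function(e) NULL)
      if (is.null(Binv)) return(list(status = "singular"))
      in_basis <- logical(nv); in_basis[basis] <- TRUE
      nonbasic <- which(!in_basis)
      AN <- Afull[, nonbasic, drop = FALSE]
      x[basis] <- as.vector(Binv %*% (b - AN %*% x[nonbasic]))
      y <- as.vector(crossprod(Binv, cost[basis]))
      d <- cost[nonbasic] - as.vector(crossprod(AN, y))
      viol <- ifelse(at_lower[nonbasic], -d, d)
      viol[!allowed[nonbasic]] <- -Inf
      elig <- which(viol > tol)
      if (length(elig) == 0L) {
        return(list(status = "optimal", x = x, basis = basis,
                    at_lower = at_lower, duals = y,
                    nonbasic = nonbasic, d = d))
      }
      obj_now <- sum(cost * x)
      if (obj_now < last_obj - 1e-12) { stalled <- 0L } else { stalled <- stalled + 1L }
      last_obj <- obj_now
      if (stalled > 5L * m) bland <- TRUE
      e <- if (bland) nonbasic[min(elig)] else nonbasic[elig[which.max(viol[elig])]]
      sigma <- if (at_lower[e]) 1 else -1
      delta <- -sigma * as.vector(Binv %*% Afull[, e])
      xB <- x[basis]
      ratio <- rep(Inf, m)
      up <- delta > tol
      dn <- delta < -tol
      ratio[up] <- (hi_f[basis[up]] - xB[up]) / delta[up]
      ratio[dn] <- (xB[dn] - lo_f[basis[dn]]) / (-delta[dn])
      t_bound <- hi_f[e] - lo_f[e]
      min_ratio <- suppressWarnings(min(ratio))
      t_best <- max(0, min(t_bound, min_ratio))
      if (!is.finite(t_best)) return(list(status = "unbounded"))
      if (min_ratio <= t_bound) {
        # a basic variable blocks first: pivot
        hits <- which(ratio <= min_ratio + tol)
        leave <- if (bland) hits[which.min(basis[hits])] else
          hits[which.max(abs(delta[hits]))]
        x[e] <- x[e] + sigma * t_best
        x[basis] <- xB + delta * t_best
        lv <- basis[leave]
        hit_upper <- delta[leave] > 0
        x[lv] <- if (hit_upper) hi_f[lv] else lo_f[lv]
        at_lower[lv] <- !hit_upper
        basis[leave] <- e
      } else {
        # entering variable flips to its opposite bound
        x[e] <- if (at_lower[e]) hi_f[e] else lo_f[e]
        at_lower[e] <- !at_lower[e]
        x[basis] <- xB + delta * t_bound
      }
    }
  }

  # phase 1: minimise sum of artificials
  cost1 <- c(rep(0, n), rep(1, m))
  allowed <- rep(TRUE, n + m)
  ph1 <- run_phase(cost1, x, basis, at_lower, allowed)
  if (ph1$status != "optimal") {
    return(list(status = if (ph1$status == "maxit") "maxit" else "solver_error",
                x = rep(NA_real_, n), objective = NA_real_,
                duals = rep(NA_real_, m), reduced_costs = rep(NA_real_, n)))
  }
  feas_tol <- 1e-7 * (1 + max(abs(b), 0))
  if (sum(ph1$x[n + seq_len(m)]) > feas_tol) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective = NA_real_, duals = rep(NA_real_, m),
                reduced_costs = rep(NA_real_, n)))
  }

  # phase 2: pin artificials to zero, optimise the real objective
  x <- ph1$x; basis <- ph1$basis; at_lower <- ph1$at_lower
  art <- n + seq_len(m)
  lo_f[art] <- 0; hi_f[art] <- 0
  x[art] <- pmax(pmin(x[art], 0), 0)
  allowed[art] <- FALSE  # never re-enters; basic artificials stay at 0
  cost2 <- c(cc, rep(0, m))
  ph2 <- run_phase(cost2, x, basis, at_lower, allowed)
  if (ph2$status != "optimal") {
    return(list(status = switch(ph2$status, maxit = "maxit",
                                unbounded = "unbounded", "solver_error"),
                x = rep(NA_real_, n), objective = NA_real_,
                duals = rep(NA_real_, m), reduced_costs = rep(NA_real_, n)))
  }
  # polish: recompute the basic values by direct solve with one step of
  # iterative refinement, so balance residuals reach machine precision
  # even when the basis inverse was mildly ill-conditioned
  xp <- ph2$x
  AB <- Afull[, ph2$basis, drop = FALSE]
  fac <- tryCatch(qr(AB), error = function(e) NULL)
  if (!is.null(fac) && fac$rank == m) {
    nb <- setdiff(seq_len(n + m), ph2$basis)
    xp[ph2$basis] <- qr.coef(fac, b - Afull[, nb, drop = FALSE] %*% xp[nb])
    for (pass in 1:2) {
      r <- b - as.vector(Afull %*% xp)
      if (max(abs(r)) < 1e-12) break
      xp[ph2$basis] <- xp[ph2$basis] + qr.coef(fac, r)
    }
  }
  xs <- xp[seq_len(n)]
  xs <- pmin(pmax(xs, lo), hi)  # clip solver dust
  # problems right on the feasibility boundary can slip through phase 1
  # by less than its tolerance yet admit no accurate solution; after
  # refinement such points are infeasible at solver precision
  resid <- b - as.vector(A %*% xs)
  if (max(abs(resid)) > 5e-9 * (1 + max(abs(b)))) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective = NA_real_, duals = rep(NA_real_, m),
                reduced_costs = rep(NA_real_, n)))
  }
  red <- rep(0, n + m)
  red[ph2$nonbasic] <- ph2$d
  duals <- as.vector(ph2$duals)
  if (maximize) {
    duals <- -duals
    red <- -red
  }
  list(status = "optimal",
       x = xs,
       objective = sum(obj * xs),
       duals = duals,
       reduced_costs = red[seq_len(n)])
}
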