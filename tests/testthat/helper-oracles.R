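# Independent oracles and miniature fixtures used across the suite.

# Brute-force vertex enumeration for min/max obj'x s.t. A x = b, lb<=x<=ub.
# Every vertex of the polytope corresponds to a nonsingular m-column basis
# with the remaining variables pinned at a bound; with all bounds finite
# (infinities clamped to the same big value the solver uses) the optimum
# of a feasible bounded LP is attained at such a vertex. Exponential in
# size, deliberately: it shares no code with the simplex path.
oracle_lp <- function(obj, A, b, lb, ub, maximize = FALSE,
                      big = 1e6, tol = 1e-7) {
  A <- as.matrix(A)
  # drop linearly dependent balance rows (keeping b consistent) so that
  # square bases exist; inconsistent dependent rows mean infeasible
  qrt <- qr(t(A))
  if (qrt$rank < nrow(A)) {
    keep <- qrt$pivot[seq_len(qrt$rank)]
    drop <- setdiff(seq_len(nrow(A)), keep)
    Ak <- A[keep, , drop = FALSE]
    for (i in drop) {
      cf <- qr.coef(qr(t(Ak)), A[i, ])
      if (abs(sum(cf * b[keep]) - b[i]) > 1e-8) {
        return(list(status = "infeasible", objective = NA_real_))
      }
    }
    A <- Ak; b <- b[keep]
  }
  m <- nrow(A); n <- ncol(A)
  stopifnot(n >= m)
  lo <- pmax(lb, -big); hi <- pmin(ub, big)
  best <- NULL
  combs <- utils::combn(n, m)
  for (ci in seq_len(ncol(combs))) {
    Bidx <- combs[, ci]
    AB <- A[, Bidx, drop = FALSE]
    if (abs(det(AB)) < 1e-11) next
    Nidx <- setdiff(seq_len(n), Bidx)
    k <- length(Nidx)
    for (mask in 0:(2^k - 1)) {
      xN <- if (k > 0) {
        ifelse(bitwAnd(mask, bitwShiftL(1, seq_len(k) - 1)) > 0,
               hi[Nidx], lo[Nidx])
      } else numeric(0)
      rhs <- b - if (k > 0) as.vector(A[, Nidx, drop = FALSE] %*% xN) else 0
      xB <- tryCatch(solve(AB, rhs), error = function(e) NULL)
      if (is.null(xB)) next
      if (any(xB < lo[Bidx] - tol) || any(xB > hi[Bidx] + tol)) next
      x <- numeric(n); x[Bidx] <- xB; x[Nidx] <- xN
      val <- sum(obj * x)
      if (is.null(best) ||
          (maximize && val > best$objective) ||
          (!maximize && val < best$objective)) {
        best <- list(objective = val, x = x)
      }
    }
  }
  if (is.null(best)) list(status = "infeasible", objective = NA_real_)
  else c(list(status = "optimal"), best)
}

# Solve a community LP spec with the vertex-enumeration oracle.
oracle_solve_spec <- function(spec) {
  stopifnot(is.null(spec$A_ineq))
  oracle_lp(unname(spec$obj), spec$A, spec$b, spec$lb, spec$ub,
            maximize = spec$maximize)
}

# Independently coded classical FBA for one species plus environmental
# exchanges: steady state S v = 0 over all metabolites, biomass rate as a
# separate variable, exchange column per extracellular metabolite
# (export-positive). Built straight from the species' stoichiometry lists,
# not from the community-matrix machinery.
oracle_fba <- function(cm) {
  stopifnot(length(cm$species) == 1)
  s <- cm$species[[1]]
  mets <- s$metabolites$id
  rxn <- s$reactions[s$reactions$kind != "biomass", , drop = FALSE]
  nr <- nrow(rxn)
  ex <- cm$exchanges
  nv <- nr + 1 + nrow(ex)
  A <- matrix(0, length(mets), nv,
              dimnames = list(mets, c(rxn$id, "BIOMASS", ex$ex_id)))
  for (j in seq_len(nr)) {
    st <- s$stoich[[rxn$id[j]]]
    A[names(st), j] <- st
  }
  A[names(s$c), nr + 1] <- s$c
  for (k in seq_len(nrow(ex))) A[ex$metabolite[k], nr + 1 + k] <- -1
  lb <- c(rxn$lb, 0, ex$phi_lb)
  ub <- c(rxn$ub, Inf, ex$phi_ub)
  obj <- c(rep(0, nr), 1, rep(0, nrow(ex)))
  res <- cfba:::simplex_solve(obj, A, rep(0, length(mets)), lb, ub,
                              maximize = TRUE)
  list(status = res$status, mu = if (res$status == "optimal") res$objective else NA_real_)
}

# Tiny obligate mutualistic pair: 10 LP variables in total, small enough
# for exhaustive vertex enumeration.
mini_pair <- function(uptake = 10, tx_ub = 1000, ty_ub = 1000) {
  sp_a <- species_model(
    "a",
    tibble::tibble(id = c("A", "Ya", "S_x", "X_x", "Y_x"),
                   role = c("intracellular", "intracellular",
                            "unique", "crossfed", "crossfed")),
    tibble::tibble(id = c("t_s", "t_x", "t_y", "growth"),
                   kind = c("unique_transport", "crossfeed_transport",
                            "crossfeed_transport", "biomass"),
                   equation = c("S_x -> A", "A -> X_x", "Y_x -> Ya",
                                "1 A + 0.5 Ya ->"),
                   lb = 0, ub = c(uptake, tx_ub, 1000, 1000)))
  sp_b <- species_model(
    "b",
    tibble::tibble(id = c("Xb", "Yb", "X_x", "Y_x"),
                   role = c("intracellular", "intracellular",
                            "crossfed", "crossfed")),
    tibble::tibble(id = c("t_x", "conv", "t_y", "growth"),
                   kind = c("crossfeed_transport", "intracellular",
                            "crossfeed_transport", "biomass"),
                   equation = c("X_x -> Xb", "Xb -> 2 Yb", "Yb -> Y_x",
                                "1 Xb ->"),
                   lb = 0, ub = c(1000, 1000, ty_ub, 1000)))
  assemble_community(
    list(sp_a, sp_b), crossfed_ids = c("X_x", "Y_x"),
    env_exchanges = tibble::tibble(metabolite_id = "S_x",
                                   J_lb = -uptake, J_ub = 0),
    X_T = 1)
}

# Fully symmetric pair: species beta is species alpha with the two
# cross-fed metabolites swapped and its own substrate.
symmetric_pair <- function(uptake = 10) {
  make <- function(id, sub, cf_out, cf_in) {
    species_model(
      id,
      tibble::tibble(id = c("A", "R", sub, cf_out, cf_in),
                     role = c("intracellular", "intracellular",
                              "unique", "crossfed", "crossfed")),
      tibble::tibble(id = c("t_s", "t_out", "t_in", "growth"),
                     kind = c("unique_transport", "crossfeed_transport",
                              "crossfeed_transport", "biomass"),
                     equation = c(sprintf("%s -> A", sub),
                                  sprintf("A -> %s", cf_out),
                                  sprintf("%s -> R", cf_in),
                                  "1 A + 1 R ->"),
                     lb = 0, ub = c(uptake, 1000, 1000, 1000)))
  }
  assemble_community(
    list(make("alpha", "S1_x", "X_x", "Y_x"),
         make("beta", "S2_x", "Y_x", "X_x")),
    crossfed_ids = c("X_x", "Y_x"),
    env_exchanges = tibble::tibble(metabolite_id = c("S1_x", "S2_x"),
                                   J_lb = c(-uptake, -uptake), J_ub = c(0, 0)),
    X_T = 1)
}

mu_at <- function(cm, f, ...) {
  sol <- maximize_growth_at_fractions(cm, f, ...)
  if (sol$status == "optimal") sol$mu else NA_real_
}

expect_close <- function(actual, expected, tol = 1e-8) {
  expect_true(is.finite(actual) && is.finite(expected) &&
                abs(actual - expected) <= tol,
              label = sprintf("|%.12g - %.12g| <= %g", actual, expected, tol))
}
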