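# Outer optimisation over the biomass-fraction simplex. The inner LP gives
# mu*(f) at fixed fractions; the outer problem (maximising mu* over f) is
# non-linear, so it is attacked with a deterministic uniform simplex grid
# followed by shrinking local pattern refinement - reproducible across
# platforms, unlike heuristic simplex searches.

# Uniform grid on the (n-1)-simplex with spacing `resolution`:
# all compositions k/m with k integer, m = round(1/resolution).
simplex_grid <- function(n, resolution) {
  stopifnot(resolution > 0, resolution <= 0.5 || n == 1)
  if (n == 1) return(matrix(1, 1, 1))
  m <- max(1L, as.integer(round(1 / resolution)))
  compositions <- function(total, parts) {
    if (parts == 1) return(matrix(total, 1, 1))
    out <- list()
    for (k in 0:total) {
      rest <- compositions(total - k, parts - 1)
      out[[length(out) + 1]] <- cbind(k, rest, deparse.level = 0)
    }
    do.call(rbind, out)
  }
  compositions(m, n) / m
}

#' Scan the community growth rate over the biomass-fraction simplex
#'
#' Solves the fixed-fraction balanced-growth LP at every point of a uniform
#' grid over the biomass fractions. Infeasible compositions (no balanced
#' steady state at any growth rate) are retained with `status
#' "infeasible"` and `mu = NA`; they are excluded from the maximum.
#'
#' @param cm A `community_model`.
#' @param resolution Fraction-grid spacing in (0, 0.5] (default 0.01 for
#'   two species, 0.05 otherwise).
#' @param extra_constraints See [build_lp()].
#' @return A `fraction_scan` object: tibble `grid` with one row per
#'   composition (columns `f_<species>`, `mu`, `status`), plus `mu_max`,
#'   `argmax` and scan metadata.
#' @export
scan_fractions <- function(cm, resolution = if (length(cm$species_ids) == 2) 0.01 else 0.05,
                           extra_constraints = NULL) {
  stopifnot(inherits(cm, "community_model"))
  n <- length(cm$species_ids)
  G <- simplex_grid(n, resolution)
  res <- map(seq_len(nrow(G)), function(k) {
    f <- stats::setNames(G[k, ], cm$species_ids)
    sol <- maximize_growth_at_fractions(cm, f, extra_constraints)
    list(mu = if (sol$status == "optimal") sol$mu else NA_real_,
         status = sol$status)
  })
  grid <- as_tibble(as.data.frame(G))
  names(grid) <- paste0("f_", cm$species_ids)
  grid$mu <- map_dbl(res, "mu")
  grid$status <- map_chr(res, "status")
  new_fraction_scan(grid, cm, resolution, extra_constraints)
}

new_fraction_scan <- function(grid, cm, resolution, extra_constraints = NULL) {
  feas <- !is.na(grid$mu)
  mu_max <- if (any(feas)) max(grid$mu[feas]) else NA_real_
  argmax <- if (any(feas)) {
    k <- which(grid$mu == mu_max)[1]
    stats::setNames(as.numeric(grid[k, paste0("f_", cm$species_ids)]), cm$species_ids)
  } else NULL
  structure(
    list(grid = grid, mu_max = mu_max, argmax = argmax,
         species_ids = cm$species_ids, resolution = resolution,
         extra_constraints = extra_constraints),
    class = "fraction_scan")
}

#' @export
print.fraction_scan <- function(x, ...) {
  cat(sprintf("<fraction_scan> %d grid points over %d species, resolution %g\n",
              nrow(x$grid), length(x$species_ids), x$resolution))
  if (!is.na(x$mu_max)) {
    cat(sprintf("  mu_max = %.6g h^-1 at (%s); %d infeasible point(s)\n",
                x$mu_max, paste(sprintf("%s=%.4g", names(x$argmax), x$argmax),
                                collapse = ", "),
                sum(is.na(x$grid$mu))))
  } else cat("  all grid points infeasible\n")
  invisible(x)
}

#' Globally maximise the community growth rate over species composition
#'
#' Coarse simplex-grid scan followed by shrinking local refinement around
#' the incumbent: at each stage the incumbent composition is perturbed
#' along all species-pair directions with the current step, the step
#' divides by 5 whenever no perturbation improves, and refinement stops
#' when the step falls below `refine_tol`. The refined maximum is never
#' below the coarse-scan maximum.
#'
#' @param cm A `community_model`.
#' @param coarse_resolution Initial grid spacing (default 0.01 for two
#'   species, 0.05 otherwise).
#' @param refine_tol Stop when the local step is below this (default 1e-5).
#' @param extra_constraints See [build_lp()].
#' @return A list with `mu_max`, `argmax` (named fraction vector) and
#'   `scan` (the coarse `fraction_scan`).
#' @export
optimize_community <- function(cm,
                               coarse_resolution = if (length(cm$species_ids) == 2) 0.01 else 0.05,
                               refine_tol = 1e-5,
                               extra_constraints = NULL) {
  scan <- scan_fractions(cm, coarse_resolution, extra_constraints)
  if (is.na(scan$mu_max)) {
    return(list(mu_max = NA_real_, argmax = NULL, scan = scan,
                status = "infeasible"))
  }
  n <- length(cm$species_ids)
  f_best <- scan$argmax
  mu_best <- scan$mu_max
  if (n > 1) {
    ref <- refine_from(cm, f_best, mu_best, coarse_resolution, refine_tol,
                       extra_constraints)
    mu_best <- ref$mu; f_best <- ref$f
  }
  list(mu_max = mu_best, argmax = f_best, scan = scan, status = "optimal")
}

# Shrinking pattern search on the simplex, seeded at f0: perturb along all
# species-pair directions, divide the step by 5 when nothing improves.
refine_from <- function(cm, f0, mu0, step0, refine_tol, extra_constraints = NULL) {
  n <- length(f0)
  f_best <- f0; mu_best <- mu0
  if (is.na(mu_best)) {
    sol <- maximize_growth_at_fractions(cm, f_best, extra_constraints)
    mu_best <- if (sol$status == "optimal") sol$mu else NA_real_
  }
  step <- step0
  while (step >= refine_tol && n > 1) {
    improved <- FALSE
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a == b) next
        f_try <- f_best
        d <- min(step, f_try[b])
        if (d <= 0) next
        f_try[a] <- f_try[a] + d
        f_try[b] <- f_try[b] - d
        f_try <- f_try / sum(f_try)
        sol <- maximize_growth_at_fractions(cm, f_try, extra_constraints)
        mu_try <- if (sol$status == "optimal") sol$mu else NA_real_
        if (!is.na(mu_try) && (is.na(mu_best) || mu_try > mu_best + 1e-12)) {
          mu_best <- mu_try; f_best <- f_try; improved <- TRUE
        }
      }
    }
    if (!improved) step <- step / 5
  }
  list(mu = mu_best, f = f_best)
}

#' Near-optimal region of biomass fractions
#'
#' The set of compositions whose maximal growth rate is within a relative
#' tolerance of the community optimum, `{f : mu*(f) >= (1 - tol) mu_max}`.
#' For two species the connected runs of near-optimal grid points are
#' refined by bisection to interval endpoints; for more species the
#' qualifying grid subset is returned.
#'
#' @param cm A `community_model`.
#' @param scan A `fraction_scan` from [scan_fractions()]; computed at the
#'   scan's resolution if missing.
#' @param tol Relative tolerance on the optimum (default 1e-6).
#' @param mu_max Reference optimum; defaults to the scan's maximum (pass
#'   the refined maximum from [optimize_community()] for sharper regions).
#' @param extra_constraints See [build_lp()].
#' @return For two species a tibble with columns `f_lo`, `f_hi` (one row
#'   per connected interval, in the fraction of the first species);
#'   otherwise a tibble of qualifying grid rows.
#' @export
optimal_fraction_region <- function(cm, scan = NULL, tol = 1e-6, mu_max = NULL,
                                    extra_constraints = NULL) {
  scan <- scan %||% scan_fractions(cm, extra_constraints = extra_constraints)
  mu_max <- mu_max %||% scan$mu_max
  if (is.na(mu_max)) abort("community infeasible on the whole grid")
  thr <- (1 - tol) * mu_max
  n <- length(scan$species_ids)
  fcol <- paste0("f_", scan$species_ids[1])
  ok <- !is.na(scan$grid$mu) & scan$grid$mu >= thr - 1e-12
  if (n != 2) return(scan$grid[ok, , drop = FALSE])

  f1 <- scan$grid[[fcol]]
  ord <- order(f1)
  f1 <- f1[ord]; okk <- ok[ord]
  mu_at <- function(f) {
    sol <- maximize_growth_at_fractions(
      cm, stats::setNames(c(f, 1 - f), scan$species_ids), extra_constraints)
    if (sol$status == "optimal") sol$mu else NA_real_
  }
  above <- function(f) { m <- mu_at(f); !is.na(m) && m >= thr }
  # refine the crossing between a below-threshold and an above-threshold
  # point; returns the above-side estimate (conservatively inside)
  bisect <- function(f_below, f_above) {
    for (it in 1:40) {
      mid <- (f_below + f_above) / 2
      if (above(mid)) f_above <- mid else f_below <- mid
      if (abs(f_above - f_below) < 1e-9) break
    }
    f_above
  }
  runs <- rle(okk)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- list()
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    i0 <- starts[r]; i1 <- ends[r]
    f_lo <- f1[i0]; f_hi <- f1[i1]
    if (i0 > 1) f_lo <- bisect(f1[i0 - 1], f1[i0])
    if (i1 < length(f1)) f_hi <- bisect(f1[i1 + 1], f1[i1])
    out[[length(out) + 1]] <- tibble(f_lo = f_lo, f_hi = f_hi)
  }
  bind_rows(out)
}

#' Scan the community growth rate over the biomass ratio of a species pair
#'
#' Chemostat experiments report species abundance as a biomass ratio
#' `r = X_num / X_den` rather than a fraction. Since
#' `f_num = r / (1 + r)`, scanning over `r` is the fraction scan under a
#' change of variables; results are identical point-for-point.
#'
#' @param cm A two-species `community_model`.
#' @param ratio_grid Positive ratios to scan.
#' @param numerator Species in the ratio's numerator (default the second
#'   species).
#' @param extra_constraints See [build_lp()].
#' @return A `fraction_scan` whose grid carries an extra `ratio` column.
#' @export
scan_biomass_ratio <- function(cm, ratio_grid, numerator = cm$species_ids[2],
                               extra_constraints = NULL) {
  stopifnot(inherits(cm, "community_model"))
  if (length(cm$species_ids) != 2) abort("biomass-ratio scan requires exactly 2 species")
  if (any(ratio_grid <= 0)) abort("biomass ratios must be positive")
  if (!numerator %in% cm$species_ids) abort("unknown numerator species")
  denominator <- setdiff(cm$species_ids, numerator)
  rows <- map(ratio_grid, function(r) {
    f_num <- r / (1 + r)
    f <- stats::setNames(c(f_num, 1 - f_num), c(numerator, denominator))
    sol <- maximize_growth_at_fractions(cm, f[cm$species_ids], extra_constraints)
    tibble(ratio = r,
           mu = if (sol$status == "optimal") sol$mu else NA_real_,
           status = sol$status)
  })
  grid <- bind_rows(rows)
  fr <- grid$ratio / (1 + grid$ratio)
  grid[[paste0("f_", numerator)]] <- fr
  grid[[paste0("f_", denominator)]] <- 1 - fr
  grid <- grid[, c(paste0("f_", cm$species_ids), "ratio", "mu", "status")]
  new_fraction_scan(grid, cm, resolution = NA_real_, extra_constraints)
}
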