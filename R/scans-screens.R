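# Higher-order analyses over flux bounds: 2-D phase planes of the optimal
# community growth rate, limitation-regime classification, dual-limitation
# detection, and the one-at-a-time cross-feeding-metabolite screen.

#' Phase-plane analysis over two flux upper bounds
#'
#' Classical phenotype phase-plane analysis lifted to the community level:
#' two upper bounds (typically the capacities of the two cross-feeding
#' transports) are varied over grids, and at every grid cell the community
#' growth rate is maximised over the biomass fractions. Each cell is
#' classified by which of the scanned bounds are active at the optimum
#' (within a relative `active_tol` of the bound — the optimal composition
#' is itself found only to `refine_tol`, so fluxes sit near, not exactly
#' on, their limits): `"crossfeed_limited"` when at least one scanned
#' bound binds, `"dual_limited"` when both bind, and `"env_limited"` when
#' neither does (some other, environmental or internal, constraint is
#' limiting). [find_dual_limitation()] is the finite-difference
#' counterpart and the more stringent notion: a bound can be active yet
#' not limiting once the composition re-adjusts.
#'
#' @param cm A `community_model`.
#' @param bound1_id,bound2_id Flux ids whose upper bounds are scanned.
#' @param grid1,grid2 Strictly increasing vectors of bound values.
#' @param coarse_resolution,refine_tol Passed to [optimize_community()]
#'   for the per-cell composition optimisation.
#' @param active_tol Relative tolerance for calling a bound active.
#' @return A `phase_plane` object; its `grid` tibble has one row per cell
#'   with `bound1`, `bound2`, `mu_max`, `f_opt_<first species>`, `regime`.
#' @export
phase_plane <- function(cm, bound1_id, grid1, bound2_id, grid2,
                        coarse_resolution = 0.05, refine_tol = 1e-4,
                        active_tol = 1e-3) {
  stopifnot(inherits(cm, "community_model"))
  if (any(diff(grid1) <= 0) || any(diff(grid2) <= 0)) {
    abort("phase-plane grids must be strictly increasing")
  }
  for (id in c(bound1_id, bound2_id)) get_flux_bounds(cm, id)  # existence check
  sp1 <- cm$species_ids[1]
  cells <- tidyr::expand_grid(bound1 = grid1, bound2 = grid2)
  res <- map(seq_len(nrow(cells)), function(k) {
    cmk <- set_flux_bound(cm, bound1_id, ub = cells$bound1[k])
    cmk <- set_flux_bound(cmk, bound2_id, ub = cells$bound2[k])
    opt <- optimize_community(cmk, coarse_resolution, refine_tol)
    if (opt$status != "optimal") {
      return(list(mu_max = NA_real_, f_opt = NA_real_, regime = "infeasible"))
    }
    sol <- maximize_growth_at_fractions(cmk, opt$argmax)
    act1 <- bound_active(sol, bound1_id, cells$bound1[k], active_tol)
    act2 <- bound_active(sol, bound2_id, cells$bound2[k], active_tol)
    regime <- if (act1 && act2) "dual_limited"
      else if (act1 || act2) "crossfeed_limited"
      else "env_limited"
    list(mu_max = opt$mu_max, f_opt = unname(opt$argmax[sp1]), regime = regime)
  })
  grid <- cells
  grid$mu_max <- map_dbl(res, "mu_max")
  grid[[paste0("f_opt_", sp1)]] <- map_dbl(res, "f_opt")
  grid$regime <- map_chr(res, "regime")
  structure(
    list(grid = grid,
         bound1_id = bound1_id, bound2_id = bound2_id,
         grid1 = grid1, grid2 = grid2,
         cm = cm, coarse_resolution = coarse_resolution,
         refine_tol = refine_tol),
    class = "phase_plane")
}

# Is the named flux at the scanned upper bound in this solution?
bound_active <- function(sol, flux_id, bound, tol) {
  v <- sol$fluxes$value[sol$fluxes$flux == flux_id]
  length(v) == 1 && is.finite(bound) &&
    abs(v - bound) <= max(tol * max(1, abs(bound)), 1e-9)
}

#' @export
print.phase_plane <- function(x, ...) {
  cat(sprintf("<phase_plane> %d x %d cells over ub(%s) x ub(%s)\n",
              length(x$grid1), length(x$grid2), x$bound1_id, x$bound2_id))
  print(table(x$grid$regime))
  invisible(x)
}

#' Phase-plane growth-rate matrix
#'
#' @param pp A `phase_plane`.
#' @return Numeric matrix of `mu_max` values, rows indexed by the first
#'   bound's grid, columns by the second's.
#' @export
phase_plane_matrix <- function(pp) {
  stopifnot(inherits(pp, "phase_plane"))
  matrix(pp$grid$mu_max, nrow = length(pp$grid1), ncol = length(pp$grid2),
         byrow = TRUE,
         dimnames = list(as.character(pp$grid1), as.character(pp$grid2)))
}

#' Detect dual-limitation cells by finite-difference probing
#'
#' A cell is dual-limited when both scanned bounds are genuinely limiting:
#' reducing either bound by the relative step `eps` (and re-optimising the
#' composition) lowers the maximal growth rate by more than `tol`. This is
#' the finite-difference counterpart of the active-set classification in
#' [phase_plane()] and serves as its independent check; on the
#' dual-limitation line the two cross-feeding capacities are equally
#' limiting, and the line ends where the environmental limitation takes
#' over.
#'
#' The probing step must dominate the tolerance of the outer composition
#' search (roughly the landscape slope times `refine_tol`), otherwise
#' genuine sensitivities drown in refinement noise; the defaults (5%
#' step, `1e-3` drop threshold) leave an order of magnitude of headroom
#' on both sides for the bundled fixtures.
#'
#' @param pp A `phase_plane`.
#' @param tol Minimal decrease in `mu_max` to call a bound limiting.
#' @param eps Relative bound reduction used for probing.
#' @return The phase-plane grid tibble with logical columns `lim1`, `lim2`
#'   and `dual_limited`.
#' @export
find_dual_limitation <- function(pp, tol = 1e-3, eps = 0.05) {
  stopifnot(inherits(pp, "phase_plane"))
  cm <- pp$cm
  sp1 <- cm$species_ids[1]
  two_species <- length(cm$species_ids) == 2
  out <- pp$grid
  out$lim1 <- FALSE; out$lim2 <- FALSE
  fcol <- paste0("f_opt_", sp1)
  for (k in seq_len(nrow(out))) {
    if (is.na(out$mu_max[k])) next
    base <- out$mu_max[k]
    for (which_b in 1:2) {
      b1 <- out$bound1[k]; b2 <- out$bound2[k]
      if (which_b == 1) b1 <- b1 * (1 - eps) else b2 <- b2 * (1 - eps)
      cmk <- set_flux_bound(cm, pp$bound1_id, ub = b1)
      cmk <- set_flux_bound(cmk, pp$bound2_id, ub = b2)
      if (two_species) {
        # re-optimise the composition locally from the cell's optimum; the
        # bound perturbation is small, so the argmax moves little
        f0 <- stats::setNames(c(out[[fcol]][k], 1 - out[[fcol]][k]),
                              cm$species_ids)
        ref <- refine_from(cmk, f0, NA_real_, pp$coarse_resolution, pp$refine_tol)
        mu_new <- ref$mu
      } else {
        opt <- optimize_community(cmk, pp$coarse_resolution, pp$refine_tol)
        mu_new <- if (opt$status == "optimal") opt$mu_max else NA_real_
      }
      drop <- if (is.na(mu_new)) Inf else base - mu_new
      if (drop > tol) {
        if (which_b == 1) out$lim1[k] <- TRUE else out$lim2[k] <- TRUE
      }
    }
  }
  out$dual_limited <- out$lim1 & out$lim2
  out
}

#' One-at-a-time cross-feeding-metabolite screen at fixed growth rate
#'
#' Which exchanged metabolite could carry the cross-feeding? For each
#' candidate, all other cross-feeding transport routes are closed, the
#' candidate's routes are opened wide, the community growth rate is pinned
#' to `fixed_mu` (e.g. the chemostat dilution rate), and the substrate
#' uptake required to sustain that rate is minimised over the biomass
#' fractions. Candidates are compared to a reference metabolite by the
#' percentage change in minimal substrate uptake; negative values mean the
#' candidate is the more efficient vehicle. A candidate lacking a
#' transporter in one of the species is reported `"blocked"` with no
#' number.
#'
#' @param cm A `community_model`.
#' @param candidate_ids Crossfed metabolite ids to test one at a time.
#' @param fixed_mu Growth rate to sustain, h^-1.
#' @param substrate_exchange_id Exchange flux whose uptake is minimised
#'   (e.g. `"EX_Glc_x"`); uptake is reported as a positive magnitude.
#' @param reference_id Reference candidate (defaults to the first).
#' @param mode `"instead"` (default): candidates replace the reference
#'   route; `"in_addition"`: the reference's routes stay open as well.
#' @param open_bound Capacity given to opened routes (effectively
#'   unconstrained).
#' @param resolution,refine_tol Composition-search controls (see
#'   [optimize_community()]).
#' @return A `screen_result`: tibble with `metabolite`, `min_uptake`,
#'   `percent_change`, `status`, ordered as given.
#' @export
crossfeed_screen <- function(cm, candidate_ids, fixed_mu,
                             substrate_exchange_id,
                             reference_id = candidate_ids[1],
                             mode = c("instead", "in_addition"),
                             open_bound = 1000,
                             resolution = 0.02, refine_tol = 1e-4) {
  stopifnot(inherits(cm, "community_model"))
  mode <- match.arg(mode)
  if (!reference_id %in% candidate_ids) {
    abort("reference_id must be among candidate_ids")
  }
  unknown <- setdiff(candidate_ids, cm$crossfed_ids)
  if (length(unknown)) {
    abort(sprintf("candidate(s) not declared crossfed: %s", paste(unknown, collapse = ", ")))
  }
  # transports of each crossfed metabolite, per species
  routes <- map(cm$species, function(s) {
    r <- s$reactions[s$reactions$kind == "crossfeed_transport", , drop = FALSE]
    touched <- map(r$id, function(rid) {
      intersect(names(s$stoich[[rid]]), cm$crossfed_ids)
    })
    tibble(species = s$species_id, reaction = r$id,
           col = paste0(s$species_id, ".", r$id), mets = touched)
  }) |> bind_rows()

  # Routes of candidate-set metabolites are switched: the tested
  # candidate's routes open wide, every other candidate's routes close.
  # Cross-fed metabolites outside the candidate set (e.g. an obligatory
  # nitrogen shuttle) keep their configured bounds.
  min_uptake_for <- function(open_ids) {
    cmk <- cm
    for (k in seq_len(nrow(routes))) {
      touches_open <- length(intersect(routes$mets[[k]], open_ids)) > 0
      touches_candidate <- length(intersect(routes$mets[[k]], candidate_ids)) > 0
      if (touches_open) {
        cmk <- set_flux_bound(cmk, routes$col[k], ub = open_bound)
      } else if (touches_candidate) {
        cmk <- set_flux_bound(cmk, routes$col[k], lb = 0, ub = 0)
      }
    }
    # minimise uptake magnitude = maximise the (negative) exchange flux
    best <- NULL
    sc <- scan_fractions_objective(cmk, resolution, fixed_mu, substrate_exchange_id)
    if (all(is.na(sc$value))) return(NA_real_)
    k0 <- which.max(sc$value)  # max phi = least-negative = min uptake
    f_best <- stats::setNames(as.numeric(sc[k0, seq_along(cm$species_ids)]),
                              cm$species_ids)
    v_best <- sc$value[k0]
    step <- resolution
    while (step >= refine_tol) {
      improved <- FALSE
      for (a in seq_along(f_best)) for (b in seq_along(f_best)) {
        if (a == b) next
        f_try <- f_best
        d <- min(step, f_try[b])
        if (d <= 0) next
        f_try[a] <- f_try[a] + d; f_try[b] <- f_try[b] - d
        f_try <- f_try / sum(f_try)
        sol <- optimize_flux_at_growth(cmk, f_try, fixed_mu,
                                       substrate_exchange_id, sense = "max")
        if (sol$status == "optimal" && sol$objective_value > v_best + 1e-12) {
          v_best <- sol$objective_value; f_best <- f_try; improved <- TRUE
        }
      }
      if (!improved) step <- step / 5
    }
    -v_best  # uptake magnitude (uptake flux is negative)
  }

  has_route <- function(sp, met) {
    any(map_lgl(seq_len(nrow(routes)), function(k) {
      routes$species[k] == sp && met %in% routes$mets[[k]]
    }))
  }

  rows <- map(candidate_ids, function(met) {
    open_ids <- if (mode == "in_addition" && met != reference_id) {
      c(met, reference_id)
    } else met
    carriers <- map_lgl(cm$species_ids, has_route, met = met)
    if (!all(carriers)) {
      return(tibble(metabolite = met, min_uptake = NA_real_,
                    percent_change = NA_real_, status = "blocked"))
    }
    v <- min_uptake_for(open_ids)
    tibble(metabolite = met, min_uptake = v,
           percent_change = NA_real_,
           status = if (is.na(v)) "infeasible" else "optimal")
  }) |> bind_rows()

  ref <- rows$min_uptake[rows$metabolite == reference_id]
  if (length(ref) == 1 && !is.na(ref) && ref != 0) {
    rows$percent_change <- ifelse(is.na(rows$min_uptake), NA_real_,
                                  100 * (rows$min_uptake - ref) / ref)
    rows$percent_change[rows$metabolite == reference_id] <- 0
  }
  structure(
    list(table = rows, reference = reference_id, fixed_mu = fixed_mu,
         substrate = substrate_exchange_id, mode = mode),
    class = "screen_result")
}

# Fixed-mu scan helper: value of the (maximised) substrate exchange flux
# at each composition grid point.
scan_fractions_objective <- function(cm, resolution, fixed_mu, flux_id) {
  n <- length(cm$species_ids)
  G <- simplex_grid(n, resolution)
  vals <- map_dbl(seq_len(nrow(G)), function(k) {
    f <- stats::setNames(G[k, ], cm$species_ids)
    sol <- optimize_flux_at_growth(cm, f, fixed_mu, flux_id, sense = "max")
    if (sol$status == "optimal") sol$objective_value else NA_real_
  })
  out <- as_tibble(as.data.frame(G))
  names(out) <- paste0("f_", cm$species_ids)
  out$value <- vals
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> reference '%s', mu = %g h^-1, substrate %s (%s)\n",
              x$reference, x$fixed_mu, x$substrate, x$mode))
  print(as.data.frame(x$table))
  invisible(x)
}
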