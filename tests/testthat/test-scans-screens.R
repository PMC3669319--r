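# Phase-plane analyses and the cross-feeding screen on small grids; the
# full-size surfaces are exercised in the acceptance suite.

test_that("phase plane is monotone in both bounds and plateaus at the environment limit", {
  cm <- toy_consortium()
  grid1 <- c(0.5, 2, 6, 20, 1000)   # succinate export cap of i
  grid2 <- c(0.5, 2, 6, 20, 1000)   # ammonium export cap of j
  pp <- phase_plane(cm, "i.t_succ", grid1, "j.t_nh3", grid2,
                    coarse_resolution = 0.05, refine_tol = 1e-4)
  M <- phase_plane_matrix(pp)
  tol <- 1e-5  # headroom for the outer composition search
  for (r in seq_len(nrow(M))) expect_true(all(diff(M[r, ]) >= -tol))
  for (c in seq_len(ncol(M))) expect_true(all(diff(M[, c]) >= -tol))
  # beyond the critical capacities the environment/anabolism limit sets a
  # plateau that further relaxation cannot raise
  expect_close(M["1000", "1000"], M["20", "1000"], 1e-4)
  expect_identical(pp$grid$regime[pp$grid$bound1 == 1000 & pp$grid$bound2 == 1000],
                   "env_limited")
  # a tight ammonium cap is flagged as a cross-feeding limitation
  expect_match(pp$grid$regime[pp$grid$bound1 == 1000 & pp$grid$bound2 == 0.5],
               "crossfeed|env")
  expect_true(any(pp$grid$regime == "crossfeed_limited"))
})

test_that("a zero cross-feeding bound pins the optimum at zero along that edge", {
  cm <- toy_consortium()
  pp <- phase_plane(cm, "i.t_succ", c(0, 2), "j.t_nh3", c(1, 3),
                    coarse_resolution = 0.1, refine_tol = 1e-3)
  edge <- pp$grid[pp$grid$bound1 == 0, ]
  expect_true(all(is.na(edge$mu_max) | edge$mu_max < 1e-8))
  expect_error(phase_plane(cm, "i.t_succ", c(2, 1), "j.t_nh3", c(1, 3)),
               "increasing")
  expect_error(phase_plane(cm, "i.nope", c(1, 2), "j.t_nh3", c(1, 2)),
               "unknown flux")
})

test_that("finite-difference probing separates dual, single and unlimited cells", {
  cm <- toy_consortium()
  pp <- phase_plane(cm, "i.t_succ", c(0.6, 1000), "j.t_nh3", c(1, 1000),
                    coarse_resolution = 0.05, refine_tol = 1e-4)
  dl <- find_dual_limitation(pp)
  # both caps tight and in proportion: reducing either lowers the optimum
  tight <- dl[dl$bound1 == 0.6 & dl$bound2 == 1, ]
  expect_true(tight$dual_limited)
  # ample succinate, tight ammonium: only the ammonium cap is limiting
  mixed <- dl[dl$bound1 == 1000 & dl$bound2 == 1, ]
  expect_true(mixed$lim2)
  expect_false(mixed$lim1)
  # deep in the plateau nothing cross-feeding-related is limiting
  deep <- dl[dl$bound1 == 1000 & dl$bound2 == 1000, ]
  expect_false(deep$lim1 || deep$lim2 || deep$dual_limited)
})

test_that("screen: reference at exactly 0%, blocked route flagged, consistency", {
  cm <- screen_consortium()
  sr <- crossfeed_screen(cm, c("Ac_x", "Et_x", "Py_x", "La_x"), fixed_mu = 1,
                         substrate_exchange_id = "EX_Glc_x",
                         reference_id = "Ac_x", resolution = 0.05)
  tb <- tidy(sr)
  expect_identical(tb$percent_change[tb$metabolite == "Ac_x"], 0)
  expect_identical(tb$status[tb$metabolite == "La_x"], "blocked")
  expect_true(is.na(tb$min_uptake[tb$metabolite == "La_x"]))
  expect_true(all(tb$min_uptake[tb$status == "optimal"] > 0))
  # the screen's percent changes follow its uptake numbers
  ref <- tb$min_uptake[tb$metabolite == "Ac_x"]
  ok <- tb$status == "optimal"
  expect_equal(tb$percent_change[ok], 100 * (tb$min_uptake[ok] - ref) / ref)
})

test_that("relaxing a candidate's transport capacity cannot raise its minimal uptake", {
  cm <- screen_consortium()
  # only the acetate route open, with varying capacity
  uptake_with_cap <- function(cap) {
    cmk <- cm
    for (id in c("S.t_et", "S.t_py", "S.t_la", "A.t_et", "A.t_py")) {
      cmk <- set_flux_bound(cmk, id, lb = 0, ub = 0)
    }
    cmk <- set_flux_bound(cmk, "S.t_ac", ub = cap)
    sc <- cfba:::scan_fractions_objective(cmk, 0.02, 1, "EX_Glc_x")
    if (all(is.na(sc$value))) return(NA_real_)
    -max(sc$value, na.rm = TRUE)
  }
  tight <- uptake_with_cap(5)
  wide <- uptake_with_cap(1000)
  expect_true(is.finite(tight) && is.finite(wide))
  expect_gte(tight + 1e-9, wide)
})

test_that("screen ranking equals brute-force enumeration over a fine fraction grid", {
  cm <- screen_consortium()
  cands <- c("Ac_x", "Et_x", "Py_x")
  sr <- crossfeed_screen(cm, cands, fixed_mu = 1,
                         substrate_exchange_id = "EX_Glc_x",
                         reference_id = "Ac_x", resolution = 0.05,
                         refine_tol = 1e-4)
  # independent brute force: close the other carriers by hand, enumerate
  # compositions densely, take the minimum uptake
  brute <- purrr::map_dbl(cands, function(cand) {
    cmk <- cm
    for (other in setdiff(c(cands, "La_x"), cand)) {
      for (sp in c("S", "A")) {
        col <- paste0(sp, ".t_", tolower(sub("_x$", "", other)))
        if (col %in% cmk$cols$col) cmk <- set_flux_bound(cmk, col, lb = 0, ub = 0)
      }
    }
    fgrid <- seq(0.01, 0.99, by = 0.001)
    vals <- purrr::map_dbl(fgrid, function(fS) {
      sol <- optimize_flux_at_growth(cmk, c(S = fS, A = 1 - fS), 1,
                                     "EX_Glc_x", sense = "max")
      if (sol$status == "optimal") -sol$objective_value else NA_real_
    })
    min(vals, na.rm = TRUE)
  })
  got <- tidy(sr)$min_uptake[match(cands, tidy(sr)$metabolite)]
  expect_identical(order(got), order(brute))
  # the brute grid is itself only resolution-accurate
  expect_true(all(abs(got - brute) < 5e-3))
})
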