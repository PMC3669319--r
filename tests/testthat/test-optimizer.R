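test_that("simplex grid is uniform, complete and on the simplex", {
  G2 <- cfba:::simplex_grid(2, 0.25)
  expect_equal(nrow(G2), 5)
  expect_true(all(abs(rowSums(G2) - 1) < 1e-12))
  G3 <- cfba:::simplex_grid(3, 0.25)
  expect_equal(nrow(G3), choose(4 + 2, 2))
  expect_true(all(G3 >= 0) && all(abs(rowSums(G3) - 1) < 1e-12))
  expect_equal(nrow(cfba:::simplex_grid(1, 0.1)), 1)
})

test_that("obligate pair is infeasible or non-growing at the simplex corners", {
  sc <- scan_fractions(mini_pair(), resolution = 0.1)
  g <- sc$grid
  corner0 <- g[g$f_a == 0, ]
  corner1 <- g[g$f_a == 1, ]
  expect_true(is.na(corner0$mu) || corner0$mu < 1e-9)
  expect_true(is.na(corner1$mu) || corner1$mu < 1e-9)
  expect_gt(sc$mu_max, 0)  # interior compositions grow
})

test_that("single-species scan collapses to the classical FBA optimum", {
  cm <- single_species_community(0.1, 10)
  sc <- scan_fractions(cm, resolution = 0.1)
  expect_equal(nrow(sc$grid), 1)
  expect_close(sc$mu_max, 1, 1e-9)
})

test_that("grid refinement never lowers the scan maximum", {
  cm <- toy_consortium()
  coarse <- scan_fractions(cm, 0.1)
  fine <- scan_fractions(cm, 0.05)  # nested grid
  expect_gte(fine$mu_max, coarse$mu_max - 1e-12)
  opt <- optimize_community(cm, coarse_resolution = 0.1, refine_tol = 1e-4)
  expect_gte(opt$mu_max, coarse$mu_max - 1e-12)
})

test_that("refined optimum matches a brute-force fine scan on the mini pair", {
  cm <- mini_pair(tx_ub = 2, ty_ub = 3)  # kinked landscape
  opt <- optimize_community(cm, coarse_resolution = 0.05, refine_tol = 1e-5)
  brute <- scan_fractions(cm, resolution = 0.001)
  expect_gte(opt$mu_max, brute$mu_max - 1e-7)
  # the brute grid itself is only accurate to its spacing times the slope
  expect_lte(abs(opt$mu_max - brute$mu_max), 5e-3)
})

test_that("symmetric pair has a symmetric growth landscape and optimum", {
  cm <- symmetric_pair()
  sc <- scan_fractions(cm, 0.1)
  g <- sc$grid
  for (k in seq_len(nrow(g))) {
    mirror <- g$mu[abs(g$f_alpha - (1 - g$f_alpha[k])) < 1e-12]
    expect_close(g$mu[k], mirror, 1e-8)
  }
  opt <- optimize_community(cm, 0.1, 1e-4)
  expect_close(opt$mu_max, mu_at(cm, c(alpha = 0.5, beta = 0.5)), 1e-6)
})

test_that("all-infeasible community is reported as such", {
  # force infeasibility: impossible maintenance with no usable source
  cm <- set_flux_bound(toy_consortium(), "EX_Glc_x", lb = 0, ub = 0)
  opt <- optimize_community(cm, 0.25, 1e-3)
  expect_identical(opt$status, "infeasible")
  expect_true(is.na(opt$mu_max))
  expect_error(optimal_fraction_region(cm, scan_fractions(cm, 0.25)), "infeasible")
})

test_that("optimal region: plateau wide for unconstrained, shrinking for critical", {
  sc_inf <- scan_fractions(toy_scenario("infinite"), 0.02)
  reg_inf <- optimal_fraction_region(toy_scenario("infinite"), sc_inf, tol = 1e-6)
  expect_equal(nrow(reg_inf), 1)
  expect_gt(reg_inf$f_hi - reg_inf$f_lo, 0.05)

  cm_crit <- toy_scenario("critical")
  sc_crit <- scan_fractions(cm_crit, 0.02)
  w <- purrr::map_dbl(c(0.05, 1e-3), function(tol) {
    r <- optimal_fraction_region(cm_crit, sc_crit, tol = tol)
    sum(r$f_hi - r$f_lo)
  })
  expect_lt(w[2], w[1])          # region shrinks as tol shrinks
  expect_lt(w[2], 0.02)          # and collapses towards a point
  # argmax lies inside the near-optimal region
  r <- optimal_fraction_region(cm_crit, sc_crit, tol = 1e-3)
  am <- sc_crit$argmax[["i"]]
  expect_true(any(am >= r$f_lo - 1e-9 & am <= r$f_hi + 1e-9))
})

test_that("biomass-ratio scan is the fraction scan under a change of variables", {
  cm <- mini_pair()
  ratios <- c(0.25, 1, 4)
  rs <- scan_biomass_ratio(cm, ratios, numerator = "b")
  expect_equal(rs$grid$f_b, ratios / (1 + ratios))
  expect_true(all(diff(rs$grid$f_b) > 0))  # monotone grids map monotonically
  for (k in seq_along(ratios)) {
    fb <- ratios[k] / (1 + ratios[k])
    expect_close(rs$grid$mu[k], mu_at(cm, c(a = 1 - fb, b = fb)), 1e-9)
  }
  expect_error(scan_biomass_ratio(cm, c(-1, 1)), "positive")
  expect_error(scan_biomass_ratio(single_species_community(), 1), "2 species")
})

test_that("two-species growth curve is continuous and locally near-linear", {
  # dense samples against linear interpolation of a coarser grid: the
  # curve is piecewise smooth (linear or gently hyperbolic segments), so
  # interpolation error stays tiny and no jumps occur inside the
  # feasible region
  cm <- toy_consortium()
  f_coarse <- seq(0.1, 0.95, by = 0.01)
  mu_coarse <- purrr::map_dbl(f_coarse, function(x) mu_at(cm, c(i = x, j = 1 - x)))
  f_dense <- seq(0.105, 0.945, by = 0.005)
  mu_dense <- purrr::map_dbl(f_dense, function(x) mu_at(cm, c(i = x, j = 1 - x)))
  interp <- stats::approx(f_coarse, mu_coarse, xout = f_dense)$y
  expect_true(all(is.finite(mu_dense)))
  err <- abs(mu_dense - interp)
  # near-zero interpolation error along the segments; only the few dense
  # points straddling a kink (slope change ~ grid/4) may deviate
  expect_lt(unname(stats::quantile(err, 0.95)), 2e-3)
  expect_lt(sum(err > 2e-3), 6)
  expect_lt(max(err), 0.05)
  expect_lt(max(abs(diff(mu_dense))), 0.2)  # no jumps at this spacing
})
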