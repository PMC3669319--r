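test_that("community of one reduces to classical FBA with a closed-form optimum", {
  cm <- single_species_community(yield_coeff = 0.1, uptake_bound = 1)
  sol <- maximize_growth_at_fractions(cm, c(m1 = 1))
  expect_identical(sol$status, "optimal")
  # biomass needs 10 mmol precursor per gDW, uptake capped at 1 => mu = 0.1
  expect_close(sol$mu, 0.1, 1e-9)
  expect_close(oracle_fba(cm)$mu, sol$mu, 1e-9)
  # all balances hold
  expect_true(all(abs(build_lp(cm, c(m1 = 1))$A %*%
                        stats::setNames(sol$fluxes$value, sol$fluxes$flux)[
                          build_lp(cm, c(m1 = 1))$var_ids]) < 1e-8))
})

test_that("fraction weights scale species columns but not exchange columns", {
  cm <- mini_pair()
  spec_half <- build_lp(cm, c(a = 0.5, b = 0.5))
  spec_full <- build_lp(cm, c(a = 1, b = 0))
  qa <- "a.t_s"
  row <- "a__A"
  expect_close(spec_half$A[row, qa], 0.5 * spec_full$A[row, qa], 1e-12)
  ex_row <- "S_x"
  expect_close(spec_half$A[ex_row, "EX_S_x"], spec_full$A[ex_row, "EX_S_x"], 1e-12)
  # mu column aggregates f-weighted biomass compositions
  expect_close(spec_half$A["a__A", "mu"], 0.5 * -1, 1e-12)
})

test_that("fixing mu moves the growth column to the right-hand side", {
  cm <- mini_pair()
  spec <- build_lp(cm, c(a = 0.5, b = 0.5),
                   objective = list(sense = "min", flux = "EX_S_x"),
                   fixed_mu = 0.2)
  expect_false("mu" %in% spec$var_ids)
  # rhs on species a's precursor row equals -f_a * c_A * mu = 0.5 * 1 * 0.2
  expect_close(spec$b[match("a__A", rownames(spec$A))], 0.5 * 1 * 0.2, 1e-12)
})

test_that("maximising mu with no finite bound anywhere is refused", {
  cm <- single_species_community()
  cm$cols$lb <- ifelse(cm$cols$lb < 0, -Inf, cm$cols$lb)
  cm$cols$ub <- Inf
  cm$exchanges$phi_lb <- -Inf
  cm$exchanges$phi_ub <- Inf
  expect_error(build_lp(cm, c(m1 = 1)), "unbounded by construction")
})

test_that("broken mutualism pins the community growth rate at zero", {
  cm <- set_flux_bound(mini_pair(), "b.t_y", ub = 0)
  sol <- maximize_growth_at_fractions(cm, c(a = 0.5, b = 0.5))
  expect_identical(sol$status, "optimal")
  expect_close(sol$mu, 0, 1e-9)
  cm2 <- set_flux_bound(toy_consortium(), "j.t_nh3", ub = 0)
  # maintenance cannot be met without the partner at interior fractions
  sol2 <- maximize_growth_at_fractions(cm2, c(i = 0.5, j = 0.5))
  expect_true(sol2$status == "infeasible" ||
                (sol2$status == "optimal" && sol2$mu < 1e-9))
})

test_that("fixed-fraction LP optimum equals vertex enumeration on the mini pair", {
  cm <- mini_pair()
  set.seed(23)
  checked <- 0
  for (k in 1:20) {
    fa <- runif(1, 0.05, 0.95)
    f <- c(a = fa, b = 1 - fa)
    spec <- build_lp(cm, f)
    got <- cfba:::lp_solve(spec)
    want <- oracle_solve_spec(spec)
    expect_identical(got$status, want$status)
    if (got$status == "optimal") {
      expect_close(got$objective, want$objective, 1e-7)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 15)
})

test_that("flux optimisation at fixed growth matches the oracle and respects mu*", {
  cm <- mini_pair()
  f <- c(a = 0.4, b = 0.6)
  mu_star <- mu_at(cm, f)
  expect_gt(mu_star, 0)
  # infeasible just above the optimum
  sol_hi <- optimize_flux_at_growth(cm, f, mu_star * 1.001, "EX_S_x", "min")
  expect_identical(sol_hi$status, "infeasible")
  # minimised uptake at half the optimum, against the oracle
  spec <- build_lp(cm, f, objective = list(sense = "min", flux = "EX_S_x"),
                   fixed_mu = 0.5 * mu_star)
  got <- cfba:::lp_solve(spec)
  want <- oracle_solve_spec(spec)
  expect_close(got$objective, want$objective, 1e-7)
  # single-species closed form: min uptake at mu is mu / yield
  cm1 <- single_species_community(yield_coeff = 0.1, uptake_bound = 10)
  sol <- optimize_flux_at_growth(cm1, c(m1 = 1), 0.5, "m1.t_S", "min")
  expect_close(sol$objective_value, 0.5 / 0.1, 1e-8)
})

test_that("steady-state residuals and bounds hold at every reported optimum", {
  cm <- toy_consortium()
  for (fa in c(0.1, 0.4, 0.7, 0.9)) {
    f <- c(i = fa, j = 1 - fa)
    sol <- maximize_growth_at_fractions(cm, f)
    expect_identical(sol$status, "optimal")
    spec <- build_lp(cm, f)
    x <- stats::setNames(sol$fluxes$value, sol$fluxes$flux)[spec$var_ids]
    expect_lt(max(abs(spec$A %*% x - spec$b)), 1e-8)
    expect_true(all(x >= spec$lb - 1e-9 & x <= spec$ub + 1e-9))
  }
})

test_that("scaling a binding uptake bound scales mu* until another bound binds", {
  for (alpha in c(0.5, 2, 10)) {
    base <- single_species_community(yield_coeff = 0.1, uptake_bound = 2)
    scaled <- single_species_community(yield_coeff = 0.1, uptake_bound = 2 * alpha)
    expect_close(mu_at(scaled, c(m1 = 1)), alpha * mu_at(base, c(m1 = 1)), 1e-8)
  }
  # yield invariance: mu*/phi_limiting constant under the same scaling
  yields <- purrr::map_dbl(c(1, 2), function(alpha) {
    cm <- single_species_community(0.1, 2 * alpha)
    sol <- maximize_growth_at_fractions(cm, c(m1 = 1))
    phi <- sol$fluxes$value[sol$fluxes$flux == "EX_S_x"]
    sol$mu / abs(phi)
  })
  expect_close(yields[1], yields[2], 1e-9)
  # a deliberately finite second bound truncates the scaling
  cm_cap <- single_species_community(yield_coeff = 0.1, uptake_bound = 20)
  cm_cap <- set_flux_bound(cm_cap, "m1.ana", ub = 10)  # precursor flux cap
  expect_close(mu_at(cm_cap, c(m1 = 1)), 1, 1e-8)  # 10 * 0.1, not 20 * 0.1
})

test_that("flux ranges are tight for unique optima and widen under degeneracy", {
  cm <- single_species_community(0.1, 10)
  fr <- flux_ranges_at_optimum(cm, c(m1 = 1))
  expect_true(all(fr$hi - fr$lo < 1e-7))
  expect_true(all(fr$incumbent >= fr$lo - 1e-7 & fr$incumbent <= fr$hi + 1e-7))

  # duplicate the uptake transporter: individual ranges widen, sum is fixed
  sp <- cm$species$m1
  rx <- sp$reactions
  dup <- tibble::tibble(id = "t_S2", kind = "unique_transport",
                        equation = "S_x -> S", lb = 0, ub = rx$ub[rx$id == "t_S"])
  sp2 <- species_model("m1", sp$metabolites, dplyr::bind_rows(rx[, names(dup)], dup))
  cm2 <- assemble_community(list(sp2), character(0),
                            env_exchanges = tibble::tibble(
                              metabolite_id = "S_x", J_lb = -10, J_ub = 0))
  fr2 <- flux_ranges_at_optimum(cm2, c(m1 = 1))
  w1 <- fr2$hi[fr2$flux == "m1.t_S"] - fr2$lo[fr2$flux == "m1.t_S"]
  expect_gt(w1, 1)  # the pair can trade the full uptake between them
  expect_close(mu_at(cm2, c(m1 = 1)), mu_at(cm, c(m1 = 1)), 1e-8)
})

test_that("extra linear constraints across species are honoured", {
  cm <- mini_pair()
  f <- c(a = 0.5, b = 0.5)
  free_mu <- mu_at(cm, f)
  # cap species a's uptake at a fraction of its optimum level
  sol0 <- maximize_growth_at_fractions(cm, f)
  q0 <- sol0$fluxes$value[sol0$fluxes$flux == "a.t_s"]
  ec <- list(list(terms = c(`a.t_s` = 1), sense = "<=", rhs = q0 / 2))
  capped <- mu_at(cm, f, extra_constraints = ec)
  expect_close(capped, free_mu / 2, 1e-8)
  expect_error(
    maximize_growth_at_fractions(cm, f, extra_constraints = list(
      list(terms = c(nope = 1), sense = "<=", rhs = 0))),
    "unknown flux")
})
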