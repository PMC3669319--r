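test_that("two disjoint species assemble block-diagonally with exchange columns", {
  mk <- function(id, sub) {
    species_model(id,
      tibble::tibble(id = c("P", sub), role = c("intracellular", "unique")),
      tibble::tibble(id = c("t", "growth"),
                     kind = c("unique_transport", "biomass"),
                     equation = c(sprintf("%s -> P", sub), "1 P ->"),
                     lb = 0, ub = c(5, 1000)))
  }
  cm <- assemble_community(list(mk("u", "Su_x"), mk("v", "Sv_x")),
                           crossfed_ids = character(0),
                           env_exchanges = tibble::tibble(
                             metabolite_id = c("Su_x", "Sv_x"),
                             J_lb = -5, J_ub = 0))
  expect_equal(nrow(cm$C), 2 + 2)  # one intracellular row each + 2 unique ext rows
  expect_equal(ncol(cm$C), 2 + 2 + 2)  # q cols + biomass cols + exchange cols
  # no row is shared: species blocks do not overlap
  expect_equal(sum(abs(cm$C["u__P", c("v.t", "v.growth")])), 0)
  expect_equal(sum(abs(cm$C["v__P", c("u.t", "u.growth")])), 0)
})

test_that("cross-fed rows merge producer, consumer and one overflow exchange", {
  cm <- toy_consortium()
  succ_row <- cm$C["Succ_x", ]
  nz <- names(succ_row)[succ_row != 0]
  expect_setequal(nz, c("i.t_succ", "j.t_succ", "EX_Succ_x"))
  expect_gt(succ_row[["i.t_succ"]], 0)  # production by i
  expect_lt(succ_row[["j.t_succ"]], 0)  # consumption by j
  expect_equal(succ_row[["EX_Succ_x"]], -1)  # export-positive overflow
  # overflow exchanges are efflux-only by default
  ex <- cm$exchanges[cm$exchanges$metabolite == "Succ_x", ]
  expect_equal(ex$phi_lb, 0)
  expect_gt(ex$phi_ub, 0)
})

test_that("conservation of stoichiometric content into C", {
  cm <- toy_consortium()
  n_from_species <- sum(purrr::map_int(cm$species, function(s) {
    Matrix::nnzero(s$N) + sum(s$c != 0)
  }))
  n_exchange <- nrow(cm$exchanges)
  expect_equal(Matrix::nnzero(cm$C), n_from_species + n_exchange)
})

test_that("assembly is order-invariant up to permutation", {
  cm1 <- toy_consortium()
  cm2 <- assemble_community(rev(unname(cm1$species)),
                            crossfed_ids = cm1$crossfed_ids,
                            env_exchanges = tibble::tibble(
                              metabolite_id = cm1$exchanges$metabolite,
                              J_lb = cm1$exchanges$J_lb,
                              J_ub = cm1$exchanges$J_ub)[
                                cm1$exchanges$metabolite %in%
                                  c("Glc_x", "N2_x", "CO2j_x"), ],
                            X_T = cm1$X_T)
  expect_equal(Matrix::nnzero(cm1$C), Matrix::nnzero(cm2$C))
  # same rows/cols as sets, and identical entries under the name matching
  expect_setequal(rownames(cm1$C), rownames(cm2$C))
  expect_setequal(colnames(cm1$C), colnames(cm2$C))
  expect_equal(as.matrix(cm2$C)[rownames(cm1$C), colnames(cm1$C)],
               as.matrix(cm1$C))
  # identical downstream optimum
  f <- c(i = 0.6, j = 0.4)
  expect_close(mu_at(cm1, f), mu_at(cm2, f), 1e-9)
})

test_that("misdeclared shared metabolites and exchanges are rejected", {
  mk <- function(id) {
    species_model(id,
      tibble::tibble(id = c("P", "Z_x"), role = c("intracellular", "unique")),
      tibble::tibble(id = c("t", "growth"),
                     kind = c("unique_transport", "biomass"),
                     equation = c("Z_x -> P", "1 P ->"), lb = 0, ub = 1000))
  }
  expect_error(assemble_community(list(mk("u"), mk("v")), character(0)),
               "crossfed")
  cm <- toy_consortium()
  expect_error(assemble_community(cm$species, cm$crossfed_ids,
                                  env_exchanges = tibble::tibble(
                                    metabolite_id = "G", J_lb = 0, J_ub = 1)),
               "intracellular|unknown")
  expect_error(assemble_community(unname(cm$species), c("Succ_x", "NH3_x", "Nope_x")),
               "unknown to every species")
})

test_that("validator flags dead ends and elemental imbalance, passes the toy", {
  expect_true(community_ok(validate_community(toy_consortium())))

  # producer without consumer and with a shut exchange is a dead end
  sp <- species_model("p",
    tibble::tibble(id = c("A", "M_x"), role = c("intracellular", "crossfed")),
    tibble::tibble(id = c("mk", "t", "growth"),
                   kind = c("intracellular", "crossfeed_transport", "biomass"),
                   equation = c(" -> A", "A -> M_x", "1 A ->"),
                   lb = 0, ub = 1000))
  cm <- assemble_community(list(sp), "M_x",
                           env_exchanges = tibble::tibble(
                             metabolite_id = "M_x", J_lb = 0, J_ub = 0))
  rep <- validate_community(cm)
  expect_false(community_ok(rep))
  expect_true(any(rep$check == "dead_end" & rep$severity == "error"))

  # glucose -> 2 pyruvate without the missing hydrogens
  spb <- species_model("q",
    tibble::tibble(id = c("Glc", "Pyr", "S_x"),
                   role = c("intracellular", "intracellular", "unique"),
                   formula = c("C6H12O6", "C3H4O3", "C6H12O6")),
    tibble::tibble(id = c("t", "split", "growth"),
                   kind = c("unique_transport", "intracellular", "biomass"),
                   equation = c("S_x -> Glc", "Glc -> 2 Pyr", "1 Pyr ->"),
                   lb = 0, ub = 1000))
  cmb <- assemble_community(list(spb), character(0),
                            env_exchanges = tibble::tibble(
                              metabolite_id = "S_x", J_lb = -10, J_ub = 0))
  repb <- validate_community(cmb)
  imb <- repb[repb$check == "elemental_balance", ]
  expect_equal(nrow(imb), 1)
  expect_match(imb$message, "H")
})

test_that("set_flux_bound updates reaction and exchange bounds coherently", {
  cm <- toy_consortium()
  cm2 <- set_flux_bound(cm, "i.t_succ", ub = 3)
  expect_equal(cm2$cols$ub[cm2$cols$col == "i.t_succ"], 3)
  cm3 <- set_flux_bound(cm, "EX_Glc_x", lb = -4)
  expect_equal(cm3$exchanges$phi_lb[cm3$exchanges$ex_id == "EX_Glc_x"], -4)
  expect_equal(cm3$exchanges$J_lb[cm3$exchanges$ex_id == "EX_Glc_x"], -4 * cm$X_T)
  expect_error(set_flux_bound(cm, "nope"), "unknown flux")
  expect_error(set_flux_bound(cm, "i.t_succ", lb = 2, ub = 1), "lb exceeds ub")
})
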