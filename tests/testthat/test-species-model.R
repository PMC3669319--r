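test_that("equation parser handles coefficients, repeats and empty sides", {
  expect_equal(cfba:::parse_equation("1 A + 2 B -> 1.5 C"),
               c(A = -1, B = -2, C = 1.5))
  expect_equal(cfba:::parse_equation("A -> "), c(A = -1))
  expect_equal(cfba:::parse_equation("A + A -> B"), c(A = -2, B = 1))
  # species on both sides net out
  expect_equal(cfba:::parse_equation("2 A -> A + B"), c(A = -1, B = 1))
  expect_error(cfba:::parse_equation("A - B"), "->")
  expect_error(cfba:::parse_equation("A -> A"), "no net stoichiometry")
  # format/parse round trip
  st <- c(G = -1, P = 2, ATP = 2)
  expect_equal(cfba:::parse_equation(cfba:::format_equation(st))[names(st)], st)
})

test_that("formula parser counts elements", {
  expect_equal(cfba:::parse_formula("C6H12O6")[c("C", "H", "O")],
               c(C = 6, H = 12, O = 6))
  expect_equal(unname(cfba:::parse_formula("N")), 1)
  expect_null(cfba:::parse_formula(NA))
  expect_error(cfba:::parse_formula("6C"), "cannot parse")
})

test_that("species model builds with four lumped processes plus transports", {
  cm <- toy_consortium()
  sp <- cm$species$i
  expect_s3_class(sp, "species_model")
  expect_equal(sum(sp$reactions$kind == "intracellular"), 5)  # 4 processes + maintenance
  expect_equal(sum(sp$reactions$kind == "biomass"), 1)
  expect_equal(ncol(sp$N), nrow(sp$reactions) - 1)  # biomass not a flux column
  expect_lt(sp$c[["B"]], 0)  # biomass consumes precursor
})

test_that("minimal chain model is valid and degenerate models error", {
  mets <- tibble::tibble(id = c("S_x", "P"), role = c("unique", "intracellular"))
  rxns <- tibble::tibble(id = c("t", "growth"),
                         kind = c("unique_transport", "biomass"),
                         equation = c("S_x -> P", "1 P ->"),
                         lb = 0, ub = c(10, 1000))
  sm <- species_model("m", mets, rxns)
  expect_equal(ncol(sm$N), 1)

  two_bm <- dplyr::bind_rows(rxns, tibble::tibble(
    id = "growth2", kind = "biomass", equation = "1 P ->", lb = 0, ub = 1000))
  expect_error(species_model("m", mets, two_bm), "exactly one biomass")
  expect_error(species_model("m", mets[1, ], rxns), "unknown metabolite")
  expect_error(species_model("m", mets, dplyr::mutate(rxns, id = c("t", "t"))),
               "duplicated reaction")
  bad_kind <- dplyr::mutate(rxns, kind = c("intracellular", "biomass"))
  expect_error(species_model("m", mets, bad_kind), "extracellular")
})

test_that("partition tiles the species matrix exactly and unpartitions back", {
  cm <- toy_consortium()
  for (sp in cm$species) {
    pm <- partition_species_matrix(sp)
    # cross-feeding transports land in the cross-feeding block
    cf_cols <- sp$reactions$id[sp$reactions$kind == "crossfeed_transport"]
    expect_true(all(cf_cols %in% colnames(pm$N_IC)))
    expect_identical(colnames(pm$N_IC), colnames(pm$N_CC))
    # every nonzero of N falls in exactly one informative block
    nnz_blocks <- sum(Matrix::nnzero(pm$N_II), Matrix::nnzero(pm$N_IC),
                      Matrix::nnzero(pm$N_IT), Matrix::nnzero(pm$N_CC),
                      Matrix::nnzero(pm$N_UU))
    expect_equal(nnz_blocks, Matrix::nnzero(sp$N))
    expect_equal(as.matrix(unpartition_matrix(pm)), as.matrix(sp$N))
  }
})

test_that("model with no cross-fed metabolites partitions to a pure intracellular block", {
  cm <- single_species_community()
  pm <- partition_species_matrix(cm$species$m1)
  expect_equal(ncol(pm$N_IC), 0)
  expect_equal(nrow(pm$N_CC), 0)
  expect_equal(Matrix::nnzero(pm$N_II) + Matrix::nnzero(pm$N_IT) + Matrix::nnzero(pm$N_UU),
               Matrix::nnzero(cm$species$m1$N))
})
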