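#' Parameters of the obligate mutualistic toy consortium
#'
#' Frozen coarse-grained parameterisation of a two-species cross-feeding
#' pair: species `i` consumes glucose and ammonium and exports succinate;
#' species `j` consumes succinate, fixes dinitrogen and exports ammonium.
#' Each species runs four lumped intracellular processes — catabolism,
#' respiration, product formation (succinate export path in `i`, nitrogen
#' fixation in `j`) and anabolism — plus membrane transports, an ATP
#' maintenance drain, and a biomass reaction. Carbon and nitrogen are
#' tracked with pseudo-element formulas (glucose C6, pyruvate-like
#' precursor C3, succinate C4, biomass precursor C3N) so every lumped
#' reaction is elementally balanced; ATP is a massless energy token.
#'
#' The defaults are chosen, once, to make the community obligately
#' mutualistic and to display the canonical limitation regimes when
#' cross-feeding bounds are varied: neither species grows alone (`i` has no
#' nitrogen source without `j`; `j` has no carbon source without `i`), the
#' ATP maintenance drain makes compositions too poor in one partner
#' infeasible rather than merely non-growing, and the finite specific
#' glucose-uptake capacity of `i` makes the environmental glucose influx
#' the binding constraint only at sufficiently high abundance of `i`.
#'
#' @param glc_influx Absolute environmental glucose supply, mmol h^-1
#'   (uptake bound on the glucose exchange).
#' @param n2_influx Absolute dinitrogen supply, mmol h^-1 (effectively
#'   unlimited by default).
#' @param glc_uptake_cap Specific glucose-uptake capacity of species `i`,
#'   mmol gDW^-1 h^-1.
#' @param succ_prod_cap Specific succinate-export capacity of species `i`
#'   (the first cross-feeding bound; `Inf`-like 1000 = unconstrained).
#' @param nh3_prod_cap Specific ammonium-export capacity of species `j`
#'   (the second cross-feeding bound).
#' @param succ_uptake_cap Specific succinate-uptake capacity of species
#'   `j`; capping it lowers the attainable growth rate of `j` uniformly,
#'   independent of composition.
#' @param atp_maintenance Non-growth ATP demand of each species,
#'   mmol ATP gDW^-1 h^-1 (a hard lower bound).
#' @param ana_cap Specific anabolism capacity of each species,
#'   mmol precursor gDW^-1 h^-1; caps the attainable growth rate
#'   independently of the community composition.
#' @param biomass_atp ATP cost of biomass synthesis, mmol gDW^-1.
#' @param X_T Total community biomass, gDW.
#' @return A named list of parameters for [toy_consortium()].
#' @export
toy_params <- function(glc_influx = 10,
                       n2_influx = 1000,
                       glc_uptake_cap = 20,
                       succ_prod_cap = 1000,
                       nh3_prod_cap = 1000,
                       succ_uptake_cap = 1000,
                       atp_maintenance = 10,
                       ana_cap = 4,
                       biomass_atp = 10,
                       X_T = 1) {
  list(glc_influx = glc_influx, n2_influx = n2_influx,
       glc_uptake_cap = glc_uptake_cap,
       succ_prod_cap = succ_prod_cap, nh3_prod_cap = nh3_prod_cap,
       succ_uptake_cap = succ_uptake_cap,
       atp_maintenance = atp_maintenance, ana_cap = ana_cap,
       biomass_atp = biomass_atp, X_T = X_T)
}

#' Obligate mutualistic two-species toy consortium
#'
#' Builds the coarse-grained cross-feeding pair described in
#' [toy_params()] and assembles it into a community model with succinate
#' and ammonium as the cross-fed metabolites (overflow to the environment
#' allowed, supply not), glucose and dinitrogen supplied by the
#' environment, and CO2 leaving freely.
#'
#' @param params Parameter list from [toy_params()].
#' @param obligate If `TRUE` (default), error if a parameter choice makes
#'   either species independently viable.
#' @return A `community_model` with species `"i"` (glucose consumer) and
#'   `"j"` (succinate consumer / nitrogen fixer).
#' @examples
#' cm <- toy_consortium()
#' maximize_growth_at_fractions(cm, c(i = 0.7, j = 0.3))$mu
#' @export
toy_consortium <- function(params = toy_params(), obligate = TRUE) {
  p <- params
  stopifnot(all(map_lgl(p, function(v) is.numeric(v) && length(v) == 1)))
  if (any(unlist(p) < 0)) abort("toy consortium parameters must be non-negative")

  mets_i <- tibble(
    id      = c("G", "P", "S4", "NH", "B", "W", "ATP",
                "Glc_x", "Succ_x", "NH3_x", "CO2i_x"),
    role    = c(rep("intracellular", 7),
                "unique", "crossfed", "crossfed", "unique"),
    formula = c("C6", "C3", "C4", "N", "C3N", "C", NA,
                "C6", "C4", "N", "C"))
  rxns_i <- tibble(
    id       = c("cat", "res", "pro", "ana", "maint",
                 "t_glc", "t_succ", "t_nh3", "t_co2", "growth"),
    kind     = c(rep("intracellular", 5),
                 "unique_transport", "crossfeed_transport", "crossfeed_transport",
                 "unique_transport", "biomass"),
    equation = c("G -> 2 P + 2 ATP",
                 "P -> 3 W + 8 ATP",
                 "1.5 P -> S4 + 0.5 W",
                 "P + NH + 6 ATP -> B",
                 "ATP ->",
                 "Glc_x -> G",
                 "S4 -> Succ_x",
                 "NH3_x -> NH",
                 "W -> CO2i_x",
                 sprintf("1 B + %g ATP ->", p$biomass_atp)),
    lb = c(0, 0, 0, 0, p$atp_maintenance, 0, 0, 0, 0, 0),
    ub = c(1000, 1000, 1000, p$ana_cap, 1000,
           p$glc_uptake_cap, p$succ_prod_cap, 1000, 1000, 1000))
  sp_i <- species_model("i", mets_i, rxns_i)

  mets_j <- tibble(
    id      = c("S", "P", "N2", "NH", "B", "W", "ATP",
                "Succ_x", "NH3_x", "N2_x", "CO2j_x"),
    role    = c(rep("intracellular", 7),
                "crossfed", "crossfed", "unique", "unique"),
    formula = c("C4", "C3", "N2", "N", "C3N", "C", NA,
                "C4", "N", "N2", "C"))
  rxns_j <- tibble(
    id       = c("cat", "res", "fix", "ana", "maint",
                 "t_succ", "t_n2", "t_nh3", "t_co2", "growth"),
    kind     = c(rep("intracellular", 5),
                 "crossfeed_transport", "unique_transport", "crossfeed_transport",
                 "unique_transport", "biomass"),
    equation = c("S -> P + W + 1.5 ATP",
                 "P -> 3 W + 8 ATP",
                 "N2 + 8 ATP -> 2 NH",
                 "P + NH + 6 ATP -> B",
                 "ATP ->",
                 "Succ_x -> S",
                 "N2_x -> N2",
                 "NH -> NH3_x",
                 "W -> CO2j_x",
                 sprintf("1 B + %g ATP ->", p$biomass_atp)),
    lb = c(0, 0, 0, 0, p$atp_maintenance, 0, 0, 0, 0, 0),
    ub = c(1000, 1000, 1000, p$ana_cap, 1000,
           p$succ_uptake_cap, 1000, p$nh3_prod_cap, 1000, 1000))
  sp_j <- species_model("j", mets_j, rxns_j)

  cm <- assemble_community(
    list(sp_i, sp_j),
    crossfed_ids = c("Succ_x", "NH3_x"),
    env_exchanges = tibble(
      metabolite_id = c("Glc_x", "N2_x", "CO2j_x"),
      J_lb = c(-p$glc_influx, -p$n2_influx, 0),
      J_ub = c(1000 * p$X_T, 1000 * p$X_T, 1000 * p$X_T)),
    X_T = p$X_T)

  if (obligate) {
    for (sp in cm$species_ids) {
      f <- stats::setNames(as.numeric(cm$species_ids == sp), cm$species_ids)
      sol <- maximize_growth_at_fractions(cm, f)
      if (sol$status == "optimal" && sol$mu > 1e-9) {
        abort(sprintf("parameters make species '%s' independently viable; not an obligate pair", sp))
      }
    }
  }
  cm
}

#' Single-species community with a closed-form optimum
#'
#' One organism converting an external substrate into biomass through a
#' single precursor: uptake bound `uptake_bound` (mmol gDW^-1 h^-1, also
#' the environmental supply), biomass needing `1 / yield_coeff` mmol of
#' precursor per gram. The maximal growth rate is analytically
#' `uptake_bound * yield_coeff`, which makes this the reference fixture
#' for equivalence with classical single-species FBA and for the
#' bound-scaling law.
#'
#' @param yield_coeff Biomass yield, gDW per mmol substrate.
#' @param uptake_bound Specific substrate uptake capacity,
#'   mmol gDW^-1 h^-1.
#' @param species_id Species name (default `"m1"`).
#' @param X_T Total biomass, gDW.
#' @return A `community_model` with a single species.
#' @export
single_species_community <- function(yield_coeff = 0.1, uptake_bound = 10,
                                     species_id = "m1", X_T = 1) {
  stopifnot(yield_coeff > 0, uptake_bound >= 0)
  mets <- tibble(
    id = c("S", "B", "S_x"),
    role = c("intracellular", "intracellular", "unique"),
    formula = c(NA_character_, NA_character_, NA_character_))
  rxns <- tibble(
    id = c("t_S", "ana", "growth"),
    kind = c("unique_transport", "intracellular", "biomass"),
    equation = c("S_x -> S", "S -> B",
                 sprintf("%.12g B ->", 1 / yield_coeff)),
    lb = 0,
    ub = c(uptake_bound, 1000 * max(1, uptake_bound), 1000))
  sp <- species_model(species_id, mets, rxns)
  assemble_community(
    list(sp), crossfed_ids = character(0),
    env_exchanges = tibble(metabolite_id = "S_x",
                           J_lb = -uptake_bound * X_T,
                           J_ub = 0),
    X_T = X_T)
}

#' Random feasible N-species chain community
#'
#' Deterministic (seeded) generator of producer-to-consumer chains:
#' species 1 consumes the environmental substrate and secretes metabolite
#' `M1`, species `k` consumes `M(k-1)` and secretes `Mk`; the final
#' product overflows to the environment. Yields and transport capacities
#' are drawn from the seeded RNG within ranges that keep every species'
#' biomass demand coverable at unit flux, so the community is feasible by
#' construction and the same seed reproduces the identical model.
#'
#' @param n_species Number of species (>= 1).
#' @param seed Integer seed fixing all randomness.
#' @return A `community_model` with species `sp1..spN`.
#' @export
random_community <- function(n_species, seed) {
  stopifnot(n_species >= 1, is.numeric(seed))
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(as.integer(seed))
    list(yield = stats::runif(n_species, 0.05, 0.5),
         uptake = stats::runif(n_species, 2, 20),
         conv = stats::runif(n_species, 0.3, 0.9))
  })
  species <- vector("list", n_species)
  for (k in seq_len(n_species)) {
    sub_id <- if (k == 1) "S0_x" else sprintf("M%d_x", k - 1)
    sub_role <- if (k == 1) "unique" else "crossfed"
    prod_id <- sprintf("M%d_x", k)
    prod_role <- if (k == n_species && n_species > 1) "unique" else
      if (n_species == 1) "unique" else "crossfed"
    # last species' product overflows; with one species it is just waste
    mets <- tibble(
      id = c("A", "B", sub_id, prod_id),
      role = c("intracellular", "intracellular", sub_role, prod_role),
      formula = NA_character_)
    rxns <- tibble(
      id = c("t_in", "conv", "t_out", "growth"),
      kind = c(if (k == 1) "unique_transport" else "crossfeed_transport",
               "intracellular",
               if (prod_role == "crossfed") "crossfeed_transport" else "unique_transport",
               "biomass"),
      equation = c(sprintf("%s -> A", sub_id),
                   sprintf("A -> %.12g B + %.12g A_rest", rng$conv[k], 1 - rng$conv[k]),
                   sprintf("A_rest -> %s", prod_id),
                   sprintf("%.12g B ->", 1 / rng$yield[k])),
      lb = 0, ub = c(rng$uptake[k], 1000, 1000, 1000))
    mets <- bind_rows(mets, tibble(id = "A_rest", role = "intracellular",
                                   formula = NA_character_))
    species[[k]] <- species_model(sprintf("sp%d", k), mets, rxns)
  }
  crossfed <- if (n_species > 1) sprintf("M%d_x", seq_len(n_species - 1)) else character(0)
  assemble_community(
    species, crossfed_ids = crossfed,
    env_exchanges = tibble(metabolite_id = "S0_x",
                           J_lb = -rng$uptake[1], J_ub = 0),
    X_T = 1)
}

#' Canonical cross-feeding limitation scenarios of the toy consortium
#'
#' Frozen parameter presets that put the toy pair into the four canonical
#' cross-feeding limitation regimes (see the methods vignette):
#' * `"infinite"` — cross-feeding unconstrained; the anabolism capacity
#'   sets a flat plateau of optimal compositions.
#' * `"critical"` — the ammonium-export cap of species `j` tuned so a
#'   unique composition attains the maximum.
#' * `"above_critical_1"`, `"above_critical_2"` — intermediate ammonium
#'   caps: the plateau value is still reached, but the cap cuts the
#'   plateau short where species `j` becomes scarce.
#' * `"below_critical"` — the succinate-uptake capacity of `j` capped, so
#'   the community plateaus at a growth rate below the unconstrained one.
#'
#' @param scenario Scenario name.
#' @return A `community_model` (as [toy_consortium()]).
#' @export
toy_scenario <- function(scenario = c("infinite", "critical",
                                      "above_critical_1", "above_critical_2",
                                      "below_critical")) {
  scenario <- match.arg(scenario)
  params <- switch(scenario,
    infinite = toy_params(),
    critical = toy_params(nh3_prod_cap = 2),
    above_critical_1 = toy_params(nh3_prod_cap = 5),
    above_critical_2 = toy_params(nh3_prod_cap = 8),
    below_critical = toy_params(succ_uptake_cap = 8))
  toy_consortium(params)
}

#' Two-species consortium with alternative cross-feeding carbon carriers
#'
#' Screen fixture: species `S` consumes environmental glucose but needs
#' ammonium; species `A` fixes dinitrogen and exports ammonium but cannot
#' take up glucose, so carbon must reach it through one of several
#' exported carriers. `S` can package carbon as an acetate-like (`Ac_x`),
#' ethanol-like (`Et_x`) or pyruvate-like (`Py_x`) metabolite, each with
#' different ATP economics on both sides, plus a lactate-like carrier
#' (`La_x`) that `A` has no transporter for (a structurally blocked
#' route). The fixture exists to exercise the one-at-a-time
#' cross-feeding-metabolite screen: at a fixed growth rate the minimal
#' glucose uptake differs between carriers, giving a strict efficiency
#' ranking.
#'
#' @param glc_influx Environmental glucose supply, mmol h^-1.
#' @param glc_uptake_cap Specific glucose-uptake capacity of `S`.
#' @param atp_maintenance Maintenance ATP demand of each species.
#' @return A `community_model` with species `"S"` and `"A"` and crossfed
#'   metabolites `NH3_x`, `Ac_x`, `Et_x`, `Py_x`, `La_x`.
#' @export
screen_consortium <- function(glc_influx = 10, glc_uptake_cap = 20,
                              atp_maintenance = 2) {
  mets_S <- tibble(
    id   = c("G", "P", "NH", "B", "W", "ATP", "Ac2", "Et2", "Py3", "La3",
             "Glc_x", "NH3_x", "Ac_x", "Et_x", "Py_x", "La_x", "CO2s_x"),
    role = c(rep("intracellular", 10),
             "unique", "crossfed", "crossfed", "crossfed", "crossfed",
             "crossfed", "unique"),
    formula = c("C6", "C3", "N", "C3N", "C", NA, "C2", "C2", "C3", "C3",
                "C6", "N", "C2", "C2", "C3", "C3", "C"))
  rxns_S <- tibble(
    id   = c("cat", "res", "ana", "maint",
             "mk_ac", "mk_et", "mk_py", "mk_la",
             "t_glc", "t_nh3", "t_ac", "t_et", "t_py", "t_la", "t_co2",
             "growth"),
    kind = c(rep("intracellular", 8),
             "unique_transport", rep("crossfeed_transport", 5),
             "unique_transport", "biomass"),
    equation = c("G -> 2 P + 2 ATP",
                 "P -> 3 W + 8 ATP",
                 "P + NH + 6 ATP -> B",
                 "ATP ->",
                 "P -> Ac2 + W + 2 ATP",
                 "P -> Et2 + W",
                 "P -> Py3",
                 "P -> La3",
                 "Glc_x -> G",
                 "NH3_x -> NH",
                 "Ac2 -> Ac_x",
                 "Et2 -> Et_x",
                 "Py3 -> Py_x",
                 "La3 -> La_x",
                 "W -> CO2s_x",
                 "1 B + 10 ATP ->"),
    lb = c(0, 0, 0, atp_maintenance, rep(0, 11), 0),
    ub = c(rep(1000, 8), glc_uptake_cap, rep(1000, 6), 1000))
  sp_S <- species_model("S", mets_S, rxns_S)

  mets_A <- tibble(
    id   = c("P", "N2", "NH", "B", "W", "ATP", "Ac2", "Et2", "Py3",
             "NH3_x", "Ac_x", "Et_x", "Py_x", "N2_x", "CO2a_x"),
    role = c(rep("intracellular", 9),
             "crossfed", "crossfed", "crossfed", "crossfed", "unique", "unique"),
    formula = c("C3", "N2", "N", "C3N", "C", NA, "C2", "C2", "C3",
                "N", "C2", "C2", "C3", "N2", "C"))
  rxns_A <- tibble(
    id   = c("use_ac", "use_et", "use_py", "res", "fix", "ana", "maint",
             "t_ac", "t_et", "t_py", "t_nh3", "t_n2", "t_co2", "growth"),
    kind = c(rep("intracellular", 7),
             rep("crossfeed_transport", 4), "unique_transport",
             "unique_transport", "biomass"),
    equation = c("2 Ac2 -> P + W + 3 ATP",
                 "2 Et2 -> P + W + 5 ATP",
                 "Py3 -> P + 2 ATP",
                 "P -> 3 W + 8 ATP",
                 "N2 + 8 ATP -> 2 NH",
                 "P + NH + 6 ATP -> B",
                 "ATP ->",
                 "Ac_x -> Ac2",
                 "Et_x -> Et2",
                 "Py_x -> Py3",
                 "NH -> NH3_x",
                 "N2_x -> N2",
                 "W -> CO2a_x",
                 "1 B + 10 ATP ->"),
    lb = c(rep(0, 6), atp_maintenance, rep(0, 6), 0),
    ub = rep(1000, 14))
  sp_A <- species_model("A", mets_A, rxns_A)

  assemble_community(
    list(sp_S, sp_A),
    crossfed_ids = c("NH3_x", "Ac_x", "Et_x", "Py_x", "La_x"),
    env_exchanges = tibble(
      metabolite_id = c("Glc_x", "N2_x"),
      J_lb = c(-glc_influx, -1000),
      J_ub = c(1000, 1000)),
    X_T = 1)
}
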