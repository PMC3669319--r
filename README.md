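# cfba — community flux balance analysis at balanced growth

Microbial consortia that cross-feed — one member's waste is another's
substrate — settle, under constant conditions, into *balanced growth*:
every member grows at the same specific rate μ, and every metabolite
pool, inside any cell or in the shared environment, is at steady state.
`cfba` predicts the complete state of such a community from the
stoichiometric models of its members: the maximal community growth rate,
the optimal biomass fractions of every species, all intracellular,
cross-feeding and environmental fluxes, and the limitation structure
around the optimum.

The core is the balanced-growth mass balance. For every variable
metabolite *i*,

    sum_j f_j ( sum_l n_ij,l q_l,j + c_ij mu ) + sum_k b_ik phi_k = 0

with biomass fractions `f_j` (dimensionless, summing to 1), specific
fluxes `q` (mmol gDW⁻¹ h⁻¹), biomass compositions `c_j` (mmol gDW⁻¹), the
shared growth rate `mu` (h⁻¹) and specific environmental exchange fluxes
`phi_k = J_k / X_T`. At fixed `f` this is a linear program (solved by an
in-package bounded-variable simplex, verified against brute-force vertex
enumeration); the composition is then optimised by scanning the
biomass-fraction simplex and refining deterministically. On top of the
optimiser sit flux-variability ranges at the community optimum, 2-D
phase planes over flux bounds with limitation-regime classification,
finite-difference dual-limitation detection, biomass-ratio scans for
chemostat data, and a one-at-a-time screen over candidate cross-feeding
metabolites at a fixed (dilution-rate) growth rate.

Models come in through a plain tabular dialect (TSV metabolite and
reaction tables with equation strings) or an SBML Level 3 (flux-bounds)
subset; consortia are described by a JSON/YAML configuration. Results
are tibbles throughout, with `tidy()`/`glance()` and `autoplot()`
methods, and a thin command-line driver
(`inst/cli/cfba.R`: `optimize | scan | screen | validate | make-fixture`)
wraps the same functions for shell use.

## A worked example

The bundled toy consortium is an obligate mutualism: species `i` eats
glucose and exports succinate but needs ammonium; species `j` eats that
succinate, fixes N₂ at an ATP premium, and exports ammonium.

```r
library(cfba)

cm <- toy_consortium()
scan <- scan_fractions(cm, resolution = 0.02)
glance(scan)
#> # A tibble: 1 × 6
#>   mu_max n_grid n_feasible resolution argmax_f_i argmax_f_j
#>    <dbl>  <int>      <int>      <dbl>      <dbl>      <dbl>
#> 1      4     51         49       0.02       0.88       0.12

opt <- optimize_community(cm, coarse_resolution = 0.02)
optimal_fraction_region(cm, opt$scan, tol = 1e-6, mu_max = opt$mu_max)
#> # A tibble: 1 × 2
#>    f_lo  f_hi
#>   <dbl> <dbl>
#> 1 0.397 0.993
```

Reading: the community's maximal growth rate is 4 h⁻¹ (the anabolism
capacity of either member — with unconstrained cross-feeding the
environment and the exchanges are not what limits growth), compositions
below a critical glucose-consumer fraction of about 0.04 admit no
balanced state at all (the two grid points with no finite μ), and any
composition with `f_i` between ≈0.40 and ≈0.99 attains the same maximal
rate — a wide optimal plateau, not a unique optimal abundance. Capping
the ammonium export of `j` (`toy_scenario("critical")`) collapses that
plateau to a unique optimal composition at a lower rate; see the
vignette for the full regime tour.

The screen asks which exported metabolite best explains a measured
chemostat state:

```r
scr <- crossfeed_screen(screen_consortium(),
                        c("Ac_x", "Et_x", "Py_x", "La_x"),
                        fixed_mu = 1, substrate_exchange_id = "EX_Glc_x",
                        reference_id = "Ac_x", resolution = 0.05)
tidy(scr)
#> # A tibble: 4 × 4
#>   metabolite min_uptake percent_change status
#>   <chr>           <dbl>          <dbl> <chr>
#> 1 Ac_x             1.69           0    optimal
#> 2 Et_x             1.72           1.86 optimal
#> 3 Py_x             1.38         -18.3  optimal
#> 4 La_x            NA             NA    blocked
```

The pyruvate-like carrier would sustain the imposed growth rate on 18%
less glucose than the acetate-like reference; the lactate-like carrier is
structurally blocked (the consumer has no transporter for it).

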