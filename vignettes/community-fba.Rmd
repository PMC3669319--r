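---
title: "Balanced-growth flux balance analysis for cross-feeding communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced-growth flux balance analysis for cross-feeding communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfba)
library(ggplot2)
```

## The model

Flux balance analysis treats an organism's metabolism as a stoichiometric
network at steady state: with stoichiometric matrix $N$ and specific fluxes
$q$ (mmol gDW$^{-1}$ h$^{-1}$), every internal metabolite satisfies
$N q = 0$, fluxes respect thermodynamic bounds $q_{\min} \le q \le q_{\max}$,
and a biomass reaction with composition vector $c$ (mmol per gram of new
biomass) proceeds at the specific growth rate $\mu$. The optimum of $\mu$
over this polytope is the classical FBA prediction.

A consortium adds two things: shared extracellular metabolites that members
produce and consume (cross-feeding), and the biomass abundance $X_j$ of
each member. This package implements the balanced-growth extension of FBA
to such communities: every species grows at the *same* specific rate $\mu$
(otherwise a cross-fed intermediate would accumulate or deplete, breaking
the steady state), the biomass fractions $f_j = X_j / X_T$ are constant in
time, and every variable metabolite — intracellular in any member or
extracellular — is balanced:

$$\sum_j f_j \Big( \sum_l n_{ij,l}\, q_{l,j} + c_{ij}\, \mu \Big)
  + \sum_k b_{ik}\, \phi_k = 0 \quad \text{for every metabolite } i,$$

where $\phi_k = J_k / X_T$ are the environmental exchange fluxes per gram
of total community biomass. For fixed $f$ this is a linear program; the
shared $\mu$ multiplies every species' biomass column, which encodes the
equal-growth-rate requirement structurally rather than through extra
constraints. The community-level problem — find the composition $f^*$
maximising $\mu^*(f)$ — is nonlinear only through $f$ and is solved by
scanning the biomass-fraction simplex and refining around the incumbent.

Like classical FBA, the community optimum is a *yield* optimum: when a
single uptake bound limits the system, scaling that bound scales
$\mu^{\max}$ proportionally, so the method effectively maximises biomass
produced per unit of limiting resource. The unit conventions are:
specific fluxes in mmol gDW$^{-1}$ h$^{-1}$, growth rates in h$^{-1}$,
absolute environmental fluxes $J$ in mmol h$^{-1}$ converted to specific
fluxes at assembly by dividing by the total biomass $X_T$ (gDW). Exchange
columns are export-positive, so uptake is a negative exchange flux.

## The linear programming core

No LP solver ships with the R installations this package targets, so the
package carries its own dense bounded-variable primal simplex (two-phase,
Dantzig pricing with a Bland's-rule fallback after degenerate stalls, basis
refactorisation every iteration). Stoichiometric LPs are small here —
tens of variables — but highly degenerate; exactness matters more than
speed, and the implementation is tested against an independent brute-force
vertex-enumeration oracle on hundreds of random and structured instances.
Primal feasibility is enforced to $10^{-9}$, steady-state residuals are
checked to $10^{-8}$ on every reported optimum, and infinite bounds are
represented internally by $\pm 10^6$; a solution resting on that stand-in
is reported as unbounded rather than optimal. Maximising $\mu$ with no
finite flux bound anywhere is refused outright ("unbounded by
construction"): the balanced-growth equations are scale-free, so some
uptake capacity must be finite for the optimum to exist.

Infeasibility at a composition is a first-class outcome, distinct from
$\mu^* = 0$: a community can be unable to satisfy its maintenance demands
at any growth rate (no balanced state exists), which is not the same as a
balanced state with zero growth. Scans retain infeasible grid points with
an explicit status; plots may render them as gaps or zeros.

Alternate optima are the rule in these models. The incumbent flux vector
returned for a single solve is solver-dependent; any claim about an
individual flux should go through `flux_ranges_at_optimum()`, which
reports each flux's min and max subject to $\mu \ge (1 -
\mathrm{tol})\,\mu^*$.

## Outer optimisation over the composition simplex

`scan_fractions()` evaluates $\mu^*(f)$ on a uniform simplex grid
(default spacing 0.01 for two species, 0.05 for more);
`optimize_community()` then refines by a shrinking pattern search along
species-pair directions, dividing the step by 5 at each stall down to
`refine_tol` (default $10^{-5}$). This is deterministic and reproducible,
and the refined maximum can never undercut the coarse scan. For two
species $\mu^*(f)$ is piecewise smooth — linear or gently hyperbolic
segments joined at kinks where the active constraint set changes — so the
grid-plus-local-refinement strategy recovers the global optimum whenever
the landscape is unimodal, which holds for all bundled fixtures;
multi-modal landscapes would require a finer coarse grid.

`optimal_fraction_region()` reports the set of compositions within a
relative tolerance (default $10^{-6}$) of the optimum, with interval
endpoints refined by bisection; the tolerance separates genuine optimal
plateaus from LP noise. `scan_biomass_ratio()` reparameterises the
two-species scan by the ratio $r = X_a/X_b$, $f_a = r/(1+r)$, matching how
chemostat experiments report composition.

## Phase planes, limitation regimes and the screen

`phase_plane()` scans two flux upper bounds — typically the two
cross-feeding capacities — and maximises the community growth rate over
the composition in every cell. Cells are classified from the active set
at the optimum (a scanned bound within a relative $10^{-3}$ of its limit;
the tolerance matches the precision of the outer composition search).
`find_dual_limitation()` is the sharper, finite-difference notion: a cell
is dual-limited only if reducing *either* bound by a relative step
(default 5%) and re-optimising the composition lowers the optimum by more
than a threshold (default $10^{-3}$ h$^{-1}$). The two notions deliberately
differ: because the composition re-optimises, a bound can be active at the
optimal composition yet have zero community-level shadow price. The probe
step must dominate the outer search's own tolerance (roughly the landscape
slope times `refine_tol`), which is why the default step is percent-scale
rather than infinitesimal.

`crossfeed_screen()` asks which exchanged metabolite could carry the
cross-feeding: one candidate at a time, all other candidate routes closed,
the candidate's transports opened wide, the growth rate pinned to a given
value (a chemostat's dilution rate), and the substrate uptake needed to
sustain it minimised over the composition. Cross-fed metabolites outside
the candidate set — an obligatory nitrogen shuttle, say — keep their
configured bounds; a candidate without a transporter in one member is
reported `blocked`. Candidates are ranked by percentage change in minimal
substrate uptake against a reference metabolite (negative = more
efficient). A combinatorial in-addition-to mode
(`mode = "in_addition"`) keeps the reference route open alongside each
candidate; one-at-a-time replacement is the default.

## The bundled fixtures and what they do (and do not) show

The package is fully testable offline through three generated fixtures.

**The toy pair** (`toy_consortium()`) is an obligate mutualism: species
`i` consumes environmental glucose, needs ammonium, and exports succinate;
species `j` consumes that succinate, fixes dinitrogen at an ATP premium,
and exports ammonium. Each species runs four lumped processes —
catabolism, respiration, product formation, anabolism — plus transports,
an ATP maintenance drain, and a biomass reaction, with carbon and nitrogen
tracked by pseudo-element formulas so every reaction balances. The frozen
defaults were chosen once so that the canonical limitation regimes appear
and are then left alone:

* the maintenance drain (10 mmol ATP gDW$^{-1}$ h$^{-1}$) makes
  compositions too poor in either partner *infeasible*, not merely
  non-growing, producing a critical fraction of the glucose consumer below
  which no balanced state exists;
* the anabolism capacity (4 mmol gDW$^{-1}$ h$^{-1}$) caps the growth rate
  identically in both species, producing a wide flat plateau of optimal
  compositions when cross-feeding is unconstrained;
* finite ammonium-export capacity produces the above-critical (truncated
  plateau) and critical (unique optimal composition) regimes, and a finite
  succinate-uptake capacity in `j` lowers the whole curve (below-critical).

Exact plateau heights and critical fractions are properties of these
frozen coefficients, not of any organism; tests therefore assert
orderings and shapes (infeasible-then-feasible, plateau wider than 0.05,
unique maximum collapsing as the tolerance shrinks, below-critical maximum
strictly lower), never particular decimal values.

**The screen consortium** (`screen_consortium()`) carries three
alternative carbon carriers with different ATP economics on both sides,
plus one carrier the consumer cannot import, giving the screen a strict,
brute-force-verifiable efficiency ranking and a structurally blocked row.

**Random chain communities** (`random_community()`) compose seeded
producer-to-consumer chains, feasible by construction, for N-species and
determinism tests; the generator restores the session RNG state, so the
same seed gives a byte-identical model regardless of context.

What these fixtures do not emulate: genome-scale network redundancy
(thousands of reactions with extensive alternate pathways), realistic
biomass compositions, regulation, or thermodynamically derived bound
values. Passing tests demonstrate the correctness of the optimisation
machinery and the qualitative community-level phenomenology, not
quantitative predictions for any real consortium — those require curated
genome-scale models supplied through the SBML or tabular readers.

## Numerical choices, edge cases

* Biomass fractions must lie on the simplex within $10^{-9}$ and are
  renormalised; a species at $f_j = 0$ simply drops out of every balance
  (its rows scale to zero) while its bounded fluxes remain harmless.
* Chemostat mode (`fixed_mu`) replaces the $\mu$ column by a constant; an
  imposed rate above $\mu^*(f)$ returns infeasible, as it must.
* Cross-fed overflow exchanges are efflux-only by default — the
  environment may absorb intermediates but not supply them
  (`allow_crossfeed_supply = TRUE` opts out). Every extracellular
  metabolite gets exactly one exchange column; uptake of a nutrient
  always requires an explicit bound in the community configuration.
* Extracellular metabolite identity across species is by declared id
  match only; a metabolite declared `unique` by two species is an error
  demanding an explicit `crossfed` declaration, never a silent merge.
* Extra linear constraints over named fluxes (e.g. a relative uptake-
  capacity link between two strains) enter the LP as additional rows and
  compose with every analysis.
* Ties in the outer pattern search resolve towards the first improving
  direction in species order; with plateaus the reported argmax is one
  point of the optimal region, and `optimal_fraction_region()` is the
  honest report.

## A worked tour

```{r scan, fig.width = 6, fig.height = 3.5}
cm <- toy_consortium()
scan <- scan_fractions(cm, resolution = 0.02)
glance(scan)
autoplot(scan)
```

```{r optimum}
opt <- optimize_community(cm, coarse_resolution = 0.02)
opt$mu_max
optimal_fraction_region(cm, opt$scan, tol = 1e-6, mu_max = opt$mu_max)
```

```{r fva}
head(flux_ranges_at_optimum(cm, opt$argmax, rel_tol = 1e-6))
```

```{r screen, fig.width = 5, fig.height = 3}
scr <- crossfeed_screen(screen_consortium(),
                        c("Ac_x", "Et_x", "Py_x", "La_x"),
                        fixed_mu = 1, substrate_exchange_id = "EX_Glc_x",
                        reference_id = "Ac_x", resolution = 0.05)
tidy(scr)
autoplot(scr)
```

The problem sizes used throughout the test suite — two-species scans at
resolutions down to $10^{-4}$, three-species simplex grids at 0.01,
30×30 phase planes with per-cell composition optimisation — were chosen
as the sizes at which the brute-force oracles remain exhaustive, so every
optimisation claim in the suite is checked against an independent
enumeration.

## Known limitations

* The non-growing steady state (organisms persisting at zero net growth
  while exchanging metabolites) is outside the balanced-growth formalism
  implemented here, as are washout ($\mu < 0$), abiotic conversions in the
  environment, and dynamic (time-resolved) extensions.
* The outer optimiser assumes an effectively unimodal $\mu^*(f)$
  landscape; pathological multi-peak landscapes need a finer coarse grid.
* The SBML reader targets the Level 3 flux-bounds subset the writer
  emits plus common conventions (objective- or name-identified biomass,
  compartment-suffix heuristics); it is not a general-purpose SBML
  validator.
* Genome-scale models are supported through the readers in principle, but
  the dense simplex core is tuned for coarse-grained models; very large
  networks would want a sparse revised simplex or an external solver.
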