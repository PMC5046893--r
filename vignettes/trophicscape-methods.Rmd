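---
title: "Methods: a desk-scale trait-based ecosystem simulator for habitat loss and fragmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale trait-based ecosystem simulator for habitat loss and fragmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophicscape)
```

# What the package models

`trophicscape` simulates a terrestrial ecosystem as two interacting layers
on a bounded rectangular grid of habitat cells:

* **Autotrophs** are per-cell biomass pools (kg), split into an edible
  *leaf* pool and an inedible *structural* pool.
* **Heterotrophs** are *cohorts*: groups of identical individuals defined
  by categorical traits — trophic group (herbivore, omnivore, carnivore),
  thermoregulation (endotherm, ectotherm), reproductive strategy
  (iteroparous, semelparous) — and quantitative traits: current body mass,
  birth mass, maturity mass (kg), and a real-valued abundance.

On top of the simulator sits a factorial land-use scenario engine
(spatial *extent* x removal *intensity* x spatial *configuration* of
monthly plant-biomass removal), the three response metrics (trophic skew,
autotroph-loss mitigation, patch occupancy by trait class), and the
statistics used to read the design (arcsine transform, subset regressions,
paired contrasts).

The intended use is directional, desk-scale experimentation: the model is
deliberately simple enough to run a full 29-treatment factorial with
replication in minutes on one CPU, while preserving the allometric and
trophic structure that drives qualitative responses to habitat loss and
fragmentation.

# The monthly step

Each month, in fixed order (a fixed order makes trajectories exactly
reproducible under a seed):

1. **Autotroph growth.** Leaf biomass grows proportionally to itself,
   logistic in the leaf pool: growth = `autotrophGrowthRate` x
   (NPP/`nppReference`)^`nppSensitivity` x L x max(0, 1 - L/K), with K =
   `carryingCapacityDensity` x cell area; the sublinear NPP response
   (default exponent 0.5) stands for reserve buffering of seasonality,
   without which monthly production swings drive large plant-biomass
   oscillations. Production is split
   `leafAllocation` : (1 - `leafAllocation`) between leaf and structural
   pools; both pools then lose a proportional climate-driven fraction
   (`climateMortality`, `structuralTurnover`), and deciduous stocks shed a
   leaf fraction in dry-season (below-annual-mean NPP) months.

   Two consequences are intentional. A *partially* cleared leaf pool
   regrows quickly (grass regrowing from reserves), so repeated fractional
   removal equilibrates well above the level naive bookkeeping predicts;
   and a *fully* cleared pool (100% removal intensity) is absorbing —
   plants do not reappear in a cell while it is razed every month. Both
   behaviours are what produce the observed mitigation pattern: positive
   top-down mitigation below 100% intensity, essentially none at 100%.

2. **Eating.** Herbivores (and omnivores at weight `omnivoreEfficiency` x
   `omnivoreHerbivoryWeight`; the efficiency factor is a jack-of-all-trades
   penalty, without which diet generalism strictly dominates both
   specialist strategies) demand leaf at a saturating per-individual
   rate `herbAttack` x m^`herbExp` x L/(L + `herbHalfSat` x area); cell
   demand above the grazeable fraction of the pool is rationed
   proportionally. Predators (carnivores, and omnivores at the
   complementary weight) kill prey-cohort biomass weighted by a log-normal
   size-preference kernel centred on `optimalPreyRatio` x predator mass,
   with a saturating intake on kernel-weighted prey density and
   proportional rationing so no cohort is over-killed. Prey biomass below
   `preyRefugeDensity` per cohort is unavailable — a low-density refuge,
   without which predation deterministically extirpates rare small-bodied
   classes from every cell over multi-decade runs. Intake times the
   assimilation efficiency is credited to the consumer.

3. **Metabolism.** Each individual pays coefficient x m^`metaExp` per
   month; ectotherm costs are Q10-scaled with cell temperature, endotherm
   costs use a larger temperature-independent coefficient. Mass never
   falls below `massFloorFraction` x birth mass. The intake exponent
   (0.7) is deliberately below the metabolic exponent (0.75): under food
   scarcity, larger-bodied cohorts run a deficit first, which is the
   mechanism behind size-ordered declines under habitat loss.

4. **Growth and reproduction.** Net surplus grows juveniles toward
   maturity mass; beyond maturity, `reproFraction` of surplus accrues to a
   per-individual reproductive pool. When the pool reaches birth mass an
   offspring cohort is spawned (abundance = parent abundance x
   pool/birth mass — mass-conserving), inheriting all traits; semelparous
   parents die on spawning.

5. **Mortality.** Abundance is multiplied by exp(-(background +
   senescence + starvation + crowding)) per month; senescence rises
   linearly with age against an allometric lifespan (`lifespanCoef` x
   maturity mass^0.25 months); the starvation term applies to cohorts
   whose realized intake/requirement ratio fell below `hungerThreshold`.
   The hunger ratio, not a mass threshold, defines starvation: with
   log-uniform birth masses a fixed fraction-of-maturity-mass rule would
   misclassify every newborn. The crowding term (`mortCrowding` x
   trophic-group biomass density / per-group `crowdingReference`, lower
   references for higher trophic levels, i.e. territoriality) is the
   self-limitation that damps consumer-resource boom-bust cycles; without
   it the desk-scale system oscillates with a coefficient of variation
   well above its steady-state target.

6. **Dispersal.** Newly spawned cohorts move with probability
   `natalDispersalProb`; hungry cohorts with probability
   `responsiveDispersalProb`. Destinations are uniform among cells within
   the allometric radius `dispersalCoef` x m^`dispersalExp` km; the grid
   boundary is closed, so a corner cohort simply has fewer candidate
   cells, and a radius below the cell spacing means no movement. Cohorts
   move wholesale (no splitting): fractional movement would be equally
   defensible, but whole-cohort movement keeps abundance bookkeeping
   exact.

7. **Cohort merging.** Cells are capped at `cohortCap` cohorts; the
   same-functional-group pair closest in log mass merges
   (abundance-weighted means; abundance and biomass conserved), and only
   if no same-group pair exists is the lowest-biomass cohort culled (and
   ledgered).

Every process writes its mass flow into a per-month ledger; the test suite
asserts that the ledger balances the state's total biomass change to
1e-9 relative, every month.

# Scenario engine

Treatments cross extent (fraction of cells impacted), intensity (fraction
of autotroph biomass removed from impacted cells *every month*), and
configuration (random cells = fragmenting; contiguous rows filled from the
first row = continuous). At 100% extent the two configurations coincide
and are deduplicated; one pristine control completes the set — with the
default four extents and four intensities, 29 treatments. Removal happens
at the start of each month, before growth, so 100% intensity
unambiguously means the cell starts every month bare; it debits leaf and
structural pools proportionally — the least-assumption reading of
"removing autotroph biomass", and a leaf-only mode is available via the
removal machinery's per-pool debits.

Runs are paired: within a replicate, every treatment (including the
pristine control) continues from the *same* end-of-burn-in state, and all
seeds derive from the base seed via a documented hash of (scale,
replicate, treatment), so any run can be reproduced in isolation.
Summaries average landscape totals over the final recording window.

# Metrics

**Trophic skew** between an impacted and a paired pristine summary is half
the L1 distance between the biomass share vectors over carnivore,
omnivore, herbivore, autotroph (the total-variation distance between
compositions). It is 0 exactly under equal proportional loss from every
compartment, bounded by 1, symmetric, invariant to rescaling either
ecosystem, and reads as the fraction of total biomass redistributed
between compartments. Complete collapse (zero impacted total) is
excluded.

**Mitigation** compares observed impacted autotroph biomass with the
naive no-trophic-effects expectation (1 - extent x intensity) x pristine
autotroph biomass: M = A_I / ((1 - E i) A_P) - 1. Positive M indicates
release from herbivory; the full-removal case E = i = 1 (naive
expectation zero) is excluded.

**Patch occupancy** applies to 100%-intensity scenarios, where impacted
cells are unambiguously unsuitable: for each class (trophic group x log10
body-mass bin, and additionally each whole trophic group), the proportion
of remaining pristine cells containing at least one cohort of the class
with abundance at or above 1 individual. Default bins quarter the seeded
mass range (origin 10^-6.4 kg, width 2.6 decades): decade-wide bins are so
narrow relative to per-cell cohort counts that most are empty even in
pristine cells, which would make occupancy thresholds meaningless at this
scale.

# Statistics layer

Skew and mitigation are arcsine-square-root transformed before linear
modelling (values above 1 — mitigation can exceed 1 — are clipped to 1
with a warning, since the transform is defined on proportions). The factorial's interactions are read through subset
regressions (transformed metric on intensity within each extent, and vice
versa; ordinary least squares) and paired t-tests between matched
scenarios (configuration contrasts pair random vs continuous at equal
extent < 100%, intensity, and replicate), plus the mean pairwise
percentage contrast on raw values. No multiple-testing correction is
applied: the subset tests interpret established differences rather than
screen new hypotheses. With the full-scale design
shape (4 levels x 2 configurations x 10 replicates) the subset
regressions have 78 residual df and the configuration contrast 119 — the
package reproduces that bookkeeping exactly when fed tables of that
shape.

# The synthetic environment

The study this design derives from drove its model with observed climate
for a specific East African location. The package instead generates a
parametric savanna: temperature = mean + amplitude x cos(2 pi (month -
phase)/12), NPP likewise with a relative wet/dry amplitude, both modulated
by a smooth multiplicative spatial field (3x3-smoothed white noise), all
deterministic under a seed. Defaults (25 C mean, 3 C amplitude,
5e4 kg/km^2/month mean NPP ~ 0.6 kg dry mass/m^2/yr, 0.6 relative NPP
amplitude, 10% spatial noise) are plausible for a tropical savanna. What
this emulates is seasonality and mild spatial heterogeneity; what it does
not emulate is interannual variability, drought sequences, soil-moisture
dynamics, or any real geography — so passing tests say the *mechanisms*
behave directionally as reported, not that any real landscape was
reproduced.

Seeding draws, per cell and functional group, maturity masses log-uniform
over 0.4 mg - 5000 kg and birth masses log-uniform below maturity, with
abundances following a Damuth-like N ~ m^-0.75 rescaled to configured
per-trophic-group biomass densities (defaults 4000 / 800 / 400 kg/km^2
for herbivores / omnivores / carnivores).

# Calibration rationale and numerical choices

Process constants were calibrated once, as part of model design, to yield
a persistent, size-structured ecosystem at desk scale: a biomass pyramid
(A >> H >= O + C) and a dynamic steady state (coefficient of variation of
total biomass < 0.2 over the last fifth of an unimpacted run) across
seeds. Notable choices:

* Leaf regrowth is fast (`autotrophGrowthRate` = 5/month at reference
  NPP) and pristine leaf is grazer-suppressed; this is the regime in
  which removing plants mostly removes *herbivory* rather than plants.
* The endotherm metabolic coefficient (0.15 kg^0.25/month) is three times
  the 20 C ectotherm coefficient.
* Carnivore optimal prey ratio 0.01 with a 1.5 log-e kernel width.
* Grid indices are 1-based row-major internally (R convention);
  exported tables carry 0-based (row, col) with (0,0) the north-west
  corner.
* Cell areas use exact spherical-quadrilateral geometry (mean Earth
  radius 6371 km); dispersal distances use a local tangent-plane
  approximation, adequate within a degree of the equator.
* Ties and degenerate cases: equal-share skew returns exactly 0; paired
  tests on zero-variance differences return a degenerate flag rather
  than a t value; non-integral impacted-cell quotas round half up with a
  warning; subset regressions skip subsets with < 3 points or a constant
  predictor.

# Problem sizes

The `desk` preset — one 5 x 5 grid of 0.1-degree cells, 240 burn-in +
240 impact months, a 36-month recording window, 3 replicates, 87 runs —
is the package's reference configuration for interactive work, tests, and
the worked examples; it completes in a few minutes on one CPU. The
`paper` preset provides the full-scale design shape (10 x 10 grids
at two scales, 1200 + 1200 months, 10 replicates, 580 runs) and is
provided for completeness; it is hours of compute, and nothing in the
test suite depends on it. Directional properties (skew rising with extent
and intensity; positive mitigation below 100% intensity and near zero at
100%; occupancy declining with extent, earlier for larger animals) are
checked as seed-majority properties over three desk-scale experiment
batches.

# Known limitations

* The package's targets are directional patterns and design-exact
  quantities. Quantitative ensemble values from field-calibrated
  ecosystem models depend on their full parameterizations and observed
  climate drivers; no attempt is made to reproduce any particular set of
  them.
* No trait evolution, no explicit home ranges, no marine processes, no
  taxonomy.
* Plant recolonization of razed cells is absent by construction; after a
  100%-intensity impact ends, a cell would need dispersal-borne seed
  input (not modelled) to recover.
* The engine is deterministic given a seed; stochasticity enters only
  through dispersal draws, mask draws, and the environment field.
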