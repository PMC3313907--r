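---
title: "Cell-ensemble modelling of apoptosis: methods and parameter choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-ensemble modelling of apoptosis: methods and parameter choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellensemble)
```

## 1. Overview

`cellensemble` simulates heterogeneous populations of single-cell ODE
models of receptor-induced apoptosis and quantifies how protein production
rates control the time of death (ToD). This vignette documents the model,
the algorithms and every default parameter, with the rationale for each
choice.

## 2. The single-cell model

A cell is a mass-action-style reaction network: species with initial
amounts, reactions with integer stoichiometry and symbolic rate laws, and
global rate constants. Networks can be defined in R (`reaction_network()`)
or read from SBML Level 2 Version 4 files (`load_sbml()`); `write_sbml()`
round-trips them. The SBML reader is deliberately strict: constructs the
simulator cannot honour (events, rules, function definitions, constraints,
initial assignments, stoichiometry math) raise errors instead of being
silently ignored, because a silently dropped event would corrupt every
downstream death time.

The ODE right-hand side is assembled once per cell by `build_rhs()`:
reaction velocities are evaluated from the symbolic rate laws and combined
through the stoichiometric matrix. Boundary-condition species (the
extracellular ligand) are held constant by the solver and changed only by
the stimulation protocol. Integration uses `deSolve::lsoda`/`lsodar`,
which switches automatically between stiff and non-stiff methods — the
caspase-activation phase is stiff.

**Time units.** Internally all times are hours. SBML time units are
converted on load via the model's time `unitDefinition` (plain SBML
defaults to seconds, factor 1/3600).

## 3. Population generation

Cell-to-cell variability enters exclusively through the **zeroth-order
protein production rates**: rate constants of reactions that have no
reactants and whose rate law references no species. This identification is
automatic (`identify_production_rates()`); stimulus-*induced* synthesis,
whose rate depends on a species, is intentionally not distributed, since it
is part of the signalling dynamics rather than of the constitutive
expression state of the cell.

For each cell and each production rate, a multiplier is drawn

$$ m \sim \mathrm{Lognormal}(\mu_{\log},\, \sigma), \qquad
   \mu_{\log} = -\sigma^2/2, $$

independently across cells and rates.

* `sigma = 0.148` (natural-log scale) by default — a moderate expression
  noise level typical of protein-abundance measurements; at this value
  about 95 % of multipliers fall within roughly ±30 % of 1.
* `center = "mean"` (default) sets $\mu_{\log} = -\sigma^2/2$, so the
  *mean* multiplier is exactly 1 and the population-average production flux
  equals the nominal model's. `center = "median"` uses $\mu_{\log} = 0$
  instead (median multiplier 1).
* Sampling is cell-major from a single RNG stream seeded by
  `ensemble_spec(seed = ...)`, so populations are bit-reproducible and a
  prefix of a larger population equals the smaller one.

`generate_tod_dataset()` produces *synthetic regression fixtures* — ToD
values drawn directly from a log-linear model with Gaussian log-noise and
optional censoring — to test the estimation stage in isolation, with known
truth. It emulates the statistical shape of simulated ToD data, not any
biology.

## 4. Stimulation protocols

`stimulus_protocol(dose, mode, pulse_minutes, horizon)`:

* `dose` in ng/ml, converted linearly to model units through the network's
  conversion factor (`dose_to_model_units()`); conversion is anchored at
  zero.
* `mode = "continuous"`: ligand clamped at the dose for the whole horizon.
* `mode = "pulse"`: ligand clamped for `pulse_minutes` (default 30 min, a
  standard transient-exposure design), then **washout**: the solver is
  restarted with free ligand set to exactly 0. Receptor-bound complexes
  and all intracellular species are untouched, so every non-ligand species
  is continuous across the washout. The reset is exact rather than modelled
  as fast decay so that "no free ligand after washout" is an invariant the
  tests can assert literally.
* `horizon = 100` h: the observation window; cells alive at the horizon
  are censored as survivors. 100 h is long relative to typical death times
  (hours to tens of hours) so censoring reflects genuine survival, not a
  short experiment.

## 5. Pre-equilibration and death detection

Before stimulation each cell is relaxed to steady state
(`equilibrate()`): staged integrations of increasing span until the
maximum relative derivative falls below $10^{-9}\,h^{-1}$. The steady
state must be **caspase-free** — every active caspase must be below
$10^{-6}$ of its procaspase's steady amount — otherwise the model would
"die" without stimulus and the run is rejected with an error. Networks
with no steady state (e.g. pure production) are likewise rejected.

Death is an event: by default 50 % cleavage of PARP
(cleaved/(cleaved + intact) ≥ 0.5), the classic commitment-point marker.
The event is located by `lsodar` root finding and then *polished* by
bisection on short re-integrations at tolerances $10^{-12}/10^{-14}$
(`refine_tol = 1e-9` by default in `simulate_cell()`). The polish matters
for the nominal sensitivity, where two nearly identical death times are
subtracted: without it, event-location error of order $10^{-4}$ h would
dominate the ×1.1 central difference.

Default solver tolerances are `rtol = 1e-8`, `atol = 1e-12`; the test
suite verifies that tightening them tenfold moves no death time by more
than 0.05 h. `simulate_population()` isolates per-cell failures and aborts
only if more than 1 % of cells fail.

## 6. Sensitivity estimators

**Population sensitivity** (`population_sensitivity()`): for each
distributed production rate, a robust straight-line fit of
$\log \mathrm{ToD}_i$ on $\log m_{p,i}$ over *dying cells only*.

* Estimator: `MASS::rlm` M-estimation with Tukey's bisquare
  ($c = 4.685$, the conventional 95 %-efficiency tuning) and MAD scale.
  Robustness is essential because early-committing outlier cells are
  expected in heterogeneous ensembles and would bias least squares.
* Survivors are excluded from the fit (their ToD is unobserved, not
  infinite) and reported per multiplier decile, so informative censoring
  is visible rather than hidden.
* The returned object is a classed model (`tod_sensitivity`) with
  `print`, `summary`, `coef` and `plot` methods, in the classic R
  modelling idiom.

**Nominal sensitivity** (`nominal_sensitivity()`): the central log-log
difference
$[\log \mathrm{ToD}(p f) - \log \mathrm{ToD}(p/f)] / (2 \log f)$ at
$f = 1.1$ — a ±10 % perturbation, small enough to approximate the local
elasticity yet large enough to dominate numerical error once death times
are polished (`refine_tol = 1e-12` here). If either perturbed cell
survives the horizon, the slope is reported as undefined (`NA` with a
flag), never as a number.

**Classification** (`summary()`, `sensitivity_report()`): slopes with
$|\beta| < 0.1$ are *negligible*; otherwise *earlier_death* ($\beta < 0$)
or *later_death* ($\beta > 0$). The 0.1 threshold marks where a two-fold
change in production shifts the death time by less than about 7 % —
below biological relevance for this system.

**Ground truth.** `make_toy_timer(k, theta)` implements
$\dot X = m k$, death at $X \ge \theta$, so $\mathrm{ToD} = \theta/(mk)$
and both estimators must return exactly −1. The test suite holds the
population slope to $10^{-7}$ and the nominal slope to $10^{-10}$.

## 7. Population statistics and knockouts

`summarize_fates()` reports the death rate (over all cells), and — over
dying cells only — the median ToD, quartiles, 1.5 × IQR whiskers,
outliers, and the **relative standard deviation** sd/mean (sample sd,
denominator $n-1$, matching R's `sd()`).

`compare_populations()` reports the death-rate difference in percentage
points and the median-ToD and relative-std differences as percentages of
the reference population.

`knockout_experiment()` sets one reaction's rate law to literal zero
(`apply_knockout()`) and simulates wild type and knockout on the *same*
sampled population (common random numbers), so differences are paired and
sampling noise largely cancels.

## 8. The demo network

`example_tnf_network()` is a small synthetic network (8 species,
13 reactions) with the canonical extrinsic-apoptosis architecture: ligand
TNF binds receptor R to form complex C; C activates procaspase C8 to
active caspase A8; C also induces a survival inhibitor I that degrades A8;
A8 cleaves PARP. Its rate constants are the package's own design choices,
tuned so that the qualitative phenomenology of the pathway appears at
convenient scales: the nominal cell dies at ~7 h under 10 ng/ml continuous
TNF, a 30-min pulse delays death into the ~25 h range, the inhibitor arm
gives inhibitor production a positive ToD slope, and population
heterogeneity visibly damps the sensitivities. It is *not* calibrated to
experimental data and supports illustration and property-based testing
only.

Problem sizes used in the shipped tests and the acceptance script
(e.g. 2 500-cell toy ensembles, 60–80-cell demo populations) are chosen to
keep runs in seconds-to-minutes while leaving the asserted effects far
above sampling noise; the regression-recovery tolerance (0.05) was frozen
from a Monte-Carlo calibration of the estimator's sampling error at those
settings before the assertions were written.

## 9. Limitations

* Deterministic ODEs with static parameter diversity: no stochastic
  reaction events, no temporal parameter drift, no cell division or
  death-independent removal.
* Production-rate multipliers are sampled independently across proteins;
  correlated expression (e.g. global expression-capacity noise) is not
  modelled.
* The SBML subset is intentionally narrow (no events/rules/function
  definitions); models using those constructs must be flattened upstream.
* The population sensitivity is a marginal, not a joint, regression: with
  several rates varying simultaneously, slopes are marginal elasticities
  averaged over the population distribution of the other rates.
* Censoring is handled by exclusion and disclosure, not by survival-model
  likelihoods; with heavy informative censoring the slopes should be read
  alongside the survivor-per-decile table.
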