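---
title: "Model and methods: lifetime cost-effectiveness of antenatal GDM prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: lifetime cost-effectiveness of antenatal GDM prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(gdmcea)
library(dplyr)
```

## The decision problem

Gestational diabetes mellitus (GDM) complicates roughly one in nine
pregnancies and carries consequences on two time scales: in the perinatal
period it raises the probability of induction of labour, Caesarean birth and
neonatal intensive/special care (NICU/SCN) admission, and over the mother's
lifetime it multiplies her risk of developing type 2 diabetes (T2DM) roughly
ninefold. A structured lifestyle (diet and/or physical activity) intervention
delivered during pregnancy reduces the incidence of GDM by about a third.
`gdmcea` quantifies what offering such an intervention to every pregnant
woman in a national annual birth cohort is worth: lifetime cases of GDM and
T2DM averted, years of life and quality-adjusted life years (QALYs) gained,
cost offsets by category, the incremental cost-effectiveness ratio (ICER),
and the return on investment (ROI) per dollar spent on delivery.

## Model structure

Each maternal age cohort (bands 15--19 through 45--49, entering at the band
midpoint) passes a decision node (intervention vs usual care) and a GDM
chance node, then enters a three-state Markov process over
{no T2DM, T2DM, dead} in one-year cycles until age 85.

* **Usual care** splits a cohort with band GDM prevalence $q$ into branches
  $\{q, 0, 1-q\}$ over {GDM, avoided GDM, never GDM}.
* **Intervention** multiplies GDM risk by the subgroup relative risk
  $RR_{GDM}$ (base case 0.67), giving $\{q \cdot RR, q(1-RR), 1-q\}$; the
  intervention costs AU$228 per woman (a mid-point coach salary of AU$82,600
  with 15% on-costs and a 20% fixed allowance, spread over a 500-woman
  annual caseload).

Branch membership fixes the lifetime T2DM hazard. Women with GDM face the
GDM-stratum incidence, women without GDM the no-GDM stratum, and women who
avoided GDM through intervention $RR_{avoided} \times$ the no-GDM stratum
($RR_{avoided} = 1$ in the base case, i.e. full risk normalisation).

### Incidence decomposition

Registry incidence refers to the total female population, a mixture of the
GDM and no-GDM strata, so the published stratum contrast
($RR = 9.51$) must first be corrected for the population prevalence of GDM
exposure ($p = 0.65\%$):

$$RR_{adj} = \frac{RR}{p\,RR + (1 - p)} = 9.01$$

The stratum rates follow as $i_{GDM} = RR_{adj}\, i_{total}$ and
$i_{noGDM} = i_{GDM}/RR$, which satisfy both the ratio identity
$i_{GDM}/i_{noGDM} = RR$ and the mixture identity
$p\,i_{GDM} + (1-p)\,i_{noGDM} = i_{total}$ exactly. A literal
"subtract the GDM incidence from the total" would produce a negative no-GDM
rate (the adjusted RR exceeds 1); the mixture-consistent decomposition is
the only reading that reproduces the printed adjusted RR and keeps all rates
positive, and is what the package implements.

### Mortality

Background mortality for the healthy state removes prevalent T2DM cases and
their deaths from the all-cause totals at ages 40 and over
(`derive_no_t2dm_mortality()`); below 40, where female T2DM deaths are
negligible, both states share the all-cause rate. Where only age-banded
rates are available, `smooth_single_year_rates()` fits a Poisson regression
with a restricted cubic (natural) spline in age, with log person-year
exposure offset and four knots at exposure-weighted quantiles -- a standard
default; the flat-curve and simulated-Gompertz recovery tests bound its
error at under 5% across ages 45--80.

### Numerical conventions

Several conventions are unstated in the published description of this model
family; the package fixes them as follows and exposes none as silent
behaviour:

* **Rate to probability**: $P = 1 - e^{-r\,\Delta t}$, guaranteeing
  probabilities below 1 at the oldest ages.
* **Competing risks within a cycle**: death is applied first, incidence to
  survivors, so incident cases are survivors who transition; the ordering
  matters at the fourth decimal and mortality data are all-state.
* **Cycle timing and discounting**: pregnancy and birth events sit at
  $t = 0$ undiscounted; Markov cycles are $t = 1, 2, \ldots$ with discount
  factor $(1+r)^{-t}$, $r = 5\%$ per year.
* **Half-cycle correction** (on by default): state-years per cycle are the
  mean of cycle-start and cycle-end occupancy.
* **Maternal pregnancy mortality** is excluded (order $10^{-5}$ per birth).

## Outcomes and costs

QALYs weight healthy state-years by age-band utilities (0.95 at 18--24
declining to 0.82 at 75+) and T2DM state-years by the uncomplicated-T2DM
utility 0.785. The published statement that T2DM utilities are "adjusted
consistently with their age-specific healthy scores" admits two readings,
both implemented and selectable via `utility_adjustment_mode`: multiplicative
(default; the healthy curve is scaled by $0.785/0.95$, anchored at the best
healthy band so the state utility is 0.785 at the reference age) or an
absolute decrement. GDM itself carries no utility decrement.

Cost categories: intervention delivery (per woman, intervention arm only);
pregnancy costs (antenatal GDM care plus event-probability-weighted
Caesarean and induction costs, GDM-specific vs not); NICU/SCN admission
costs (toggled by `include_nicu_scn`, off in the primary healthcare
perspective); chronic T2DM management; and, in the societal scenario,
direct non-health costs and income-support payments per T2DM year.

Chronic costs have two engines. The base case applies age-specific
*attributed* annual costs to T2DM state-years (half-cycle-consistent with
the QALY engine). The micro-costing scenarios decompose end-of-cycle T2DM
occupancy into incident cases (first-year, newly-diagnosed cost) and
carried-over cases (subsequent-year cost); this decomposition uses
end-of-cycle occupancy regardless of the half-cycle flag, since
"first year of diagnosis" is a per-case, not per-state-year, notion.

ROI is defined from the results-table arithmetic of this model family:
savings (negated non-intervention category increments) divided by the
incremental intervention cost; with the published base-case increments this
yields 1.22 excluding and 1.57 including NICU/SCN savings, which is how the
definition was confirmed. `efficiency_frontier()` implements strict and
extended dominance for multi-strategy comparisons.

## Scenarios

* **base** -- excess GDM risk persists for life; avoided-GDM women revert
  fully to the no-GDM hazard; attributed chronic costs; healthcare
  perspective.
* **s1_10yr** -- the GDM branch's excess hazard lapses 10 cycles after
  birth, reverting to the total-population incidence.
* **s2_rr_sweep** -- $RR_{avoided}$ varies over $[1, 9.5]$;
  `scenario2_sweep()` traces ROI and ICER over the grid and locates the
  $ROI = 1$ and $ICER = AU\$50{,}000$ roots by bisection. At
  $RR_{avoided} = RR = 9.51$ the intervention prevents no lifetime T2DM
  cases and only perinatal effects remain (verified exactly in the tests).
* **s3_microcost_health / s4_microcost_societal** -- micro-costed chronic
  disease from the healthcare and societal perspectives.

## Uncertainty analysis

One-way deterministic sensitivity analysis re-runs the model at each
parameter's bounds: published 95% CIs for relative risks and utilities,
$\pm 1.96\,SE$ with $SE = 10\%$ of the mean for costs. The probabilistic
sensitivity analysis (default 10,000 iterations, single seed) samples all
parameters independently: log-normal for relative risks with
$\sigma = (\ln U - \ln L)/3.92$ and the location chosen mean-preserving
($\mu = \ln m - \sigma^2/2$, so the sampled mean matches the deterministic
input to well under 1%); beta by method of moments for utilities; gamma for
costs. Draws producing a structurally invalid model are resampled and
counted (the families used make this a null event in practice). A fully
degenerate distribution set collapses the PSA to the deterministic run
exactly, which the tests assert. Threshold searches (intervention cost at
which the ICER reaches the willingness-to-pay; scenario-2 roots) use
bisection to AU$1 and $10^{-4}$ RR respectively.

## Input data, fixture and synthetic generator

All inputs travel in a five-table CSV bundle (`cohorts`, `epi`,
`relative_risks`, `utilities`, `costs`) validated by
`validate_parameters()`; the packaged reference bundle
(`load_reference_fixture()`) carries every main-text parameter verbatim.
Values published only in supplementary registry tables -- age-band births,
single-year incidence/mortality/prevalence schedules, perinatal and chronic
unit costs, subgroup intervention unit costs -- ship as nationally plausible
synthetic stand-ins flagged `provenance = "synthetic"`: total births 306,599
(the published intervention spend divided by AU$228), band GDM prevalence
rising 5.5% to 26% (overall ~11.9%), logistic-in-age T2DM incidence
plateauing near 1.1%/year, Gompertz--Makeham female mortality, and an
NICU/SCN admission cost near AU$17,000 implied by the published cost and
admission totals. Exact replication of the published headline numbers
(8,248 cases prevented, ROI 1.22, the scenario-2 roots 2.71 and 8.62, the
AU$2,030 cost threshold, 70.5% cost-saving PSA iterations) therefore
requires transcribing the supplementary tables into the same bundle format;
with the stand-ins the pipeline reproduces the qualitative pattern (about
7,700 cases prevented, dominant ICER, ROI near 1.5) and all structural
identities, which is what the test suite asserts.

The synthetic generator (`generate_synthetic_bundle()`) exists so the whole
pipeline is testable from code alone. It emulates the *shape* of the real
inputs -- strictly increasing band GDM prevalence, logistic incidence,
Gompertz-like mortality, cost magnitudes scaled from the fixture -- under a
single seed, with multiplicative log-normal noise re-monotonised after
perturbation. It makes no attempt to match any national registry
numerically. Passing tests on synthetic bundles therefore demonstrate
engine correctness (conservation, identities, linearity in cohort size,
oracle agreement), not calibration to any real population.

## Validation strategy and problem sizes

The Markov engine is checked against an independent individual-level
microsimulation (100,000 women per check, agreement within 3 Monte Carlo
standard errors on cases, life-years and T2DM-years), occupancy
conservation and absorbing-death monotonicity are asserted over 1,000
random schedules, the incidence decomposition identities hold to $10^{-12}$
relative, and the seeded 10,000-iteration PSA is run twice and compared
exactly. A full two-arm lifetime comparison over all seven cohorts runs in
about 2 ms through the compiled internal representation, which is what
makes the full-size PSA routine.

## Known limitations

* No cardiovascular sequelae of GDM, no offspring outcomes, no
  subsequent-pregnancy costs, no diabetes complication sub-states -- the
  scope matches the published model.
* Parameters are sampled independently in the PSA; no correlation
  structure is available to impose.
* The per-woman denominator for incremental results is total included
  births across cohorts (the published table does not print it; this
  reading reproduces its per-woman magnitudes).
* Single pregnancy per woman; cohort entry at the band midpoint.

## A worked example

```{r example}
params <- load_reference_fixture()
res <- run_comparison(params, model_config())
res
glance(res)
```

```{r sweep, fig.width = 6, fig.height = 5}
sw <- scenario2_sweep(params, model_config(), rr_grid = seq(1, 9.5, 0.5))
sw$roots
autoplot(sw)
```
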