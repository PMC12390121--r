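---
title: "The daily accumulation model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The daily accumulation model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dampfos)
```

## The model

`dampfos` implements a one-compartment daily accumulation model (DAM) for
perfluorooctane sulfonate (PFOS) in beef cattle. The animal's whole-body
PFOS burden $A_d$ (µg) is kept as a running log with one row per day of
life: each day the dietary PFOS mass $I_d$ enters (100% gut absorption by
default) and a first-order elimination leaves,

$$E_d = A \left(1 - 0.5^{\,1/T}\right),$$

where $T$ is the elimination half-life in days. Under the default update
order the elimination acts on the post-intake burden,
$A_d = (A_{d-1} + I_d)\, 0.5^{1/T}$. Daily intake sums four routes —
forage, drinking water, incidental soil ingestion, and (pre-weaning) milk —
each the product of a physiological intake rate and a medium concentration
from the exposure scenario.

Muscle and serum concentrations follow from static partitioning:

$$C_\text{muscle} = \frac{R_\text{mb}\, A_d}{F_\text{mbw}\, BW_d},
\qquad C_\text{serum} = C_\text{muscle} / R_\text{ms},$$

with $R_\text{mb}$ the muscle:body PFOS mass ratio (0.231 ± 0.090),
$F_\text{mbw}$ the muscle fraction of body weight (0.361 ± 0.117 kg/kg) and
$R_\text{ms}$ the muscle:serum concentration ratio (0.080 ± 0.016; PFOS
partitions strongly into serum, so serum concentrations exceed muscle by a
factor of 12.5). The partitioning assumes PFOS redistributes quickly
relative to its multi-month half-life; immediately after an abrupt change
in exposure the predicted muscle and serum values can lag reality by a few
days, a known limit of the one-compartment form.

## Physiology submodels

All curves are evaluated at integer ages (day 0 = birth) and floored at
zero outside their fitted ranges.

* **Body weight.** Daily gain is the cubic rate polynomial
  $0.5584 + 2(0.001787)d - 3(1.549\times10^{-6})d^2 -
  4(1.332\times10^{-9})d^3$ kg/day up to day 540, then a constant
  0.32 kg/day. Weight is integrated by simple daily summation (one step
  per day), mirroring the row-per-day structure; the closed-form quartic
  growth curve whose derivative this is serves only as a test oracle, and
  the two agree within 0.5% at every age from 1 to 540. Birth weight is
  35.45 ± 3.27 kg (a cross-breed average).
* **Forage dry-matter intake (DMI).** A single logarithmic curve,
  $5.4702\ln d - 22.889$ kg DM/day, covering calves and finishers, zero
  before day 66. The curve crosses zero near day 66 so the switch-on is
  effectively continuous. The energy-balance derivation of pre-weaning
  forage intake — $(DEI \cdot BW - DE_M \cdot DMI_M)/DE_F$ with
  $DEI = 0.0783$ Mcal/kg BW/day, $DE_M = 4.87$ and $DE_F = 2.27$ Mcal/kg —
  is implemented (`calf_forage_dmi()`) as the documented derivation path
  but is not wired into the simulation: the operative rule is the
  zero-before-66 logarithmic curve. Published descriptions of the intake
  machinery differ on whether calves take measurable forage from about day
  30; we follow the tabulated operative rule (zero before day 66), which
  the logarithmic curve's zero crossing makes numerically immaterial.
* **Milk.** The dam's fluid milk production is a quartic lactation curve
  (constant term 1.445 kg/day), zero from weaning at day 240; the calf
  drinks all of it, and fluid milk is 13% dry matter.
* **Water and soil.** Nursing calves drink 4 L per kg forage DM; finishers
  40.84 L/day and lactating cows 56.47 L/day (NRC temperature-averaged
  constants — seasonal temperature dependence is deliberately not
  modelled). Grazing animals ingest soil at 2.43% of forage DMI. The water
  class switches from nursing calf to finisher at weaning (day 240); no
  explicit switch day is published, and weaning is the natural boundary.

## The milk pathway

The dam's own kinetics are not modelled (no parameters exist for them);
instead a milk transfer factor of 0.0213 d/kg maps her *current daily*
PFOS intake (µg/day) to her fluid-milk concentration (µg/kg):
$C_\text{milk} = 0.0213 \times I_\text{cow}$. Her intake combines her
lactating-cow DMI (quadratic in calf age, constant term 11.697 kg), her
water (56.47 L/day) and her soil ingestion with the scenario's
cow-specific concentrations. The chained composition (cow intake →
transfer factor → milk concentration → calf fluid-milk consumption) keeps
units consistent (d/kg × µg/d × kg/d = µg/d). The chain, and the
intake-first update order, were fixed once by checking the generic
constant-ration run against its published endpoint (0.270 µg/kg ration →
0.501 µg/kg muscle; this package computes 0.507) and then frozen.

In the generic scenario the dam eats the same ration as the growing
animal — "total ration" is read as the whole herd's feed — so the nursing
phase is exposed through milk even though the calf eats no forage before
day 66.

## Weight-of-evidence half-life

Six literature half-life estimates (whole body 114.2, steer plasma 120,
heifer plasma 106, grouped muscle 165, serum 74.1, muscle 77 days) are
pooled by quality weights: exposure (single 1 / daily 3), ingestion type
(water 1 / food 3), tissue (blood 1 / muscle or body 3) and duration
(acute 1 / chronic 3), divided by a per-study divisor that limits the
contribution of studies reporting several tissues. Each row contributes
100 × its total weight points drawn from normal(half-life, SD) — 4200
points in all — giving a pooled 108.9 ± 40.5 days. Where a study reports
no SD, 20% of the value is used. Normal is chosen as the sampling family
because the evidence arrives as mean ± SD; negative draws (possible in
principle with a heavy-tailed row) are rejected and redrawn since a
half-life must be positive, and no additional truncation is applied before
pooling. The pooled mean necessarily sits at the weighted mean of the
table (108.66 by direct computation); the sampled value fluctuates around
it with an SE of about 0.6 days at 4200 points.

## Monte Carlo layer

Probabilistic runs draw each uncertain parameter from a normal
distribution truncated at its 5th and 95th percentiles (inverse-CDF
sampling), which keeps calculated fields physically plausible; intakes and
concentrations are additionally floored at zero and half-life draws at 0.1
day. Two sampling scopes mirror the spreadsheet-like row structure:

* **per-day** (redrawn every simulated day): half-life, daily gain, forage
  DMI (SD = 0.0013 × BW), milk production (CV 35.5%), cow DMI (CV 6.2%),
  soil and water intake, and — when `forage_cv > 0` — the day's forage
  concentration for both the animal and the dam (multiplicative CV,
  default 0.40, the within-field variation observed in field data).
* **per-iteration** (animal-level constants): birth weight, muscle:body
  ratio, muscle:serum ratio.

Scopes are configurable per parameter (`default_sampling_scopes()`);
per-day parameters largely average out over a 540-day trajectory, so the
output spread is dominated by the per-iteration partition parameters.

**The muscle:BW fraction is held at its mean by default** (scope
`"fixed"`, SD retained in the profile). Its uncertainty derives from the
same tissue-mass measurements that produce the muscle:body ratio: muscle
mass appears in the numerator of one quantity and the denominator of the
other, so sampling the two independently double-counts the same
measurement uncertainty and inflates the predicted herd spread. Two
observable consequences support fixing it: (i) with it fixed, the model's
95th-percentile outputs reproduce the published probabilistic endpoints
(0.190 µg/kg ration → p95 ≈ 0.50 µg/kg muscle; probabilistic BAF ≈ 2.6),
while sampling it independently inflates them by roughly a third; and
(ii) only with it fixed can the muscle:serum ratio (CV 20%) rank second
for the serum prediction, the published sensitivity ordering. Users who
prefer the fully independent treatment can set
`scopes["muscle_bw_fraction"] <- "per_iteration"`.

Sensitivity is ranked by Spearman correlation between per-iteration
parameter draws and the output concentration; per-day parameters are
summarised by their per-iteration mean draw, which understates their
leverage (each day's draw acts alone) but preserves the ordering of the
animal-level constants, which is the decision-relevant output. The
muscle:body ratio dominates the muscle prediction (ρ ≈ 0.99).

## Scenarios and the inverse problem

`build_generic()` is the constant-ration lifetime scenario: the herd's
feed carries one concentration, water and soil are PFOS-free, burden
starts at zero, slaughter at day 540. With zero initial burden the model
is linear in the exposure concentrations, so the deterministic inverse
problem (what ration yields 0.5 µg/kg muscle — the USDA screening level —
at slaughter?) is solved exactly by one unit-ration simulation and a
scaling, then verified by re-simulation to 10⁻⁶ relative error. The
probabilistic inverse (`regulatory_ration_limit(..., "p95")`) bisects on
the ration concentration until the Monte Carlo 95th percentile meets the
target, holding the random-number stream fixed across bisection steps
(common random numbers); bisection is preferred over a derivative-based
method because each evaluation is a stochastic percentile. Published
probabilistic endpoints are stated without fully specifying whether the
parameter distributions were active alongside the forage variation; both
configurations are runnable (`param_distributions = FALSE` keeps only the
forage CV), and the full-distribution configuration is the default and the
one that reproduces the published numbers.

`build_synthetic_history()` generates piecewise-constant feeding
histories — equal-length seasonal segments with uniform base
concentrations, day-to-day within-field noise (CV 0.40 by default) and a
terminal depuration period on clean feed — emulating the *structure* of
real farm case studies (seasonal feed-source changes, pre-slaughter
clean-feed periods). What it does not emulate: correlated day-to-day
weather effects, PFOS precursor loads (which make measured residues exceed
PFOS-only predictions), measured farm-specific concentration series, or
redistribution lags after abrupt feed changes. Tests passing on synthetic
histories therefore demonstrate mass-balance correctness and scenario
plumbing, not field-level predictive accuracy.

## Numerical choices and conventions

* Ages are integer days; trajectory row $d$ is the state at the end of the
  animal's $d$-th day of life, after elimination. Scenario day $d$ holds
  the concentrations in force during that day.
* The default `update_order = "intake_first"` applies elimination to the
  post-intake burden; `"eliminate_first"` is the alternative convention.
  The two differ by one day of elimination (≈0.6% at the default
  half-life). The steady-state burden under constant intake $I$ is
  $I f/(1-f)$ for intake-first and $I/(1-f)$ for eliminate-first, with
  $f = 0.5^{1/T}$; both are verified to 0.2% after 10 half-lives.
* Truncation quantiles default to (0.05, 0.95) and are profile fields.
* A seed is mandatory for every stochastic entry point; equal seeds give
  bit-identical results.
* Problem sizes used by the test-suite and acceptance computations: 1000
  Monte Carlo iterations over 540-day trajectories (the reference
  configuration), 4200-point half-life pools, and smaller n for pure
  plumbing tests. At n = 1000 the seed-to-seed SE of the 95th percentile
  is about 1–2% of its value.

## Known limitations

One compartment only: no liver/kidney/fat time courses, no redistribution
lag after exposure shifts, no dam kinetics behind the milk transfer
factor, PFOS only (no precursors or mixtures), no inhalation or dermal
routes, and 100% gut absorption unless overridden. Parameter draws are
independent (no correlation structure is published); the muscle:BW
default scope above is the one place that independence is deliberately
broken by fixing a parameter.

## A worked run

```{r example}
res <- simulate_dam(build_generic(ration_conc = 0.270, slaughter_day = 540))
res
bioaccumulation_factor(res$final_muscle_conc, 0.270)

mc <- run_monte_carlo(build_generic(0.190, 540), n = 1000, seed = 1,
                      forage_cv = 0.40)
mc
head(sensitivity_ranking(mc), 3)
```
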