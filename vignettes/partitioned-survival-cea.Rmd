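---
title: "Methods: a partitioned-survival cost-effectiveness pipeline for advanced biliary tract cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned-survival CEA pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partsaCEA)
```

## The decision problem

`partsaCEA` implements a multinational cost-utility comparison of first-line
pembrolizumab plus gemcitabine/cisplatin against gemcitabine/cisplatin alone
in advanced biliary tract cancer (ABTC), from the healthcare-system
perspective of China, Japan, the United States and Switzerland. The clinical
evidence base is a large two-arm randomized trial (533 vs 536 patients;
median OS 12.7 months and median PFS 6.5 months in the immunochemotherapy
arm). Because trial-level individual patient data (IPD) are not public, the
pipeline works the way published economic evaluations do: survival curves
are digitized from the published Kaplan–Meier figures, pseudo-IPD are
reconstructed from the digitized coordinates and the numbers-at-risk tables,
parametric distributions are fitted and extrapolated, and a three-state
partitioned survival model converts the curves into discounted costs and
QALYs per arm.

## The partitioned survival model

The model has three states — progression-free (PFS), progressed disease
(PD), and death — with occupancy read directly off the two survival curves
rather than through transition probabilities:

$$\pi_{PFS}(t) = \min\{S_{PFS}(t),\, S_{OS}(t)\},\qquad
  \pi_{death}(t) = 1 - S_{OS}(t),\qquad
  \pi_{PD}(t) = S_{OS}(t) - \pi_{PFS}(t).$$

The `min` clamp guarantees non-negative PD occupancy when extrapolated
curves cross. Time runs in 21-day cycles over a 10-year horizon; the cycle
count is `ceiling(10 * 365.25 / 21) = 174` so the final partial year is
covered rather than truncated. By the horizon essentially all patients have
died under any of the fitted families, so the horizon choice is not a
binding truncation.

**Evaluation convention.** Occupancy is evaluated at each cycle *start*
(`t_i = i * 21/365.25 * 12` months, `i = 0 … 173`), the common default of
the dedicated modeling packages; `model_settings(half_cycle_correction =
TRUE)` switches to midpoint evaluation so the discretization sensitivity
can be quantified directly. Costs and QALYs accruing in cycle `i` are
discounted by `(1 + r)^(-i * 21/365.25)`, i.e. the first cycle is
undiscounted.

**Cost accrual.** Per cycle, PFS occupants accrue the first-line regimen
(pembrolizumab 200 mg flat, once per cycle, at most 35 cycles; gemcitabine
1,000 mg/m² and cisplatin 25 mg/m² on days 1 and 8, cisplatin capped at 8
cycles) plus an administration cost; all alive patients accrue an
examination cost; PD occupants accrue a fixed second-line mixture
(FOLFOX : post-progression immunotherapy : best supportive care =
47% : 0.9% : 52.1% in the experimental arm, 49% : 1.1% : 49.9% in the
control arm); incremental deaths accrue a one-time end-of-life cost; and
the whole cohort accrues the four grade-≥3 adverse-event management costs
(neutropenia, leukopenia, thrombocytopenia, anemia; probability × cost)
once, in the first cycle only. QALYs accrue as
`21/365.25 × (u_PFS π_PFS + u_PD π_PD)` per cycle.

**Dosing and vials.** mg/m² doses are scaled by the country's mean body
surface area and rounded *up* to whole vials per administration (no vial
sharing) — the conservative standard when the source analysis is silent.
Vial sizes are explicit per drug and country (cisplatin is a 50 mg vial in
Japan but 10 mg elsewhere; fluorouracil 500 mg in Switzerland vs 250 mg
elsewhere), so no shared pack size is ever assumed.

**ICER and dominance.** `run_cea()` reports
`ICER = ΔCost / ΔQALY` when the ratio is meaningful and a dominance status
otherwise: `dominant` (cheaper, more effective), `dominated` (costlier,
less effective), `undefined` (|ΔQALY| < 1e-12). Serialized tables carry
these as explicit tokens, never as numbers.

## Design choices where the source analysis is open

Several inputs of the published analysis are not pinned down by its text;
the package makes each choice explicit, once:

* **"Disease management cost"** is mapped to the tabulated
  *Administration* per-cycle cost — the input table has no other candidate
  row.
* **Second-line duration.** A partitioned model cannot track time in
  state without tunnel machinery the source never mentions, so second-line
  costs accrue for the entire PD occupancy at the fixed mixture weights.
  This is likely conservative (it overstates late second-line drug cost).
* **FOLFOX dosing** is not stated in the source; the package uses standard
  mFOLFOX6 (oxaliplatin 85, leucovorin 400, fluorouracil 2,800 mg/m² per
  14-day course) prorated ×1.5 onto the 21-day model cycle, overridable
  via the config key `folfox_doses`.
* **Post-progression immunotherapy** (agent unnamed in the source) is
  costed as one 200 mg pembrolizumab administration per cycle
  (`io_dose_mg`), so price-reduction scenarios propagate to it
  automatically.
* **AE disutilities** are mentioned by the source but never tabulated; the
  config hook `ae_disutility` exists and defaults to 0 in the base case.
* **AIC vs BIC.** Both criteria are computed; when they disagree the
  package selects by AIC by default with an explicit `criterion`
  argument, and ties resolve to fewer parameters, then to a fixed family
  order (exponential < weibull < gamma < loglogistic < lognormal) so
  selection is fully deterministic.
* **Currency.** All inputs are USD as published; the source's exchange
  rates are carried as config metadata and never applied in computation.

## Pseudo-IPD reconstruction

`reconstruct_ipd()` implements the interval-by-interval allocation scheme
of Guyot et al. (2012), the de-facto standard for this task: within each
numbers-at-risk interval, the censoring count is solved iteratively so the
running at-risk count matches the printed value at the next boundary,
censoring times are spread uniformly across the interval, and event counts
at each digitized drop are chosen to match the digitized survival ratios.
An optional global event total is enforced exactly by relabeling the
latest event/censoring records. Digitized coordinates are cleaned before
use — survival clipped to [0, 1] and made non-increasing by an isotonic
pass — with violations beyond a 0.005 digitization tolerance rejected as
errors. If no risk table is available the code falls back, with a loud
warning, to a no-censoring assumption before the last plotted time.

Information lost at digitization is irrecoverable between clicks: all
events in a gap are necessarily placed at the next click. Digitization
grids should therefore include the time-axis tick marks (where the risk
table is printed and where accuracy is assessed); `export_digitized()`
does this by default. Under that convention the round trip
generate → digitize (30 clicks) → reconstruct reproduces the original KM
curve within 0.02 absolute at all risk-table times for n = 200 arms across
20 seeds (part of the test suite).

## Parametric fitting and extrapolation

Five families are fitted to each endpoint and arm by maximizing the
right-censored log-likelihood
`Σ_events log f(t) + Σ_censored log S(t)`:
exponential, Weibull, gamma (survival via the regularized incomplete gamma
function), log-logistic and lognormal. Optimization runs on the
log-parameter scale (positivity without constraints) from deterministic
method-of-moments starts — Nelder–Mead, then BFGS, then a guarded Newton
polish on the numerical score, because derivative-free search alone stalls
at the likelihood's double-precision noise floor (~1e-8 relative in the
parameters; the polish reaches ~1e-9, verified against the exponential
closed form `events / total time`). The covariance of the estimator is the
inverse observed information (numerical Hessian) on the optimization
scale, retained for probabilistic sensitivity analysis. Medians use closed
forms where they exist and the gamma quantile function otherwise; a
bisection oracle cross-checks them in the tests, and `flexsurv` serves as
an independent likelihood cross-check (it is never the implementation).

## The synthetic trial generator

There is no deposited dataset, so `generate_arm()` emulates the trial
inputs. Per subject a PFS time is drawn (exponential by default — a median
is the only printed calibration target, and the exponential is fully
determined by one: rate `log(2)/median`), and OS is constructed as
PFS plus an exponential post-progression survival, so PFS ≤ OS holds by
construction. The post-progression rate is solved numerically
(`uniroot` on the hypoexponential survival function) so the *true* OS
median equals its target exactly. Each subject receives a single censoring
time — administrative at 30 months, or uniform dropout before that with
probability 0.05 — applied to both endpoints consistently. Sampling is by
inverse-CDF transform of uniforms drawn in fixed order, so times respond
monotonically to the arm specification's medians at a fixed seed. A Weibull PFS option
exists for model-selection tests.

Defaults are the study conditions: experimental arm n = 533 with medians
OS 12.7 / PFS 6.5 months. The source prints **no control-arm medians**;
the shipped control defaults (n = 536, OS 10.9, PFS 5.6 months) are
synthetic calibration values chosen once so that the experimental arm
dominates on survival, and are documented as not sourced from the trial.
The 30-month administrative censoring and 5% dropout produce risk tables
with realistic attrition for reconstruction tests.

At n = 533 the KM median of a single generated cohort has a sampling
standard deviation of roughly 0.6 months for OS (0.4 for PFS); the
calibration is unbiased, but any single-seed check of the medians should
be read with that noise in mind.

What the generator does *not* emulate: subgroup or biliary-subtype
structure, covariate-dependent hazards, non-proportional effects, or
delayed-separation immunotherapy hazard shapes. Passing tests therefore
demonstrate the pipeline's correctness and calibration on well-behaved
survival data, not fidelity to every feature of the real trial curves —
which is also why headline economic outputs are reproduced at the level of
the qualitative conclusion (ICER far above every national
willingness-to-pay threshold) rather than to the published digit.

## Uncertainty analysis

* **One-way DSA** (`one_way_dsa()`): each parameter is set to ±20% of base
  (probabilities and utilities capped at 1) with all others at base, the
  model rerun twice, and bars sorted by width (tornado order). Joint
  constraints such as `u_PD ≤ u_PFS` are intentionally *not* re-validated
  while varying one parameter at a time — standard DSA practice.
* **PSA** (`run_psa()`, default 5,000 draws): cost parameters draw from
  gamma and probabilities/utilities from beta distributions matched by
  moments to the base value and a standard error derived from the ±20%
  range treated as a 95% interval (`sd = (high − low)/(2 × 1.96)`), since
  the source states distribution families and ranges but no standard
  errors. Survival-curve parameters are drawn (by default) from the
  multivariate normal implied by each fit's covariance on the optimization
  scale — the source does not say whether its PSA varied the curves, so a
  `vary_survival = FALSE` flag freezes them. Gamma/beta moment matching is
  mean-preserving, so the PSA mean of ΔCost tracks the base case.
* **CEAC** (`ceac()`): fraction of draws with positive net monetary
  benefit `λ·ΔQALY − ΔCost` over a WTP grid (default 0–1.2M USD/QALY,
  201 points, covering all four national thresholds).
* **ICE quadrants** (`ice_quadrants()`): boundary points (a zero delta)
  are assigned to the positive side of that axis; the counts always
  partition the draws.
* **Price scenarios** (`scenario_price_grid()`,
  `price_threshold_for_wtp()`): the pembrolizumab vial price is scaled by
  (1 − r) everywhere it is costed; the threshold search brackets on the
  scenario grid then bisects to 0.1%, and is verified by re-evaluation in
  the tests. ΔQALY is invariant under price scenarios, so the ICER is
  strictly decreasing in r.

## Numerical choices and degenerate inputs

* Occupancy conservation `π_PFS + π_PD + π_death = 1` holds to 1e-12 by
  construction and is asserted over all 174 cycles in the tests.
* Vial counts use `ceiling(dose/vial − 1e-9)` to avoid spurious extra
  vials from floating-point representation of exact multiples.
* `select_distribution()` refuses to compare fits with different `n_obs`.
* Zero events is a hard error for fitting; an all-censored KM curve is
  the constant 1.
* Empty result sets serialize as header-only files; results CSVs carry
  full double precision (17 significant digits) and round-trip to 1e-9.
* Reconstruction keeps all times strictly positive (an event digitized at
  t = 0 is moved to a vanishing positive time).

## Problem sizes in the shipped checks

The test suite and acceptance script run at desk scale by design: arm
sizes 100–533 subjects, 30-click digitization grids, risk tables every 6
months, 20-seed loops for stochastic properties, and one 5,000-draw PSA
(the published draw count). Parameter-recovery checks use n = 2,000
(Weibull) and n = 5,000 (exponential bias) samples. The full pipeline —
two arms, digitization, reconstruction, twenty maximum-likelihood fits,
AIC selection and a 174-cycle model — runs in a few seconds.

## Known limitations

* The exact fitted survival parameters of the source analysis were
  published only in an unavailable supplement; the synthetic calibration
  reproduces medians, not curve shapes, so absolute costs and QALYs are
  indicative rather than replications.
* Control-arm survival calibration is asserted, not sourced (see above);
  every end-to-end quantitative claim that depends on the control curves
  inherits that approximation.
* Second-line costing over the whole PD occupancy overstates long-tail
  costs relative to a time-limited course.
* No budget-impact, EVPI, cure-fraction, waning, or covariate modeling;
  those are out of scope by design.
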