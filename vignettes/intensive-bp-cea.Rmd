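---
title: "Methods: microsimulating intensive blood-pressure control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsimulating intensive blood-pressure control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprintcea)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical conventions, and the
design decisions taken where the published record leaves the design open.

## The question

SPRINT showed that treating high-risk adults to a systolic blood pressure
(SBP) below 120 mm Hg, rather than below 140 mm Hg, reduces cardiovascular
events and mortality. Whether a health system should adopt that target
depends on (a) how many people would qualify and (b) whether the extra
drug costs and serious adverse events (SAEs) are offset, over remaining
lifetimes, by prevented myocardial infarctions (MI), strokes, heart
failure (HF) and deaths. The package answers both with a screening module
over a survey-style population and an individual-level cost-effectiveness
microsimulation comparing the two treatment goals.

## Eligibility screen

Criteria are applied in a fixed order so a *first failed step* can be
reported, but they are conjunctive — permuting them changes the recorded
failure step, never the eligibility flag (pinned by a test):

1. age ≥ 50 years;
2. SBP 130–180 mm Hg. Surveys rarely record antihypertensive *class
   counts*, so the default is this relaxed window on any number of
   classes; `strict_med_classes = TRUE` restores the original
   medication-stratified windows (130–180 on ≤ 1 class, 130–170 on ≤ 2,
   130–160 on ≤ 3, 130–150 on ≤ 4);
3. at least one high-CVD-risk condition: coronary heart disease history;
   eGFR 20–59 mL/min/1.73 m²; 10-year general-CVD risk ≥ 15%; age ≥ 75.
   All four are evaluated for every individual even after one is met, so
   the composition of risk conditions can be tabulated;
4. no exclusion: diabetes, stroke history, heart failure, end-stage renal
   disease.

All printed bounds are read inclusively ("130–180", "20 to 59", "≥ 15%"),
and tests pin the boundary semantics at 130/180 mm Hg, eGFR 20/59, risk
0.15 and ages 50/75.

**Risk score.** We use the *continuous* (Cox-model) form of the
sex-specific Framingham general-CVD function, not the points chart:
`risk = 1 − S₀^exp(lp − lp̄)` with the linear predictor on log age, log
SBP (separate treated/untreated coefficients), log total and HDL
cholesterol, smoking and diabetes. The published equation was derived for
ages 30–74, so ages are clamped to that range for the score; this is
immaterial for screening because age ≥ 75 is an eligibility condition in
its own right.

**Kidney function.** The authors do not state which eGFR equation they
used; we default to CKD-EPI 2009 (creatinine, age, sex, no race term) as
the contemporary standard. A recorded eGFR value always wins over
derivation from creatinine (passthrough precedence).

**Funnel.** `build_funnel()` reports, for each sequential criterion and
for the usual subgroups (hypertensive — SBP ≥ 140 or DBP ≥ 90 or on
treatment — non-hypertensive with SBP 130–139, treated, untreated), the
survey-weighted proportion with a Wald 95% CI and the represented
millions. The variance estimator is the linearised ratio-estimator form
`Σw²(y − p̂)² / (Σw)²` with no stratification or finite-population
correction: the survey's design variables are not recoverable from the
published record, so design-based corrections would be invented
precision.

## The microsimulation

### States and cycle convention

Nine states: event-free on treatment; acute and post (chronic) states for
MI, stroke and HF; CVD death; non-CVD death. One cycle is one year. The
convention, chosen once and pinned by tests, is:

* the state labels the year being lived; a year accrues life-years,
  utility and cost if the individual is alive at its start;
* a single categorical draw at the end of each year over
  {MI, stroke, HF, CVD death, non-CVD death, continue} decides the next
  year. One draw avoids the order-of-draw bias that sequential Bernoulli
  draws would introduce among competing risks. If the event probabilities
  sum past 1 the row is rate-normalised and a warning is emitted once;
* a death draw ends accrual — death years accrue nothing. In a constant-
  hazard toy model expected life-years are therefore
  `E[LY] = Σₖ (1−q)^k` (≈ 1/q), which is what the closed-form oracle
  tests assert;
* no half-cycle correction. The life-table expectancy used for validation
  (`life_table_expectancy()`) applies the same whole-year convention, so
  the self-consistency check is exact up to Monte-Carlo error;
* acute states last exactly one cycle and then mature into their post
  state. The draw *out of* an acute year uses elevated first-year
  probabilities (`secondary_y1`, `cvd_death_y1`): this is the
  multiple-events-in-the-first-year pathway, e.g. a stroke in the year
  after an MI. A same-type recurrence within the acute year is not
  modelled as a separate event — without that exclusion an acute state
  could repeat back-to-back, contradicting the one-cycle acute
  convention; the excluded mass falls to "continue";
* the horizon is lifetime, implemented as death or an age cap of 100
  (bounds runtime; survival beyond 100 contributes negligibly at these
  hazards).

### Hazards

Primary MI/stroke/HF incidence is risk-equation-driven and recomputed
every cycle as age advances; all other baseline covariates are frozen (no
covariate-updating model is published). The exact published event-specific
equations are not public, so the default configuration splits the
10-year general-CVD risk into MI/stroke/HF by configurable shares
(0.30/0.45/0.25 — stroke-heavy, as in Chinese cohorts), annualised by the
constant-hazard transform `1 − (1−p₁₀)^(1/10)`. The coefficient tables
live in the parameter object, so a different equation is a configuration
change, not a code change. `params$fixed_primary` bypasses the equations
with constant probabilities; toys and validation use this.

Background non-CVD mortality is the life-table all-cause probability
times `1 − cvd_death_fraction` (default 0.40, the approximate CVD share
of deaths in China); ages past the table use its terminal row. The
default life table is a synthetic Gompertz calibrated to whole-year
remaining life expectancy at 45 of ~31 years (men) and ~36 years
(women); real tables load from CSV.

Treatment effects are relative risks applied in the *hazard domain*,
`1 − (1−p)^rr`, never as probability multiplication: results stay in
[0, 1) for any rr and the operation composes multiplicatively (both
properties are tested). Under the intensive strategy the RRs apply to the
primary incidences (per type), to every CVD-death probability, to
secondary-event components (per resulting type), and to the SAE
probability. Defaults are SPRINT-flavoured: MI 0.83, stroke 0.89, HF
0.62, CVD death 0.57, SAE 1.88.

SAEs are drawn independently each alive year and — by assumption, as in
the source analysis — do not alter event risks. They only carry cost and
a utility penalty.

### Common random numbers

Each individual owns a deterministic uniform stream derived from
(master seed, individual index, run index), with event and SAE draws
interleaved so the first *t* cycles' draws do not depend on the horizon
length. Both arms replay identical streams: with all RRs at 1 and equal
arm costs every per-individual delta is *exactly* zero (tested), and with
only the CVD-death RR lowered every simulated life is at least as long
under intensive treatment — the death boundary can only move later along
a fixed uniform sequence.

## Economics

All monetary values are 2017 international dollars; Int$1.00 = 3.54 yuan
at purchasing power parity. Per year: strategy-specific drug cost (Int$
361 intensive / 178 standard; drugs continue after events), acute
hospitalisation cost in acute years (MI 7,500; stroke 5,500; HF 4,500),
chronic annual cost in post years (800/1,300/1,000), SAE cost (500) only
in SAE years. Death years accrue nothing — the fatal event's cost was
accrued in its acute year.

Utilities: age–sex baseline for a hypertensive population (0.93 → 0.79
for men, 0.92 → 0.76 for women across 10-year bands from 45), times a
state multiplier (acute: MI 0.80, stroke 0.65, HF 0.70; post: 0.90,
0.78, 0.76). An SAE year spends one week at utility 0.5:
`u − (u − 0.5)·(7/365.25)`, the only reading of the one-week rule
consistent with an annual-cycle model; the adjustment never raises
utility when the base is ≥ 0.5. Costs, QALYs discounted at 3%/year,
cycle 0 undiscounted.

The cost, transition-probability and utility defaults are **placeholders
with realistic magnitudes**, clearly not estimates of the original
study's unpublished supplementary tables; every analysis function takes
the parameter object explicitly and YAML/JSON round-trips are tested.

## Synthetic populations

`generate_population()` stands in for restricted survey microdata. It
reproduces the features the screen and simulation actually depend on:

* sex-stratified truncated-normal marginals for age, SBP, DBP, total and
  HDL cholesterol, creatinine;
* a Gaussian copula over those variables with the Pearson latent
  correlation chosen as `2·sin(π·ρₛ/6)` so the *requested Spearman rank
  correlations* are attained (quantile transforms are monotone, so rank
  correlation survives truncation); age–SBP defaults to 0.30;
* treatment status from a logistic model on realised age and SBP
  (intercept −1.8, 0.03/year, 0.025/mm Hg), giving the
  age–SBP–treatment dependence the screen needs and a low overall
  treatment rate;
* binary flags (smoking — strongly male-skewed, diabetes, histories,
  ESRD) at sex-specific prevalences; HDL clamped below total cholesterol;
* log-normal survey weights (sdlog 0.5), mean-normalised to 1 and scaled
  by a represented-population factor, so national projections are
  `proportion × scale` and testable.

It does **not** emulate multistage sampling design, nonresponse
adjustment, item missingness (beyond the read-time missing-SBP rule),
within-household clustering, or secular trends. A green test on synthetic
data therefore establishes the *correctness of the machinery* —
weighting, screening logic, engine behaviour — not the original survey's
national estimates, which additionally depend on the real microdata.

Reading foreign CSVs: only SBP missingness is handled (rows dropped and
counted, mirroring the published exclusion flow); all other fields are
required after read, and a non-numeric SBP is a row-level error naming
the row.

## Sensitivity analysis conventions

* **One-way (tornado):** each parameter to its low/high bound with all
  else at base, identical streams for every run, rows ordered by absolute
  ICER spread. With common random numbers a zero-width range reproduces
  the base ICER bit-for-bit. Dominant/dominated outcomes are ordered as
  −∞/+∞ but labelled, never averaged.
* **Probabilistic:** support-matched families — Beta for probabilities
  and utilities, Gamma for costs, log-normal for relative risks
  (mean-preserving `meanlog = log(m) − σ²/2`) — with independent draws;
  no correlation structure is published, so none is invented. Percentile
  (2.5–97.5) intervals summarise ΔC and ΔQ; ICER uncertainty is reported
  as CEAC probabilities, not an ICER interval, because the ratio's
  distribution is ill-behaved around ΔQ = 0.
* **CEAC:** `P(λ·ΔQ − ΔC > 0)` on a threshold grid; the 1× and 2× GDP
  probabilities in `cea_summary()` are exactly the curve's values at
  those thresholds (internal-consistency test).
* **ICER quadrants:** ratio only in the north-east quadrant; "dominant"
  requires ΔQ > 0 with ΔC ≤ 0; "dominated" requires ΔQ < 0 with ΔC ≥ 0;
  the south-west quadrant reports the ratio with an explicit tag; ΔQ = 0
  yields "equivalence" (ΔC = 0) or "undefined_ratio". All nine sign
  combinations are pinned.
* **Subgroups** (sex, age < 75 / ≥ 75, SBP 130–139 / ≥ 140) re-run the
  whole pipeline independently with seeds derived from the master seed —
  not post-hoc tagging of a pooled run — because paired subgroup
  uncertainty is then self-contained.

## Numerical choices and degenerate inputs

* Risk-equation output clamped to (0, 1) by 1e-12 margins; a cumulative
  risk of 1 is rejected (infinite hazard) rather than silently capped.
* Competing-probability rows are rate-normalised only when their sum
  exceeds 1, with a single warning per run.
* Zero-SD marginals and {0, 1} prevalences are legal and produce
  deterministic populations; a correlation matrix is accepted iff
  symmetric, unit-diagonal and PSD (eigenvalue tolerance −1e-8), sampled
  through an eigendecomposition factor so semidefinite matrices work.
* Every seeded routine restores the caller's RNG state, so package calls
  do not perturb user scripts.
* Seeds derived from the master seed stay below 2³¹ via modular
  arithmetic in double precision.

## Validation strategy

Deeper than unit tests, three independent oracles back the engine: an
analytic matrix-power cohort model for time-homogeneous configurations
(hand-coded in the test helpers, sharing no engine code); closed-form
geometric life expectancy for constant hazards; and the life table
itself when all CVD hazards are switched off. The common-random-number
null and an injected-RR recovery experiment (the annual-hazard ratio
implied by the two arms' 5-year mortality estimates the injected 0.75
exactly in expectation) complete the acceptance suite, alongside
arithmetic targets fully determined by published numbers.

## Known limitations

* Parameter defaults are placeholders; headline ICERs under them are
  illustrative, not replications.
* Risk-equation covariates other than age are frozen at baseline; no
  covariate drift, adherence dynamics or within-year event timing.
* SAEs are pooled, not subtype-specific, and risk-neutral by assumption.
* Long-term renal outcomes are not modelled.
* The weighted-variance estimator ignores the survey's design strata and
  clusters; CIs on national projections are approximate.
* Whole-year accrual (no half-cycle correction) biases life expectancy
  about half a year high relative to mid-year conventions; the validation
  comparator uses the same convention, so the comparison is fair, but
  absolute values carry that convention.
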