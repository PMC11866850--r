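---
title: "Methods: physical activity, frailty, mortality and life expectancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physical activity, frailty, mortality and life expectancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and design

`frailpa` implements the full analytical chain of a cohort study asking how
device-measured physical activity and deficit-accumulation frailty jointly
shape all-cause mortality and residual life expectancy in middle-aged and
older adults. Because the motivating data (a UK-Biobank-scale accelerometer
cohort and national mortality schedules) are access-controlled, the package
pairs every analysis stage with a synthetic cohort generator that emulates
the study design with known ground truth, so that every stage is testable
end to end without any data download.

The pipeline stages, each an exported function, are:

1. **Synthetic cohort** — `cohort_config()`, `generate_cohort()`,
   `generate_epochs()`, `simulate_survival()`, `inject_missingness()`.
2. **Frailty index** — `default_deficit_codebook()`, `code_deficits()`,
   `compute_fi()`, `classify_fi()`, `add_frailty_index()`.
3. **Exposures** — `assess_wear_validity()`, `aggregate_epochs()`,
   `assign_tertiles()`.
4. **Survival models** — `fit_cox()`, `joint_group_hrs()`,
   `rcs_dose_response()`, `lrt_interaction()`, `reri()`, `ph_check()`.
5. **Life expectancy** — `build_life_tables()`, `le_difference()`,
   `bootstrap_le_ci()`.
6. **Orchestration** — `pipeline_config()`, `run_pipeline()`.

# The synthetic cohort generator

The generator's defaults are the study conditions, not free dials: 78,508
participants, 55.5% women, age 62.0 (SD 7.8) truncated to 45–80, activity
exposure means and SDs equal to the published cohort descriptives (TVPA
38.4 ± 11.9 mg; MVPA 0.517 ± 0.447, LPA 5.27 ± 1.58, ST 7.98 ± 1.60
h/day), about 2.9% deaths over a median 6.9 years of follow-up, and the
published covariate category mixes.

**Exposures.** The four exposures are drawn through a Gaussian copula with
zero-truncated normal marginals. The untruncated location and scale of each
marginal are solved by moment matching (`truncnorm_params()`) so that the
*truncated* distribution has exactly the target mean and SD — material for
MVPA, where roughly 12% of an untruncated normal would fall below zero. The
copula correlations (TVPA–MVPA 0.70, TVPA–LPA 0.60, TVPA–ST −0.40,
MVPA–LPA 0.30, MVPA–ST −0.25, LPA–ST −0.35) are a plausible choice for
wrist-accelerometer exposures; the source study shows its correlation
structure only graphically, so these are design defaults, not published
values. MVPA + LPA + ST is capped at the 16-hour awake window by
truncating ST to the remainder; this shifts the realised ST mean about
0.1–0.2 h below its marginal target, which we accept as the price of a
physically coherent time budget.

**Epoch emission.** Each participant contributes 3–7 complete wear days
(mean ≈ 6.7) of 2,880 30-second epochs starting on a random weekday, so
weekend-coverage filters are exercised. Awake-window epochs carry behaviour
labels whose daily counts equal the participant's quantised MVPA/LPA/ST
hours (quantisation to whole epochs is why the cohort's summary columns are
exact multiples of 30 s); remaining awake epochs are labelled sleep (naps),
and placement within the window is random. ENMO per epoch is a
behaviour-scaled lognormal draw rescaled per participant so the awake-window
ENMO mean equals the drawn TVPA *exactly*; the epoch→summary round trip is
therefore exact by construction, and tests assert it to within one epoch.
Epochs are generated in fixed blocks of 250 participants with block seeds
derived from the cohort seed, making emission identical however the work is
chunked and allowing tens of thousands of participants to be streamed
through `summarise_epoch_exposures()` without holding ~10^8 rows in memory.

**Frailty deficits.** A latent liability (standard normal, correlated −0.35
with the latent TVPA score, so frailer participants move less) drives 49
deficit items through logistic models with fixed, evenly spread intercepts
and loadings plus an age slope of 0.035/year. The intercept level and
loading spread were set once so that the default cohort reproduces the
published frailty mix (≈63% robust, ≈32% pre-frail, ≈4–5% frail) and a
right-skewed FI; they are part of the generator's definition.

**Survival.** The baseline hazard is Gompertz in attained age with shape
log(2)/8 per year (doubling roughly every 8 years, typical of adult
all-cause mortality). The level is solved at generation time by `uniroot`
so that the *expected* death fraction over the realised ages, group
effects and censoring horizons equals the 2.9% target; entry is uniform
over a 2.9-year accrual window with administrative censoring 8.35 years
after its start, giving a median follow-up of ≈6.9 years. True group
effects are injected as log hazard ratios on the nine FI-by-TVPA-tertile
groups (defaults spanning 0.6–3.0, reference robust × tertile 1) plus a
0.4 log-HR male excess; the injected linear predictor is returned as
ground truth for parameter-recovery tests. Follow-up is recorded in whole
months (ceiling), which intentionally produces tied event times.

**What the generator does not emulate.** Raw triaxial signal, device
calibration and non-wear artefacts, informative (non-MCAR) missingness,
seasonality of behaviour, and confounding between covariates and either
exposure or outcome: covariates are drawn independently of survival, so
adjusted and unadjusted effect estimates coincide in expectation. Passing
tests therefore demonstrate the correctness of the statistical machinery
under the emulated design, not robustness to confounding structures the
generator never creates.

# Frailty index

Deficits are coded per a 49-item codebook: binary items score 0/1, ordinal
items map their severity levels onto equally spaced scores in [0, 1]
(the published item-level mapping table is not reproduced here, so the
default codebook is a structurally faithful stand-in and can be replaced
via `read_deficit_codebook()`). The FI is the mean deficit score; by
default any missing item marks the participant incomplete (they are
excluded by the pipeline's complete-FI rule, mirroring the study), with an
optional `min_fraction_scored` quorum mode for reuse outside this design.
Categories use robust ≤ 0.12 < pre-frail < 0.24 ≤ frail; both boundary
values go to the outer categories, matching the anchors printed with the
category names.

# Exposure derivation

TVPA is the mean ENMO over awake-window epochs (default 06:00–22:00,
half-open) pooled across valid days — pooling rather than day-means of
day-means is a declared choice; the difference is second order.
MVPA/LPA/ST are mean daily hours in epochs carrying the respective label
inside the window; sleep-labelled epochs inside the window count toward
the ENMO mean (TVPA is defined by clock time) but not the behaviour hours.
A day is valid when at least 75% of its 24 h is covered (a conventional
wear-time QC threshold; the exact figure is configurable and only relative
behaviour matters), and a record is valid with ≥3 valid days and any
Saturday or Sunday data. Tertiles cut at the sample's 33.3/66.7
percentiles with ties resolving to the lower tertile; tertile 1 is always
the reference.

# Survival modelling

All models are Cox proportional-hazards fits on the month timescale with
the Efron tie approximation (month resolution guarantees heavy ties; the
source study does not state its tie handling). Mutual adjustment follows
the stated rule: MVPA and LPA models add ST, the ST model adds MVPA, the
TVPA model adds nothing. Assessment centre enters as an ordinary
categorical covariate rather than a stratum. A categorical level with no
events, or any missing modelled value, is a hard error rather than a
silent drop.

The joint analysis codes the nine FI × tertile groups as indicators
against robust × tertile 1 and reports Wald 95% intervals. Dose–response
curves use a restricted (natural) cubic spline with four knots at the
5/35/65/95th percentiles of the analysis sample — computed within the
frailty stratum when the curve is stratified, since the stratified curves
are per-category — with the 5th percentile as the reference
(HR = 1 exactly) and pointwise Wald bands; the basis is linear beyond the
boundary knots by construction. Multiplicative interaction is a
likelihood-ratio test of the cross-product terms; additive interaction is
RERI = HR11 − HR10 − HR01 + 1 with a seeded parametric bootstrap
(β* ~ MVN(β̂, Σ), percentile 2.5/97.5) as the default interval and the
delta method as an option — the bootstrap was preferred because the
life-expectancy stage needs the same machinery anyway. Proportionality is
checked by score tests of the scaled Schoenfeld residuals against
event-time rank. α = 0.05 two-sided throughout, with no multiplicity
correction, as in the source design.

# Life expectancy

Group life tables from age 50 to 100 combine three inputs: a sex- and
age-specific population mortality schedule, sex-specific group hazard
ratios, and observed sex-specific group prevalences. The reference-group
rate is back-calculated by prevalence-weighted normalisation,
`m_ref(a) = m_pop(a) / Σ_g p_g hr_g`, the unique construction under which
the prevalence-weighted group rates reproduce the population schedule
exactly at every age (asserted at machine precision in tests). Conversions
are declared conventions: `q = 1 − exp(−m)`; person-years
`L(a) = l(a)(1 − q(a)/2)` (mid-interval deaths, a_x = 0.5); a closed
cohort with `q(100) = 1`, so in the zero-rate limit residual life
expectancy tends to 50.5 years (50 full years plus the terminal half
year). Hazard ratios are applied age-constant within sex; an age-band HR
table would slot into the same engine but is not a default. Uncertainty is
propagated by parametric bootstrap over the group coefficients (default
10,000 runs, percentile intervals, prevalences held fixed); a non-PSD
coefficient covariance is projected onto the PSD cone with a warning. The
packaged population schedule is synthetic (Gompertz with national-level
parameters, labelled as such) so nothing is downloaded.

The published headline results (e.g. ≈3-fold mortality for frail ×
least-active participants, ~10-year life-expectancy deficits in frail men)
require the restricted cohort and official rate schedules; they are not
reproducible from this package and are not claimed by it. What the package
reproduces, and what its tests assert, are the design-level descriptives
of the default generator and the frequentist calibration of its own
procedures.

# Numerical and testing choices

Problem sizes in the test suite were chosen to give tight Monte-Carlo
error at desk scale: generator calibration uses the full 78,508-person
cohort (no epochs) plus a 10,000-person epoch subsample for the exposure
means; joint-group recovery uses 500 replicates of n = 5,000 with an
event fraction (~20%) high enough that every FI × tertile cell retains
events — the default 2.9% death rate would leave ~2 events in the rarest
cell and meaningless Wald intervals; bootstrap coverage uses 400
replicates of 1,000-run bootstraps; the interaction type-I error uses 500
null replicates at n = 2,000. Brute-force partial-likelihood maximisation
on tie-free toy datasets serves as the independent oracle for the Cox
core, and closed-form geometric sums for the life-table engine.

# Known limitations

The deficit codebook is a structural stand-in, not the published item
list. Covariates do not confound exposure or outcome in the generator.
Missingness is MCAR only. Hazard ratios in the life tables are
age-constant within sex. Competing risks, time-varying coefficients,
age-as-timescale models and cause-specific mortality are out of scope.
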