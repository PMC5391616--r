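---
title: "Updating and evaluating a ten-year stroke risk score: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Updating and evaluating a ten-year stroke risk score: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokesynth)
```

## The problem

Established stroke risk equations such as the Framingham stroke risk score
(FSRS) predict an individual's ten-year probability of a first stroke from a
short list of clinical covariates, but omit several risk factors with good
literature support (ethnicity, exercise, adiposity measures, HDL cholesterol,
hormone replacement therapy).  Refitting a joint model would require a new
cohort measured on all covariates and followed for a decade.  *Synthesis
analysis* sidesteps this: it updates an existing risk equation with
literature-reported relative risks, standardized against a reference
population, without any refitting.  The package implements that update and a
full censored-data evaluation suite — discrimination, calibration and
reclassification — plus a cohort simulator with a closed-form risk oracle so
every stage can be validated against known ground truth.

## Baseline model

A `cox_risk_model` stores, per sex, per-unit log-hazard coefficients
$\beta$, centring values $\bar x$, and the baseline survival $S_0$ at the
horizon.  A subject's risk is

$$p_{\text{old}} = 1 - S_0^{\exp(\beta^\top (x - \bar x))}.$$

The packaged file transcribes the eight coefficients of the revised
(medication-window) Framingham stroke profile: the antihypertensive-treatment
term counts only while systolic pressure lies in 110–200 mmHg (boundaries
inclusive — the conventional reading of a stated range; the choice is
isolated in `apply_med_window()` and trivially changeable).  The original
baseline-survival constants and covariate means are not reproduced in the
sources available to this package, so the packaged centring values and
baseline survivals (0.945 male / 0.957 female at a 65-year-old average
profile) are representative values; the file is versioned and any compatible
JSON file can be substituted.  Subjects outside the 55–84 development range
are scored anyway but flagged, since applying the score to a 45–64 cohort is
an extrapolation the evaluation design itself makes.

## Synthesis update

Each literature factor $f$ carries a relative-risk function $rr_f$ and a
reference-population distribution.  Its standardized multiplier is

$$m_f(x) = \frac{rr_f(x)}{E_{\text{ref}}[rr_f(X)]},$$

so the population-average multiplier is exactly 1 and an average subject is
not moved.  The update acts on the cumulative-hazard scale,

$$H_{\text{new}} = H_{\text{old}} \prod_f m_f(x), \qquad
p_{\text{new}} = 1 - e^{-H_{\text{new}}}, \qquad
H_{\text{old}} = -\log(1 - p_{\text{old}}),$$

which keeps $p_{\text{new}}$ in $[0,1]$ for any multiplier product and agrees
with the proportional-hazards form of the baseline (odds- or
probability-scale updates do neither).  Factors are assumed conditionally
independent of the baseline covariates and of each other beyond their own
standardization; no cross-adjustment is attempted.  Continuous factors use
piecewise-constant relative risks over bins rather than log-linear per-unit
effects, because literature estimates are usually reported per category; the
bins are part of the factor file and configurable per factor.  An
applicability predicate lets a factor skip subjects outside its domain (HRT
applies only to postmenopausal women; everyone else gets multiplier exactly
1).  When the total multiplier is exactly 1 the baseline risk is returned
bit-for-bit, so a null factor file is a true identity.

The packaged factor file is **illustrative**: the literature meta-analysis
behind the seven factors is out of scope here, so the file carries synthetic
placeholder relative risks of realistic sign and size (e.g. 1.8 for African
American ethnicity, 0.8/0.7 for moderate/high exercise) chosen once at design
time.  Substitute a vetted file for any substantive use.

## Recalibration

A model developed elsewhere is often miscalibrated in level on a new cohort.
Recalibration matches the overall predicted incidence to the overall observed
incidence — one scalar constraint, so the package fits one scalar: the
hazard-scale power $c$ in $p' = 1 - (1-p)^c$, solved by geometric bisection
on $c \in [10^{-6}, 10^6]$ to $10^{-8}$ on the mean (the mean is monotone in
$c$, so bisection cannot fail).  The observed incidence is the Kaplan–Meier
cumulative incidence at the horizon, not the raw event fraction, which
censoring would bias downward.  Because the map is strictly monotone, ranks
— and hence both concordance statistics and the quantile-based risk classes —
are invariant; only level-sensitive quantities (calibration statistics,
classless NRI) change.  This is why the pipeline reports concordance and
class NRI once but calibration and classless NRI before and after
recalibration.  Decile-specific or slope recalibration is deliberately out of
scope: matching one observed number is one degree of freedom.

## Evaluation statistics

**Concordance.**  A pair is *usable* when the shorter observed time is an
event time; it is concordant when that subject has the higher predicted risk
(ties in risk credit 1/2; tied event times yield no usable pair).  Harrell's
C is the weighted fraction over all usable pairs; Uno's C truncates at
$\tau$ and weights each usable pair by $1/\hat G(t_i-)^2$, the inverse
squared Kaplan–Meier censoring survival just before the event, making the
estimand free of the censoring distribution.  Both run through one shared
engine (Harrell is the unit-weight case), so with no censoring before $\tau$
they agree bit-for-bit.  Standard errors and intervals come from the common
percentile bootstrap rather than an asymptotic formula, for uniformity with
the NRI machinery.

**Calibration.**  Subjects are ranked by predicted risk into ten equal-count
partitions; per partition the expected count is $\sum p_i$ and the observed
count is $n_g$ times the within-partition KM incidence at $\tau$.  The
statistic is $\sum_g (O_g-E_g)^2 / (E_g(1-E_g/n_g))$, with a working
lack-of-fit threshold of 20.  Degenerate partitions (expected 0 or $n_g$)
are merged into a neighbour and reported.  Note that for an *externally*
specified model nothing is estimated in-sample, so each partition term is a
standardized binomial quadratic and the null distribution is approximately
$\chi^2$ with one degree of freedom **per partition** ($\chi^2_{10}$ here);
the familiar $g-2$ rule applies only to in-sample logistic fits.  The test
suite verifies this null behaviour by simulation.

**Reclassification.**  For the classless NRI any risk increase is an upward
move; for the class NRI a move is a change of risk class, where the three
classes are cut at quantiles of *each model's own* predicted-risk
distribution (so a subject can change class without changing rank between
models — faithful to the stated procedure, and it makes the class NRI
invariant under recalibration).  Under censoring the event/non-event
proportions among movers are estimated with the Kaplan–Meier incidence at
$\tau$ inside each movement group (risk-set weighting); deleting censored
subjects would bias the components.  The overall NRI is defined as event
plus non-event component, so additivity is structural.

**Bootstrap.**  All intervals are percentile bootstrap over subjects
(default $B = 1000$), one seed per call, deterministic; a statistic
undefined on more than 10% of resamples is declared unstable rather than
silently summarized.

## The synthetic cohort

The generator emulates a two-sex community cohort aged 45–64 followed ten
years: uniform ages, truncated-normal pressures and lipids, correlated BMI
and waist (bivariate normal, $\rho = 0.8$), sex-specific prevalences for the
binary factors, LVH fixed to "no" (mirroring a baseline visit that did not
measure it), age-dependent menopause and HRT among postmenopausal women.
Event times are exponential with rate $H_0 \exp(\text{lp})/\text{horizon}$,
where $H_0 = -\log(1-\text{baseline incidence})$ — the simplest law with a
closed-form oracle (`true_risk()`), and nothing downstream depends on the
hazard shape.  Censoring is exponential dropout (default 0.02/year) plus
administrative censoring at the horizon, giving both definite non-events and
mid-follow-up censoring, which the NRI estimator must handle.

Two default choices define the simulated study conditions.  First, the true
log hazard ratios equal the packaged baseline coefficients plus the packaged
factor log relative risks — continuous factors act through the same
piecewise-constant bins the factor file carries — so the updated model is
correctly specified up to standardization constants and the evaluation suite
measures estimator behaviour rather than model error.  Second, the
sex-specific baseline incidences (0.0394 male, 0.0301 female) were
calibrated once so a default cohort shows about 4.9% ten-year incidence with
the male:female ratio (≈1.36) implied by the packaged models, and then
frozen; with that ratio a single overall recalibration leaves no per-sex
intercept bias.  What passing tests on these cohorts do *not* show:
robustness to non-proportional hazards, informative censoring, measurement
error, or misspecified factor relative risks — none of which the generator
emulates.

## Numerical choices and degenerate inputs

Truncated normals are drawn by inverse-CDF, so cohorts are reproducible to
the byte given a seed.  Concordance loops run per event over vectorized
comparisons ($O(\text{events} \times n)$), and the product-limit estimator
used inside bootstrap loops is a small sorted-pass implementation
cross-checked against `survival::survfit()`.  The IPCW weight guard refuses
a censoring survival of exactly zero before an event inside $\tau$ (advice:
lower $\tau$).  Empty cohorts, all-flagged exclusions, all-zero predictions,
single-sex tables and score ties all have defined behaviour exercised by the
test suite.  Problem sizes in the tests (up to $n = 15{,}000$ single runs,
500 replicates at $n = 2{,}000$ for null-distribution checks, 200 outer
replicates for bootstrap coverage) were chosen as the smallest sizes at
which the checked properties are statistically sharp.

## Known limitations

* The packaged coefficients are a transcription and the factor relative
  risks are placeholders; both files exist to make the machinery auditable,
  not to ship a clinically validated score.
* Intercept-only recalibration cannot repair slope miscalibration.
* The class NRI depends on each model's own quantile thresholds; with
  heavily tied predicted risks class sizes can deviate from the nominal
  quantile split.
* Bootstrap intervals are percentile, not BCa; for very small event counts
  they can undercover.
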