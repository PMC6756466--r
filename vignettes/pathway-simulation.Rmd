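---
title: "Modelling the hyperacute stroke pathway: simulation, outcomes and decision transplants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the hyperacute stroke pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokepathsim)
```

## The problem

Thrombolysis (clot-dissolving treatment with alteplase) is the main licensed
drug treatment for acute ischaemic stroke, and its benefit decays sharply
with the time from stroke onset to treatment. Use of thrombolysis varies
severalfold between hospitals, and national clinical audits record why only
indirectly: the audit reports a single use rate and a door-to-needle time per
hospital, while the variation is actually produced by three distinct levers —
how often the onset time is ascertained, how fast the in-hospital pathway
runs, and how ready clinicians are to treat the patients who arrive in time.

`strokepathsim` separates these levers. It combines:

1. a Monte-Carlo **pathway model** of the journey from stroke onset to
   needle,
2. an **outcome model** converting onset-to-treatment time into additional
   disability-free outcomes, and
3. a machine-learning **clinical decision model** that learns each
   hospital's treatment decisions and can transplant one hospital's decision
   culture onto another hospital's patients,

together with a **synthetic cohort generator** so that the full analysis
chain can be exercised, tested and calibrated without access to confidential
audit records.

## The pathway model

A patient receives thrombolysis in the model only if four criteria hold in
sequence:

1. the stroke onset time is known (probability $p_{\mathrm{onset}}$);
2. the patient arrives within 4 h of onset (probability $p_{4h}$,
   conditional on a known onset);
3. the stroke is ischaemic ($p_{\mathrm{isch}}$) and the patient is judged
   clinically eligible ($p_{\mathrm{elig}}$, evaluated only for patients
   scanned with at least 30 min left in their window);
4. the summed onset-to-treatment time
   $T = T_{\mathrm{onset\to arrival}} + T_{\mathrm{arrival\to scan}} +
   T_{\mathrm{scan\to needle}}$ fits the age-dependent window
   $W(a) = 270$ min for $a < 80$ and $180$ min for $a \ge 80$.

Process times are log-normal, parameterised by a median (minutes) and a
geometric dispersion (the sdlog); onset-to-arrival is sampled conditionally
on being at most 240 min, because arrival within 4 h is already an explicit
Bernoulli gate and an untruncated distribution would conflate the two.
Setting a dispersion of zero produces the "fixed time, no variation" used
by improvement scenarios. The window cut-off is deliberately strict: no
simulated treatment ever occurs outside $W(a)$, whereas real clinicians
allow a little flexibility. The documented consequence is that the model
slightly underpredicts observed use when fitted to real audit data (roughly
a tenth relative); on self-consistent synthetic data, where the generator
applies the same strict rule, this bias vanishes — a contrast the test suite
asserts rather than hides.

With every distribution degenerate and inside the window, the treated
fraction collapses to the analytic product
$p_{\mathrm{onset}} \, p_{4h} \, p_{\mathrm{isch}} \, p_{\mathrm{elig}}$,
which serves as the simulator's closed-form oracle.

All per-patient randomness is drawn as a fixed block of uniforms (one vector
per pathway stage, drawn whether or not the stage is reached) and pushed
through quantile functions. Two simulations with the same seed therefore
share common random numbers stage by stage, which (a) makes paired scenario
comparisons low-variance, and (b) makes treated status pathwise monotone in
every gate probability and (stochastically) in every process time — a
property the tests check directly rather than on averages.

Admissions per simulated year are fixed at the profile's annual count rather
than Poisson-distributed; this isolates parameter effects in scenario
comparisons. Poisson arrivals are available via `arrivals = "poisson"`.
Replicate summaries report mean and 95% CI over (by default) 100 one-year
runs, using the normal approximation $\bar{x} \pm 1.96\,s/\sqrt{n}$;
percentile intervals are available with `ci = "percentile"`. The 2.5%/97.5%
quantiles of the yearly replicates themselves are also kept, as the natural
expression of expected year-to-year variation when comparing a model against
a single observed year.

## Scenarios

`standard_scenarios()` defines the improvement levers: `A` fixes
arrival-to-scan and scan-to-needle at 15 min with no variation; `B` fixes
eligibility at 60% (the proportion of ischaemic patients arriving in time
that trial re-analyses suggest are suitable); `C` fixes known-onset at 77%
(the national upper quartile); `ABC` combines all three.
`alternative_scenario()` is the realistic composite target: known-onset
floored at the national median 67% (hospitals already above keep their own
value), both in-hospital times fixed at 20 min with 10% of patients not
scanned within 4 h of arrival, and eligibility taken from a benchmark
decision model (below). Because gates only ever move up and times only ever
move down in `A`, `B`, `C`, the expected ordering
$\mathrm{base} \le A, B, C \le ABC$ holds per hospital for both thrombolysis
use and clinical benefit, and is asserted in the acceptance tests.

## The outcome model

For a treated patient the model reports the probability of an *additional*
good outcome (modified Rankin Scale 0–1) attributable to thrombolysis:

$$\Delta(t) = \frac{\mathrm{OR}(t)\, o_0}{1 + \mathrm{OR}(t)\, o_0} - p_0,
\qquad o_0 = \frac{p_0}{1 - p_0},$$

where $p_0$ is the untreated probability of mRS 0–1 (default 0.30) and
$\mathrm{OR}(t)$ the treatment odds ratio at onset-to-treatment time $t$.
The default curve is log-linear,
$\log \mathrm{OR}(t) = 0.77862 - 0.0024334\,t$, calibrated by passing a line
through the pooled alteplase-trials interval estimates — OR 1.75 for
treatment within 3 h and OR 1.26 for 3–4.5 h — anchored at the interval
midpoints (90 and 225 min). Benefit is clamped to zero at and beyond
`max_benefit_min` (default 270 min; with the strict window, treatment never
occurs later anyway). Any monotone non-increasing curve can be supplied via
`effect_curve`; the benefit curve is age-independent (age conditions the
window, not the effect). Summed over a period's treated patients and scaled
by admissions, this yields the "additional good outcomes per 1000
admissions" metric.

## The synthetic cohort generator

`synthesize_cohort()` is first-class, tested code, not a fixture: it is the
package's stand-in for a multi-hospital audit extract. Each hospital profile
holds gate probabilities, time distributions, an age distribution
(normal, censored to 40–100 years as audit extracts do for anonymity), a
case mix of clinical features (15 itemised NIHSS components whose maxima sum
to 42, drawn binomially from a patient-level latent severity; sex,
comorbidity, medication and pre-stroke disability variables), and a latent
decision rule. The rule is logistic in the NIHSS total with a per-hospital
aggressiveness offset and penalties for anticoagulation and pre-stroke
disability; its offset is calibrated by Monte-Carlo so that the mean
decision-to-treat probability over the case mix equals the profile's
$p_{\mathrm{elig}}$, keeping the generator consistent with the closed-form
gate product. A zero logistic scale gives a deterministic severity-threshold
rule, used as the separable limit in classifier tests.

The bundled `reference_hospital_profiles()` span the documented
between-hospital ranges (known onset 44–73%, arrival-to-scan medians
11–56 min, scan-to-needle medians 21–44 min, eligibility 31–52%, roughly
520–600 admissions/hospital/year, i.e. ~7870 records over two years across
seven units) and are synthetic, not any real hospital's parameters.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: treatments given outside the strict window
(about 8% of real treatments); in-hospital-onset strokes; correlation
between pathway speed and severity (severe strokes are often treated
faster); scanner contention and time-of-day effects; practitioner-level
variation within a hospital; and the audit's exact field dictionary. Tests
passing on synthetic cohorts demonstrate internal consistency of the
estimators and models, not external validity.

## Fitting profiles from records

`fit_profile_from_records()` estimates gates as observed proportions and
time distributions by maximum likelihood on the log scale, honouring how
each time is observed: onset-to-arrival (for within-4 h arrivers) as a
log-normal truncated at 240 min, and scan-to-needle — observed only for
treated patients, i.e. only when it fits each patient's remaining window —
with the matching per-observation truncated likelihood. Plain log-moment
fits would be biased here by several standard errors at audit sample sizes;
the truncation-aware MLE recovers the generating values within 3 SE, which
the tests assert using the observed-information standard errors.

Between the clinical decision and the needle sits the window check, so the
raw treated fraction among patients scanned in time slightly understates the
decision rate. The fitted $p_{\mathrm{elig}}$ therefore divides treated
counts by the fitted probability that scan-to-needle fits the remaining
window (an inverse-probability correction); the raw fraction is kept
alongside in `fit_info`.

`fit_pathway_model()` wraps this as a classed model object with `print`,
`summary`, `coef`, `simulate` and `predict` methods.

## The clinical decision model

Only patients for whom a decision was genuinely possible enter the decision
dataset: completed NIHSS, known onset, and scanned with at least 30 min left
in the window. Haemorrhagic strokes meeting these criteria stay in by
default — the model must learn that contraindication — with
`ischaemic_only = TRUE` to restrict. Features follow a declared schema
(deterministic column order; hospital attended one-hot encoded last).

The classifier is pluggable; the default is a random forest (ranger, 500
fully grown trees). Fully grown trees mean a hospital's model reproduces its
own observed rate when applied to its own patients, so the transplant
matrix's diagonal anchors to the observed rates while off-diagonal entries
remain genuinely out-of-sample. Tie votes in prediction are broken with a
fixed seed so predictions are deterministic. Validation uses stratified
ten-fold cross-validation: folds differ in size by at most one, per-fold
class counts sit within one patient of proportionality, and every patient is
tested exactly once.

Entry $(i, j)$ of the decision-transplant matrix is the percentage of
hospital $j$'s included patients that the model trained on hospital $i$
predicts would be treated. When transplanting, the hospital-identity columns
of the cohort are set to the training hospital's identity, so the entry
reads as "hospital $i$'s decision culture applied to hospital $j$'s case
mix"; row variation therefore expresses decision culture and column
variation case mix. A benchmark model trained on a reference hospital set
(by default the most treatment-predisposed row of the matrix) supplies the
eligibility probability for the `alternative` scenario; because the
simulator applies eligibility downstream of the ischaemic gate, that rate is
computed on the ischaemic subset of the target cohort.

## Validation procedures

`bootstrap_validation()` draws samples of 600 patients (a typical stroke
unit's annual intake), resampling separately from treated and untreated
strata to sweep the overall use rate across 1–25%, fits a profile to each
sample, simulates it (100 one-year runs averaged per sample by default), and
regresses predicted on actual use. Target rates are evenly spaced by default
— deterministic and uniformly covering the range — with uniform-random
placement behind a flag. Both the ordinary $R^2$ and a through-origin fit
(slope and uncentred $R^2$) are reported, since the regression form behind a
published scatter is rarely stated. On self-consistent synthetic data the
through-origin slope lies in $[0.9, 1.1]$ and $R^2 \ge 0.95$; against real
audit data a slope of ~0.89 would be expected instead, for the strict-window
reason above.

`hospital_comparison()` closes the loop per hospital: generate (or load)
records, fit, simulate 100 one-year replicates, and compare observed with
modelled use, flagging whether the observed rate falls inside the replicate
year-to-year interval.

## Numerical choices and degenerate inputs

* Degenerate (zero-dispersion) time distributions short-circuit the
  quantile transforms exactly, so scenario arithmetic is exact, not
  approximate.
* A truncated distribution whose degenerate median lies beyond its
  truncation bound is rejected at sampling time.
* Cohorts record times as integer minutes (as audits do); the induced
  rounding bias on log-scale fits is far below one standard error at the
  sample sizes involved.
* Profiles with $p_{\mathrm{elig}} \in \{0, 1\}$ map to decision-rule
  offsets of $\mp\infty$ (never/always treat) without special cases
  downstream.
* Cohorts with no treated patients fit $p_{\mathrm{elig}} = 0$ and fall
  back to reference scan-to-needle parameters, which are then irrelevant.
* Fold assignment deals each class, shuffled, into the currently smallest
  fold (ties broken by fold index), which yields the size and stratification
  guarantees above deterministically given the seed.

## Problem sizes

The test suite and the acceptance script run at the sizes the analyses are
designed for: product-of-gates and parameter-recovery checks at 10 000
patients; the strict-window sweep over one million simulated patients across
randomised profiles; the self-consistency loop over seven hospitals with two
years of synthetic records and 100 replicate years; bootstrap validation at
100 samples of 600 patients with 100 inner runs each; and the
decision-decomposition recovery over 20 seeded repetitions per construction.

## Limitations

The package models a single pathway to thrombolysis: no thrombectomy or
interhospital transfer, no advanced-imaging selection of late or
unknown-onset patients, no scanner-capacity or queueing effects, and no
within-hospital practitioner variation. The decision model's accuracy
(around 80% on realistic synthetic cohorts, by design of the latent rules'
stochasticity) is adequate for audit-level insight into variation but not
for individual patient guidance. The outcome model reports only additional
mRS 0–1 outcomes; it does not model the full disability distribution,
mortality, or haemorrhagic complications.
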