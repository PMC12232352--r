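---
title: "Methods: microsimulation of second-line type 2 diabetes treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsimulation of second-line type 2 diabetes treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diamicro)
```

## The modelling problem

When glycaemic control is inadequate on metformin alone, people with type 2
diabetes (T2DM) add a second-line oral agent -- most commonly a
sulphonylurea (SU), a DPP4 inhibitor (DPP4i) or an SGLT2 inhibitor
(SGLT2i).  Randomised trials compare these classes on a handful of
endpoints in selected populations; what a clinician or policy-maker often
wants instead is the predicted long-term burden of *all* major diabetes
complications, for the real mix of people who present for second-line
treatment in routine practice, under each hypothetical choice of drug.

`diamicro` addresses this with an individual-level discrete-time
microsimulation.  Each simulated person carries baseline demographics,
comorbidity history and nine clinical risk factors, and is advanced through
90-day quarters for up to 31 quarters (about 7.6 years).  Each quarter the
person (1) has a treatment regimen, (2) accrues per-quarter probabilities
of ten complications given their current state, and (3) has their risk
factors updated into the next quarter.  Because the same individual can be
re-simulated under each second-line class while everything else is held
fixed, the package produces *counterfactual* outcome sets whose paired
differences estimate comparative treatment effects.

The pipeline has four stages, each usable on its own:

1. **Cohort synthesis** (`generate_cohort()`) -- a synthetic baseline
   population matching published marginal summaries.
2. **Pathway simulation** (`simulate_pathways()`) -- quarter-resolution
   regimen sequences with persistence, switching and administrative
   censoring.
3. **Calibration** (`assess_agreement()`, `recalibrate()`) -- hold-out
   comparison of predicted and observed mean trajectories, with additive
   offset recalibration for flagged risk factors.
4. **Counterfactual contrasts** (`run_counterfactuals()`, `contrast()`) --
   paired between-treatment differences with normal-based 95% CIs, overall
   and by baseline cardiovascular disease (CVD) status.

## Cohort synthesis

Only marginal summaries (medians with IQRs, category percentages) of the
target population are available, not record-level data, so the generator
reconstructs a joint distribution from them:

* **Marginal families.**  Each continuous variable is assigned a
  two-parameter family solved from its target median and IQR: normal
  (mean = median, sd = IQR / (2 qnorm(0.75))) where the printed IQR is
  roughly symmetric (SBP, DBP, eGFR, HDL, LDL, total cholesterol, age),
  log-normal (meanlog = log median, sdlog = log(q3/q1) / (2 qnorm(0.75)))
  where the median sits well below the IQR midpoint (BMI, triglycerides,
  HbA1c, years since diagnosis).  Both solutions reproduce the target
  median *exactly* in expectation, which is the property the downstream
  checks rely on.  Printed IQRs that are strongly asymmetric (notably
  years-since-diagnosis, 4.9 with IQR 2.5--5.0) cannot be matched exactly
  by any two-parameter family; the generator prioritises the median and
  accepts an approximate IQR.  This is a deliberate fidelity/parsimony
  trade-off, and user-supplied `cohort_spec()` objects can override any
  family.
* **Dependence.**  The nine risk factors are coupled by a Gaussian copula
  parameterised on the Spearman scale: a target rank correlation $r_s$ is
  mapped to the latent Pearson correlation $2\sin(\pi r_s/6)$, which is
  exact for the Gaussian copula, so sample rank correlations converge to
  the spec values.  No correlation matrix is published for the target
  population, so the default encodes weak, clinically plausible structure
  only (LDL and HDL with total cholesterol, SBP with DBP, BMI with blood
  pressure and triglycerides, inverse HDL--triglycerides).  Tests exercise
  both the identity matrix and the default.
* **Comorbidity co-occurrence.**  The four cardiovascular history flags
  (angina, MI, stroke, heart failure) sum to 18.3% individually, but the
  composite "any CVD" target is 13.8% -- histories co-occur.  Drawing the
  flags independently would overshoot the composite (about 17%).  The
  generator instead draws the composite at its target rate and, within
  CVD-positive individuals, draws the component flags conditional on at
  least one being set, with conditional probabilities solved by
  fixed-point iteration so every component marginal is also matched.  The
  composite is then the exact OR of its components, as its definition
  requires.
* **Units.**  HbA1c is stored in NGSP % with the exact IFCC conversion
  `hba1c_pct_to_mmolmol()` (mmol/mol = 10.929 (% − 2.15)); lipid fractions
  are stored in mg/dL throughout, matching the magnitudes of the published
  medians (42.5 / 81.2 / 158.5) even where source tables label those rows
  mmol/L -- magnitudes of that size are only consistent with mg/dL, and the
  mg/dL reading is used consistently rather than asserting intent about
  the labelling.

What the generator does **not** emulate: measurement error and
within-person visit-to-visit variability, missing data patterns,
age-dependence of comorbidity prevalence, or any regional/practice-level
clustering.  Passing cohort-fidelity tests therefore shows the generator
reproduces the *published summary table*, not that it reproduces the full
joint distribution of the underlying population.

## Pathway simulation

Treatment pathways are first-order Markov over an 18-category regimen
taxonomy: no therapy, seven monotherapies, nine named dual therapies and a
single triple-or-other bucket.  Quarter 0 is always the individual's
metformin dual.  The `transition_spec()` has four ingredients: a per-quarter
hazard of leaving the initial dual, a destination distribution for leavers
(time-band dependent), an inter-category matrix for subsequent moves
(absorbing by default -- the minimal structure the calibration targets
identify), and a per-quarter administrative censoring hazard.

The default spec is obtained by *deterministic moment-matching* to printed
population percentages, not by fitting to data
(`default_transition_spec()` documents each target):

* Per-quarter censoring hazards are solved year-by-year from the published
  available-follow-up counts (57 951 at year 1 down to 10 035 at year 7 of
  62 640), implying ~84% cumulative censoring by year 7.  Censoring is
  simulated independently of regimen and arm, reflecting its
  administrative origin (end of data coverage), and cessation hazards are
  common to the three arms (cessation has been reported similar across
  them).
* The year-1 leave hazard is a least-squares compromise between two
  slightly inconsistent published figures: 73% persistence among those
  still observed, and a year-1 dual mix of 33/28/7% whose sum (68%) only
  equals 73% x 92.5% if those class percentages are shares of the *full*
  baseline cohort including the censored.  The package adopts exactly that
  denominator convention: `pathway_prevalence()` reports shares among
  at-risk individuals (and reports its denominator), while the calibration
  targets for the year-1 mix are evaluated on the full-cohort scale.  The
  resulting common per-quarter stay probability is about 0.924 in year 1.
* The post-year-1 hazard is solved from the end-of-follow-up dual mix
  (16/12/4% among those still observed), and the two destination
  distributions from the year-1 metformin-monotherapy (12%) and triple
  (7%) shares and the 31% on triple therapy at the end of follow-up.
  Destination categories that no published figure constrains (insulin
  duals, minor monotherapies) receive fixed plausibility weights chosen
  once; they matter only for regimen-specific treatment effects downstream.

Concomitant statin and blood-pressure-therapy flags are independent
Bernoulli draws per quarter (defaults 0.72 and 0.62, typical prescribing
prevalences in incident second-line T2DM populations); they enter the
simulation only through risk-equation coefficients.

The Markov default permits re-entering a previously held category if the
user supplies an inter-category matrix that allows it; the shipped default
does not move individuals after their first switch, which is the smallest
model consistent with the calibration targets.

## Risk-factor engine

Each of the nine risk factors follows a linear AR(1) per quarter:

$$x_{t+1} = \beta_0 + \lambda x_t + \beta' z + \beta_\tau (t+1) +
  \mathrm{effect}(\text{regimen}_t) + \delta_{t+1} + \epsilon$$

with baseline covariates $z$ (age, sex, years since diagnosis, CVD
history) plus the quarter's concomitant-therapy flags, an additive regimen
effect from the effects registry, an optional recalibration offset
$\delta$, and a Gaussian residual used only in stochastic mode.  The
functional form is the package's declared contract -- coefficient *values*
are entirely config-driven (`read_risk_equations()`), so any linear
first-order dynamic can be represented.  Defaults use $\lambda = 0.9$
(0.95 for BMI, 0.98 for eGFR), so a sustained per-quarter effect $e$
settles at a steady-state level shift $e/(1-\lambda)$; default effect
magnitudes are quoted per quarter with this multiplier in mind.  eGFR
additionally carries a small negative time trend (about −0.8 mL/min/1.73m²
per year asymptotically) so that kidney-disease risk rises realistically
over follow-up.

Expected mode (the default) propagates means and consumes no random
numbers; stochastic mode adds residuals and is used to create synthetic
"observed" data and for uncertainty experiments.  Predictions are clipped
at documented physiologic floors (eGFR at 0, HbA1c at 4%, etc.); clipping
events are counted on the returned object.

## Event engine

Ten complications are modelled on the per-quarter probability scale with a
logistic link: hypoglycaemia, MI, unstable angina, stroke, heart-failure
hospitalisation, lower-extremity amputation (LEA), end-stage kidney
disease (ESKD), diabetic eye disease, and all-cause death.  At the small
per-quarter probabilities involved, the discrete-time logistic model is
numerically close to a proportional-hazards formulation, which is why
registry effects on events are expressed as log hazard-ratios and added to
the linear predictor.

Acute events (hypoglycaemia, MI, unstable angina, stroke) can recur; their
prior-occurrence count enters the linear predictor linearly (an
indicator-mode alternative is configurable).  ESKD and death are
absorbing; eye disease and LEA are modelled as first occurrences.  In
expected mode the prior-event covariate is the expected count accumulated
so far, and absorbing events are reported as at-risk probabilities
throughout follow-up -- the headline "probability of a complication by
year 5" is the naive cumulative incidence
$1 - \prod_t (1 - p_t)$ over the first 20 quarters conditional on
follow-up, not a cause-specific cumulative incidence function adjusted for
competing death.  In stochastic mode events are drawn, and after simulated
death no further events or updates occur.  Recurrent events are summarised
as expected counts $\sum_t p_t$.

Default event-model coefficients are illustrative: intercepts are solved
so a reference individual (age 60, median risk factors, no CVD) has 5-year
cumulative incidences of roughly 23% eye disease, 6% death, 3.2% ESKD,
2.8% HF, 2% stroke, 1% unstable angina, 0.63% LEA and 0.52% MI, with
clinically signed covariate effects (glycaemia on microvascular risk, low
eGFR on ESKD, age/CVD on macrovascular risk and death).

## Treatment effects

The effects registry holds per-class point effects versus no therapy, of
two types: additive per-quarter shifts on risk-factor scales and log
hazard-ratios on event scales.  Regimens combine their component classes
*additively on the transformed scale*; no interaction structure is
assumed, and a user hook can replace the combination rule.  The
triple-or-other bucket is resolved through a representative composition
(metformin + SU + DPP4i, the most prevalent classes).  The shipped default
values are deliberately labelled non-authoritative: their signs and rough
magnitudes follow the meta-analytic literature (all classes lower HbA1c;
SGLT2i lower BMI, SBP and the hazards of HF hospitalisation and ESKD; SU
and insulin raise weight and hypoglycaemia risk), and they exist so that
the direction-level behaviour of the simulator can be exercised and
tested.  Quantitative use requires supplying an effects table
(`load_effects()`) sourced from meta-analyses.

## Counterfactual contrasts

`run_counterfactuals()` simulates three copies of every individual, one
per second-line class, sharing the identical baseline, the identical
second-line duration, the identical downstream regimen sequence and the
identical censoring time: wherever the observed timeline shows the
person's own metformin dual, the counterfactual timeline substitutes the
assigned class's dual, and nothing else changes.  In stochastic mode the
three copies share common random numbers, which removes simulation noise
from paired differences.

Within a quarter the fixed order is: read regimen, evaluate event
probabilities from the current state, then update risk factors.  Horizon
summaries use the convention that an individual contributes at horizon
$h$ years only if their follow-up reaches quarter $4h$ (matching declining
available-follow-up denominators); event endpoints aggregate quarters
$0..4h-1$ and risk factors are read at quarter $4h$.  Aggregation is the
mean across contributing individuals with the normal-based 95% CI
$\bar{x} \pm 1.96\, s/\sqrt{n}$.  Contrasts are *paired* within-individual
differences -- the three counterfactual copies are the same people, so
pairing is both available and variance-reducing -- aggregated the same
way, overall and within baseline-CVD subgroups (CVD defined at baseline
only, as the composite of the four history flags).

## Calibration and recalibration

`split_holdout()` makes a seed-deterministic split stratified by
second-line class.  `assess_agreement()` compares an observed mean
trajectory against the predicted 95% band quarter by quarter; the default
flagging rule is "any quarter outside the band", with a
fraction-of-quarters alternative.  The coverage property of this rule is
nominal ~95% per quarter *when the observed value is a single draw from
the predictive distribution of the mean*; if the observed series carries
its own independent sampling noise of the same magnitude, coverage is
mechanically lower -- users comparing two equally sized samples should
widen the band accordingly.

`recalibrate()` estimates additive per-quarter equation offsets for
flagged risk factors.  Because an offset injected at quarter $t$
propagates through the AR(1) lag, the raw mean discrepancy $d_t =
\text{obs}_t - \text{pred}_t$ obeys $d_t = \lambda d_{t-1} + \delta_t$;
the offsets are recovered by the exact deconvolution $\delta_t = d_t -
\lambda d_{t-1}$ (least squares with one parameter per quarter), then
optionally smoothed by a centred moving average.  This is the smallest
adjustment class that can reconcile an arbitrary mean trajectory, and it
leaves all covariate coefficients untouched.  Only risk-factor outcomes
are recalibratable in this version.  Recovery is validated by parameter
recovery: a known drift (0.05 per quarter per quarter on BMI) injected
into the generating equations is recovered from synthetic hold-out data of
10 000 individuals with RMSE well under 20% of the drift magnitude.

Accuracy of any such model degrades at long horizons as follow-up thins;
the package caps the horizon at 31 quarters and leaves further truncation
to the user rather than truncating automatically.

## Numerical choices and degenerate inputs

* Quantiles are type-7 (linear interpolation) throughout.
* Category frequency vectors are renormalised when they sum to within
  0.5% of 1 (printed percentages round); larger deviations are errors.
* Correlation matrices must be symmetric, unit-diagonal and PSD (eigen
  check at tolerance 1e-8).
* Rare constraint violations after marginal sampling (DBP >= SBP,
  HDL > total cholesterol, non-positive values) are repaired by capping
  rather than rejection, preserving determinism; under the default spec
  these affect essentially no individuals.
* Empty cohorts, zero at-risk denominators, degenerate hold-out fractions
  and mismatched quarter grids raise informative errors rather than
  propagating NaN.
* All generators and simulators are bit-reproducible given (spec, seed);
  expected-mode prediction consumes no RNG at all.

## Problem sizes used in the test suite

The shipped tests generate all data programmatically: cohort fidelity and
pathway calibration run at the full population size of 62 640 (a few
seconds each); copula and marginal checks at 50 000; direction-level
counterfactual properties at 10 000 individuals x 31 quarters x 3 arms;
recalibration recovery at a hold-out of 10 000; Monte-Carlo oracles for
the incidence formulas at 10^6 replicates; and the remaining unit tests on
cohorts of 1--2 000.  These sizes keep every Monte-Carlo tolerance at
least three standard errors wide.

## Known limitations

* Treatment-effect defaults are direction-level placeholders, not
  estimates; all quantitative conclusions require a user-supplied effects
  table.
* Additive effect combination across co-prescribed classes ignores
  pharmacological interaction.
* The competing-risk convention (naive cumulative incidence conditional on
  follow-up) overstates absolute incidences slightly relative to a
  cause-specific decomposition when mortality is non-trivial.
* The pathway model is first-order Markov with administrative censoring
  independent of health state; informative dropout is not modelled.
* The copula reconstruction cannot recover joint features absent from the
  published marginals (e.g. tail dependence), and two-parameter marginal
  families cannot match strongly asymmetric printed IQRs exactly.
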