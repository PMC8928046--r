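---
title: "Methods: multidimensional physical activity profiling and trial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multidimensional physical activity profiling and trial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`mdpa` implements the quantitative machinery of a wearable-feedback
physical-activity (PA) trial: minute-by-minute energy-expenditure records
are turned into six health-harnessing PA dimensions, traffic-light health
targets are evaluated (including activity review and forward planning),
and two-arm trials of such profiles are analysed with baseline-adjusted
ANCOVA, bias-corrected and accelerated (BCa) bootstrap intervals and
Hedges *g*. Because raw minute-level device data for such trials are
rarely shareable, the package includes a minute-level synthetic cohort
generator calibrated to published group summaries; it is first-class,
tested code and the backbone of the package's validation.

## Minute processing

A *minute record* carries a timestamp, a MET value (multiples of resting
metabolic rate, RMR), energy expenditure in kcal/min, a step count and a
wear flag. Processing builds complete 24-hour days:

* **Intensity classes.** The MET axis is partitioned into half-open
  intervals: sedentary $[0, 1.8)$, light $[1.8, 3.0)$, moderate
  $[3.0, 6.0)$, vigorous $[6.0, \infty)$. Boundary values belong to the
  upper class.
* **Non-wear imputation.** Every missing or non-wear minute is assigned
  the resting rate: $\mathrm{kcal} = \mathrm{RMR}/1440$, METs $= 1.0$,
  steps $= 0$, flagged `imputed`. Observed minutes are never altered, so
  daily energy is conserved:
  $\mathrm{TEE} = \sum_\text{worn}\mathrm{kcal} +
  n_\text{imputed}\cdot\mathrm{RMR}/1440$.
* **Wear validity.** A day is valid when at least 80% of an assumed
  16-hour waking day was worn (768 of 960 minutes under the default
  07:00--23:00 window); a week is valid with at least 6 valid days.
  The waking window is a fixed, configurable clock window: the source
  criterion is phrased against "an assumed 16-hour waking day" without
  anchoring it, so we anchor it explicitly and apply the 80% rule to the
  window only (wear outside it does not count towards validity).

Imputed minutes sit at 1.0 MET and therefore count as sedentary in class
tallies; they remain distinguishable via the `imputed` flag. The epoch is
fixed at 1 minute; sub-minute data must be aggregated upstream.

## The six dimensions

For a valid week (averaging over valid days; weekly bouted channels are
normalized by $7/n_\text{valid}$, exact when all 7 days are valid --
computing over valid days only avoids the downward bias a mostly-imputed
invalid day would introduce):

1. **PAL** -- mean daily total energy expenditure divided by RMR.
2. **Sedentary time** -- % of waking-window minutes below 1.8 METs.
3. **Moderate activity** -- minutes/day at $\ge 3$ METs (vigorous
   included).
4. **Bouted vigorous** -- min/week in runs $\ge 10$ min at $\ge 6$ METs.
5. **Bouted MVPA** -- min/week in runs $\ge 10$ min at $\ge 3$ METs.
6. **Steps** -- mean daily step count.

**Bout rule.** Bouts are maximal runs of consecutive qualifying minutes
within a calendar day; the entire maximal run counts (a 23-minute run
contributes 23 minutes), runs do not span midnight, and strict contiguity
is the default. Whether brief interruptions were tolerated in the source
analyses is not recoverable, so strict contiguity -- the minimal,
oracle-checkable reading of "accumulated in bouts of at least 10 minutes"
-- is the default, with an interruption allowance exposed as
`max_interruption` (minutes, default 0).

## Feedback computations

Five health targets are evaluated with a traffic-light rule: for at-least
dimensions, green when the attained value reaches the target, amber when
it reaches `target * (1 - amber_band)`, red otherwise; sedentary time is
the only at-most dimension and uses the mirrored rule. The published
description never prints the deployed target values or the definition of
"close to the target", so the defaults are declared, guideline-scale
choices (calorie burn $1.6\times$RMR kcal/day, sedentary $\le 65$% of the
waking day, moderate $\ge 120$ min/day, bouted MVPA $\ge 150$ min/week,
bouted vigorous $\ge 75$ min/week, amber band $\pm 10$%), all
personalizable per participant.

Planned activities take MET values from a bundled mini-compendium (a
package-curated subset of compendium-style values) and cost
$\mathrm{kcal} = \mathrm{MET}\cdot(\mathrm{RMR}/1440)\cdot\text{minutes}$
-- the personalized scaling consistent with the imputation rule, rather
than the 3.5 ml/kg/min convention. Forward planning replaces the
underlying minutes, recomputes the profile and targets on the modified
week, and leaves the original week untouched.

## Trial analysis

For each outcome and follow-up, the adjusted mean difference is the arm
coefficient of

$$y_\text{follow-up} \sim \text{arm} + y_\text{baseline} + \text{sex} +
\text{weight status},$$

with weight status the binary BMI $\ge 30$ indicator used in the
stratified randomization. Constant covariates are dropped with a warning.
Confidence intervals come from a hand-authored BCa bootstrap:
participants are resampled with replacement *stratified by arm*
(preserving the 36:15 allocation -- our operationalization of
"accounting for unequal variance because of unequal group allocation"),
the bias constant is $z_0 = \Phi^{-1}\!\left(\#\{\theta^* <
\hat\theta\}/B\right)$, and the acceleration comes from the plain
delete-1 jackknife skewness
$a = \sum(\bar\theta - \theta_i)^3 \big/ 6\left[\sum(\bar\theta -
\theta_i)^2\right]^{3/2}$. Percentile extraction uses R's default
(type-7) quantiles. Note that under stratified resampling some reference
implementations compute stratum-centered influence values for $a$; we
keep the plain jackknife formula and verify agreement with the `boot`
package on unstratified statistics and by paired rejection behaviour on
stratified ones.

Hedges $g$ standardizes the adjusted difference by the follow-up SD
pooled across arms with the small-sample factor
$J = 1 - 3/(4(n_1+n_2-2) - 1)$; the pooled *follow-up* SD (not the
baseline or residual SD) is a declared convention, as the source does not
state its choice. $g$ is scale invariant and its CI is taken from the
same bootstrap resamples. Default replications are 5000; validation
studies reduce this (e.g. 500--999) purely for speed.

Subgroup descriptives split by sex or by baseline activity (cohort median
baseline PAL, ties to the low group). The eligibility screen excludes
participants with baseline PAL $\ge 2.0$.

## The synthetic cohort generator

The generator defines the study conditions; it is calibrated, not tuned.

**Calibration.** Printed group means with 95% CIs convert to
between-person SDs via $\mathrm{sd} = (\mathrm{CI_{hi}} -
\mathrm{CI_{lo}})/(2 z_{0.975})\cdot\sqrt{n}$. The default configuration
takes each arm's printed baseline and week-6 cell means and sets the
intervention week-12 mean to the control week-12 mean plus the printed
adjusted difference, so the programmed week-12 effects are exactly the
published ones (PAL 0.09, moderate 24 min/day, bouted MVPA 195 min/week,
bouted vigorous 18 min/week, steps 1545/day, sedentary $-40$ min of the
960-minute waking day $= -4.17$ percentage points). Keeping the printed
week-6 means reproduces the published "no 6-week effect" pattern up to
the small printed differences rather than forcing exact zeros.

**Draws.** Each participant-week draws the six dimensions from normal
distributions with the configured means/SDs, clamped to the feasible
region. Daily moderate minutes and weekly bouted MVPA are drawn *jointly*
(bivariate normal, default correlation 0.8) with bouted MVPA clamped to
$7\times$ daily moderate, because bouted minutes are a subset of all
$\ge 3$-MET minutes; independent draws would violate that subset
constraint for a fifth of control-arm draws and the necessary clamping
would bias the recovered MVPA difference by about $-10$%. The
vigorous-bout channel is drawn from a moment-matched gamma distribution
(shape $(\mu/\sigma)^2$, rate $\mu/\sigma^2$): its calibrated CV exceeds
1, so a normal draw clamped at zero could not follow the configured mean
-- truncation would inflate both arms and their difference -- whereas the
gamma matches the configured mean and SD exactly on $[0,\infty)$ and
mirrors the right-skew implied by the published asymmetric CIs.
Assessments
are drawn independently across weeks (the configuration carries no
cross-week correlation parameter), which makes the baseline covariate
uninformative in the ANCOVA -- a deliberate simplification; real PA
tracks within person.

**Minute encoding.** Each day is a sleep block at 0.9 METs outside the
waking window plus a waking sequence assembled from runs: vigorous and
moderate bouts (lengths from a truncated geometric on 10--60 min, mean
18), scattered 1--9-minute moderate runs carrying the unbouted moderate
minutes, and sedentary/light filler with at least one non-MVPA minute
between qualifying runs so bouts never merge. Day-to-day deviations are
mean-centred within the week, and integer minute totals use
largest-remainder rounding, so the week-level value equals the draw
exactly up to the 1-minute grid. Within-class MET levels are solved per
day (proportional-headroom tilt inside each class interval) so the day's
MET-minute total matches the drawn PAL; kcal follows
$\mathrm{METs}\cdot\mathrm{RMR}/1440$ exactly.

**Steps.** The cadence bands (sedentary 0, light 60--89, moderate
90--119, vigorous $\ge 120$ steps/min) are used as jittered relative
propensities scaled to the day's step target rather than literal
cadences: literal band cadences over the calibrated light + moderate
minutes would imply $\sim$25k steps/day, incompatible with the
calibrated $\sim$7--8k steps/day channel. Steps remain positive only in
non-sedentary worn minutes and correlate with intensity.

**Wear gaps.** Gap counts are Poisson (default 2/day) with geometric
lengths (default mean 15 min), and gaps are punched out of sedentary runs
of the waking window. Placing gaps uniformly anywhere would occasionally
land them inside programmed activity bouts, where resting-rate imputation
would destroy the bout and bias every dimension's recovery; sedentary
placement still exercises the imputation path (the imputed minutes are
sedentary either way, and PAL solving accounts for their 1.0-MET
contribution) while keeping the programmed dimension values exact after
imputation. Device removal during sedentary contexts is also the
plausible regime. With the defaults, wear stays near 97% of the day,
comparable to the reference cohort, and weeks remain valid.

**Within-person day-to-day variation** is not identifiable from the
published summaries; the defaults (CVs: PAL 0.04, sedentary 0.06,
moderate 0.30, steps 0.25) are stated configuration, not reconstructed
values, and do not affect week-level recovery because deviations are
centred within the week.

**What the generator does not emulate:** raw accelerometer/heat-flux
signals, activity-type structure (commuting vs sport), within-person
tracking across assessments, seasonal or day-of-week patterns, dropout
(the reference trial had none), or questionnaire outcomes. Passing
closed-loop tests therefore demonstrates the pipeline's internal
correctness under the programmed statistical structure, not device
validity on real recordings.

## Validation design and numerical choices

* **Zero-variance recovery.** With all SDs at zero and no gaps, the
  pipeline recovers the configured means exactly (up to the 1-minute
  grid); with gaps, values are unchanged. This pins the minute encoding
  as an exact transport layer for the dimension draws.
* **Closed-loop recovery.** `recovery_study()` runs replicate calibrated
  51-participant trials through the full pipeline and compares the mean
  recovered week-12 adjusted difference per dimension with the
  programmed value within 3 Monte-Carlo standard errors of the mean (an
  a priori ~99.7% band for an unbiased pipeline). The shipped study size
  is 200 replicates with 500 bootstrap replications.
* **Oracles.** Bout detection is checked against a brute-force
  minute-scan on 1000+ random minute vectors; the BCa implementation is
  checked against an exhaustive enumeration of all $5^5$ resamples at
  $n = 5$ and against the `boot` package on a skewed fixture.
* **Type-I error.** Under a null configuration (identical arm
  parameters), the 95% BCa interval for the adjusted difference is
  evaluated over 2000 replicate cohorts drawn at the dimension layer --
  the minute layer is a deterministic encoding verified exactly by the
  zero-variance tests, so under the null it shifts both arms identically
  and the rejection rate is unchanged, at a fraction of the cost. Known
  behaviour to expect: percentile-family bootstrap intervals are
  anti-conservative at these sample sizes (particularly $n_2 = 15$), and
  we measure rejection near 7% rather than the nominal 5%; paired
  comparisons show the reference `boot` implementation rejects the same
  datasets. This is a property of small-sample BCa, not of this
  implementation; it is reported rather than patched (e.g. we do not
  widen intervals ad hoc).
* **Degenerate inputs.** Empty days impute fully and are invalid;
  constant bootstrap distributions return a point-mass interval with a
  warning; constant covariates are dropped with a warning; infeasible
  generator means (sedentary + active minutes exceeding the waking
  window, bouted MVPA above $7\times$ moderate) are rejected with a
  diagnostic at configuration time.

## Problem sizes

The shipped validation uses 200 replicate trials (each 51 participants
$\times$ 3 assessment weeks $\times$ 10,080 minutes) with 500-replication
bootstraps, 2000 dimension-layer cohorts for the type-I study, and
1000+ random vectors for the bout oracle. One replicate trial with a
500-rep bootstrap over all six dimensions completes in a few seconds on
one CPU.

## Known limitations

* Between-assessment independence makes the ANCOVA's baseline adjustment
  a no-op in simulation; on real data the adjustment matters and the
  estimator is the same.
* The minute grid quantizes sedentary percentages to steps of about
  0.01% of the waking day and step counts to integers.
* BCa small-sample anti-conservatism, above.
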