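# mdpa — multidimensional physical activity profiles and wearable-feedback trial analysis

Wearable monitors that estimate minute-by-minute energy expenditure make it
possible to describe a person's physical activity (PA) along several
health-relevant dimensions at once, and to feed those dimensions back to the
wearer as concrete health targets. `mdpa` is an R package for researchers
running (or re-analysing) small two-arm trials of such feedback systems. It
implements the full quantitative chain:

1. **Minute processing** — MET-based intensity classification (sedentary
   `< 1.8` METs, light `1.8–3`, moderate `3–6`, vigorous `≥ 6`), resting-rate
   imputation of non-wear minutes (`kcal = RMR/1440`, 1.0 MET), and wear
   validity (a valid day covers ≥ 80 % of an assumed 16-hour waking day;
   a valid week has ≥ 6 valid days).
2. **Six PA dimensions** per participant-week — PAL (total energy
   expenditure / resting metabolic rate), sedentary % of the waking day,
   moderate minutes/day (all minutes ≥ 3 METs), weekly vigorous and MVPA
   minutes accumulated in ≥ 10-minute bouts, and mean daily steps.
3. **Feedback computations** — five traffic-light health targets with a
   configurable amber band, activity tagging (energy cost and intensity of a
   day segment), and forward planning: superimposing planned activities
   (MET values from a bundled mini-compendium, energy cost
   `MET · RMR/1440 · min`) on a recorded week to preview target attainment.
4. **Trial statistics** — the baseline-adjusted ANCOVA
   `follow-up ~ arm + baseline + sex + weight status`, hand-implemented
   bias-corrected and accelerated (BCa) bootstrap CIs (participants resampled
   stratified by arm; bias constant from the bootstrap distribution,
   acceleration from the delete-1 jackknife skewness), Hedges *g* with the
   small-sample correction `J = 1 − 3/(4·df − 1)`, subgroup descriptives and
   a PAL ≥ 2.0 baseline eligibility screen.
5. **A calibrated synthetic cohort generator** — minute-level two-arm trials
   (default 36:15 over three assessment weeks) whose dimension distributions
   are calibrated from published group means and 95 % CIs
   (`sd = CI-halfwidth / z₀.₉₇₅ · √n`), so the whole pipeline can be validated
   closed-loop against programmed ground truth.

## Worked example

Simulate a calibrated 51-participant trial, profile it, and estimate the
week-12 intervention effect on PAL:

```r
library(mdpa)

cfg   <- default_sim_config(seed = 42)
trial <- simulate_trial(cfg)          # 51 x 3 raw minute-level weeks
prof  <- profile_table(trial)         # imputation, validity, 6 dimensions
head(prof, 2)
#>   participant          arm    sex weight_status     week      pal sedentary_pct
#> 1         P01 intervention female             1 baseline 1.590079      92.63393
#> 2         P01 intervention female             1    week6 1.624101      62.76786
#>   moderate_min_day vigorous_bout_min_week mvpa_bout_min_week steps_day
#> 1         40.00000                      0                  0 11450.286
#> 2         34.57143                     85                222  5675.857

adjusted_effect(prof, "pal", "week12", reps = 500, seed = 7)
#> <adjusted_effect> pal at week12
#>   adjusted difference 0.1343 (95% BCa CI 0.03571 to 0.2013)
#>   Hedges g 1.17 (0.2773 to 1.858) | n = 36/15 | 500 bootstrap reps
```

This particular replicate drew an effect of 0.134; the generator programs
0.09 (the published adjusted difference), and across replicate trials the
mean recovered estimate converges to it — that closed loop is the package's
core validation (`recovery_study()`). The per-week feedback side:

```r
reports <- target_report_table(prof, trial$participants)
subset(reports, participant == "P01" & week == "week12")
#>    participant   week      dimension   attained   target direction status
#> 11         P01 week12   calorie_burn 2699.86324 2482.884  at_least  green
#> 12         P01 week12      sedentary   73.83929   65.000   at_most    red
#> 13         P01 week12       moderate  114.57143  120.000  at_least  amber
#> 14         P01 week12     mvpa_bouts  802.00000  150.000  at_least  green
#> 15         P01 week12 vigorous_bouts    0.00000   75.000  at_least    red
```

`run_pipeline(cfg, out_dir = "run1")` executes the whole chain
(simulate → metrics → feedback → analyze) and writes `profiles.tsv`,
`target_reports.tsv`, `effects.tsv`/`.json`, a config snapshot and a run log
with every excluded week and its reason.

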