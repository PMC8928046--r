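# Trial-level simulation configuration and calibration from published
# group summaries.

#' Reference group summaries used to calibrate the default generator
#'
#' Group-level means and 95% CIs for the six physical activity dimensions
#' of a 6-week wearable multidimensional-feedback trial (36 intervention,
#' 15 control; assessments at baseline, 6 and 12 weeks). These printed
#' summaries are the calibration targets for the default synthetic cohort.
#'
#' @return Data frame with columns `dimension`, `arm`, `week`, `mean`,
#'   `ci_low`, `ci_high`.
#' @export
trial_reference_summary <- function() {
  cell <- function(dimension, arm, week, mean, lo, hi) {
    data.frame(
      dimension = dimension, arm = arm, week = week,
      mean = mean, ci_low = lo, ci_high = hi, stringsAsFactors = FALSE
    )
  }
  rows <- list(
    cell("pal", "intervention", "baseline", 1.61, 1.55, 1.66),
    cell("pal", "intervention", "week6", 1.62, 1.57, 1.67),
    cell("pal", "intervention", "week12", 1.67, 1.63, 1.72),
    cell("pal", "control", "baseline", 1.62, 1.55, 1.68),
    cell("pal", "control", "week6", 1.65, 1.58, 1.72),
    cell("pal", "control", "week12", 1.58, 1.52, 1.64),
    cell("sedentary_pct", "intervention", "baseline", 69, 66, 73),
    cell("sedentary_pct", "intervention", "week6", 69, 66, 72),
    cell("sedentary_pct", "intervention", "week12", 66, 63, 69),
    cell("sedentary_pct", "control", "baseline", 69, 64, 73),
    cell("sedentary_pct", "control", "week6", 66, 62, 70),
    cell("sedentary_pct", "control", "week12", 70, 65, 74),
    cell("moderate_min_day", "intervention", "baseline", 111, 94, 129),
    cell("moderate_min_day", "intervention", "week6", 118, 105, 130),
    cell("moderate_min_day", "intervention", "week12", 132, 118, 147),
    cell("moderate_min_day", "control", "baseline", 117, 99, 135),
    cell("moderate_min_day", "control", "week6", 127, 107, 148),
    cell("moderate_min_day", "control", "week12", 109, 89, 131),
    cell("vigorous_bout_min_week", "intervention", "baseline", 42, 23, 65),
    cell("vigorous_bout_min_week", "intervention", "week6", 48, 30, 70),
    cell("vigorous_bout_min_week", "intervention", "week12", 50, 30, 73),
    cell("vigorous_bout_min_week", "control", "baseline", 26, 12, 43),
    cell("vigorous_bout_min_week", "control", "week6", 46, 24, 71),
    cell("vigorous_bout_min_week", "control", "week12", 33, 14, 55),
    cell("mvpa_bout_min_week", "intervention", "baseline", 539, 435, 646),
    cell("mvpa_bout_min_week", "intervention", "week6", 584, 495, 675),
    cell("mvpa_bout_min_week", "intervention", "week12", 658, 571, 750),
    cell("mvpa_bout_min_week", "control", "baseline", 509, 400, 622),
    cell("mvpa_bout_min_week", "control", "week6", 580, 441, 725),
    cell("mvpa_bout_min_week", "control", "week12", 462, 340, 587),
    cell("steps_day", "intervention", "baseline", 7403, 6705, 8093),
    cell("steps_day", "intervention", "week6", 8207, 7269, 9114),
    cell("steps_day", "intervention", "week12", 8782, 7987, 9656),
    cell("steps_day", "control", "baseline", 7767, 6626, 8884),
    cell("steps_day", "control", "week6", 8280, 7268, 9114),
    cell("steps_day", "control", "week12", 7236, 6496, 7991)
  )
  do.call(rbind, rows)
}

#' Reference week-12 adjusted differences programmed into the default
#' generator
#'
#' Baseline-adjusted intervention-minus-control differences at week 12 from
#' the same reference trial: PAL 0.09, daily moderate minutes 24, bouted
#' MVPA 195 min/week, bouted vigorous 18 min/week, steps 1545/day. The
#' sedentary effect was reported as -40 minutes of the waking day; over a
#' 960-minute window that is -4.1667 percentage points.
#'
#' @return Named numeric vector over the six dimensions.
#' @export
reference_adjusted_differences <- function() {
  c(
    pal = 0.09,
    sedentary_pct = -40 / 9.6,
    moderate_min_day = 24,
    vigorous_bout_min_week = 18,
    mvpa_bout_min_week = 195,
    steps_day = 1545
  )
}

#' Convert printed group means and 95% CIs into generator means and SDs
#'
#' The between-person SD implied by a printed group mean and its 95% CI is
#' `sd = (ci_high - ci_low) / (2 * z_0.975) * sqrt(n)`; means are copied
#' through.
#'
#' @param group_summary Data frame with columns `dimension`, `arm`, `week`,
#'   `mean`, `ci_low`, `ci_high` (see [trial_reference_summary()]).
#' @param n_per_group Named vector of group sizes, e.g.
#'   `c(intervention = 36, control = 15)`.
#' @return Data frame with columns `arm`, `week`, `dimension`, `mean`, `sd`
#'   (the `dimension_params` of [sim_config()]).
#' @examples
#' calibrate_from_summary(
#'   data.frame(
#'     dimension = "pal", arm = "intervention", week = "baseline",
#'     mean = 1.61, ci_low = 1.55, ci_high = 1.66
#'   ),
#'   c(intervention = 36)
#' )
#' @export
calibrate_from_summary <- function(group_summary, n_per_group) {
  need <- c("dimension", "arm", "week", "mean", "ci_low", "ci_high")
  if (!all(need %in% names(group_summary))) {
    stop("`group_summary` must have columns ", paste(need, collapse = ", "))
  }
  if (any(group_summary$ci_high < group_summary$ci_low)) {
    stop("ci_high < ci_low in group summary")
  }
  n <- n_per_group[group_summary$arm]
  if (anyNA(n)) stop("`n_per_group` missing an arm present in the summary")
  sd <- (group_summary$ci_high - group_summary$ci_low) /
    (2 * stats::qnorm(0.975)) * sqrt(n)
  data.frame(
    arm = group_summary$arm, week = group_summary$week,
    dimension = group_summary$dimension, mean = group_summary$mean,
    sd = as.numeric(sd), stringsAsFactors = FALSE
  )
}

#' Simulation configuration for a two-arm minute-level trial
#'
#' @param dimension_params Data frame with columns `arm`, `week`,
#'   `dimension`, `mean`, `sd` covering all six dimensions for every
#'   arm/week (see [calibrate_from_summary()]).
#' @param n_intervention,n_control Arm sizes (default 36 and 15).
#' @param weeks Assessment labels, in chronological order.
#' @param day_cv Named within-person day-to-day coefficients of variation
#'   for the daily channels; deviations are centered within the week so the
#'   week-level value equals the drawn one.
#' @param mvpa_moderate_cor Correlation between the daily-moderate and
#'   bouted-MVPA draws (bouted minutes are a subset of moderate minutes).
#' @param gaps_per_day,gap_mean_min Non-wear gap process: mean number of
#'   gaps per day (Poisson) and mean gap length in minutes (geometric).
#' @param waking A [waking_window()].
#' @param bout_len_mean Mean bout length (minutes) of the truncated
#'   geometric bout-length distribution on 10-60 minutes.
#' @param rmr_mean,rmr_sd Resting metabolic rate distribution (kcal/day).
#' @param bmi_mean,bmi_sd BMI distribution (kg/m^2); weight status is the
#'   binary indicator BMI >= 30.
#' @param p_female Probability that a participant is female.
#' @param sex_effect_ratio Multiplier applied to the intervention effect for
#'   female participants (males receive `2 - ratio`); 1 means the effect is
#'   sex-independent.
#' @param start_date Calendar date of the first baseline day.
#' @param seed Integer seed; mandatory for reproducibility.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(dimension_params,
                       n_intervention = 36L, n_control = 15L,
                       weeks = c("baseline", "week6", "week12"),
                       day_cv = c(
                         pal = 0.04, sedentary_pct = 0.06,
                         moderate_min_day = 0.30, steps_day = 0.25
                       ),
                       mvpa_moderate_cor = 0.8,
                       gaps_per_day = 2, gap_mean_min = 15,
                       waking = waking_window(),
                       bout_len_mean = 18,
                       rmr_mean = 1600, rmr_sd = 180,
                       bmi_mean = 28, bmi_sd = 4.5,
                       p_female = 28 / 51,
                       sex_effect_ratio = 1,
                       start_date = as.Date("2026-01-05"),
                       seed = 20260101L) {
  if (n_intervention <= 0L || n_control <= 0L) {
    stop("arm sizes must be positive")
  }
  if (any(dimension_params$sd < 0)) stop("SDs must be non-negative")
  if (mvpa_moderate_cor < 0 || mvpa_moderate_cor >= 1) {
    stop("`mvpa_moderate_cor` must lie in [0, 1)")
  }
  if (gaps_per_day < 0 || gap_mean_min < 0) {
    stop("gap process parameters must be non-negative")
  }
  for (a in c("intervention", "control")) {
    for (w in weeks) {
      cellp <- dimension_params[
        dimension_params$arm == a & dimension_params$week == w,
      ]
      if (!setequal(cellp$dimension, dimension_names())) {
        stop("dimension_params incomplete for ", a, "/", w)
      }
      m <- stats::setNames(cellp$mean, cellp$dimension)
      budget <- waking$length * m[["sedentary_pct"]] / 100 +
        m[["moderate_min_day"]]
      if (budget > waking$length) {
        stop(
          "infeasible dimension means for ", a, "/", w,
          ": sedentary + moderate minutes exceed the waking window"
        )
      }
      if (m[["mvpa_bout_min_week"]] > 7 * m[["moderate_min_day"]]) {
        stop(
          "infeasible dimension means for ", a, "/", w,
          ": bouted MVPA exceeds 7 x daily moderate minutes"
        )
      }
    }
  }
  structure(
    list(
      dimension_params = dimension_params,
      n_intervention = as.integer(n_intervention),
      n_control = as.integer(n_control),
      weeks = weeks, day_cv = day_cv,
      mvpa_moderate_cor = mvpa_moderate_cor,
      gaps_per_day = gaps_per_day, gap_mean_min = gap_mean_min,
      waking = waking, bout_len_mean = bout_len_mean,
      rmr_mean = rmr_mean, rmr_sd = rmr_sd,
      bmi_mean = bmi_mean, bmi_sd = bmi_sd,
      p_female = p_female, sex_effect_ratio = sex_effect_ratio,
      start_date = start_date, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default generator configuration calibrated to the reference trial
#'
#' Between-person SDs come from [calibrate_from_summary()] applied to
#' [trial_reference_summary()]; each arm keeps its printed baseline and
#' week-6 means, and the intervention week-12 mean is set to the control
#' week-12 mean plus the printed adjusted difference
#' ([reference_adjusted_differences()]), so the programmed week-12 effects
#' are exactly the published ones.
#'
#' @param seed Integer seed.
#' @param ... Further arguments passed to [sim_config()].
#' @return A [sim_config()].
#' @export
default_sim_config <- function(seed = 20260101L, ...) {
  params <- calibrate_from_summary(
    trial_reference_summary(),
    c(intervention = 36, control = 15)
  )
  diffs <- reference_adjusted_differences()
  for (dm in names(diffs)) {
    ctl <- params$mean[params$arm == "control" & params$week == "week12" &
      params$dimension == dm]
    params$mean[params$arm == "intervention" & params$week == "week12" &
      params$dimension == dm] <- ctl + diffs[[dm]]
  }
  sim_config(params, seed = seed, ...)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d intervention / %d control | weeks: %s | seed %d\n",
    x$n_intervention, x$n_control, paste(x$weeks, collapse = ", "), x$seed
  ))
  invisible(x)
}

#' Extract per-arm per-week generator parameters
#'
#' @param config A [sim_config()].
#' @param arm `"intervention"` or `"control"`.
#' @param week Assessment label.
#' @param sex Optional participant sex (`"female"`/`"male"`); when the
#'   config programs a sex-dependent effect, the intervention means are
#'   shifted accordingly.
#' @return Parameter list consumed by [simulate_participant_week()].
#' @export
arm_week_params <- function(config, arm, week, sex = NULL) {
  pick <- function(a) {
    cellp <- config$dimension_params[
      config$dimension_params$arm == a &
        config$dimension_params$week == week,
    ]
    list(
      mean = stats::setNames(cellp$mean, cellp$dimension)[dimension_names()],
      sd = stats::setNames(cellp$sd, cellp$dimension)[dimension_names()]
    )
  }
  p <- pick(arm)
  r <- config$sex_effect_ratio
  if (!is.null(sex) && r != 1 && arm == "intervention") {
    ctl <- pick("control")
    effect <- p$mean - ctl$mean
    mult <- if (identical(sex, "female")) r else 2 - r
    p$mean <- ctl$mean + mult * effect
  }
  week_index <- match(week, config$weeks) - 1L
  c(p, list(
    day_cv = config$day_cv,
    mvpa_moderate_cor = config$mvpa_moderate_cor,
    gaps_per_day = config$gaps_per_day,
    gap_mean_min = config$gap_mean_min,
    bout_len_mean = config$bout_len_mean,
    waking = config$waking,
    start_date = config$start_date + 42L * week_index
  ))
}

draw_participants <- function(config) {
  n <- config$n_intervention + config$n_control
  bmi <- stats::rnorm(n, config$bmi_mean, config$bmi_sd)
  data.frame(
    participant = sprintf("P%02d", seq_len(n)),
    arm = rep(c("intervention", "control"),
      c(config$n_intervention, config$n_control)
    ),
    sex = ifelse(stats::runif(n) < config$p_female, "female", "male"),
    bmi = bmi,
    weight_status = as.integer(bmi >= 30),
    rmr_kcal_day = pmax(stats::rnorm(n, config$rmr_mean, config$rmr_sd), 1000),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete two-arm minute-level trial
#'
#' Draws the participant table (arm, sex, BMI, weight status, RMR) and one
#' raw minute-level week per participant and assessment occasion. Fully
#' reproducible: the same config (including its seed) yields an identical
#' trial.
#'
#' @param config A [sim_config()].
#' @return Object of class `simulated_trial`: `participants` (data frame),
#'   `weeks` (named list of [simulate_participant_week()] raw weeks, keyed
#'   `"<participant>.<week>"`) and the `config`.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  participants <- draw_participants(config)
  n <- nrow(participants)
  nw <- length(config$weeks)
  seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, n * nw), n, nw
  )
  params_cache <- new.env(parent = emptyenv())
  get_params <- function(arm, label, sex) {
    key <- paste(arm, label, sex, sep = "|")
    if (is.null(params_cache[[key]])) {
      params_cache[[key]] <- arm_week_params(config, arm, label, sex)
    }
    params_cache[[key]]
  }
  weeks <- list()
  for (i in seq_len(n)) {
    for (w in seq_len(nw)) {
      label <- config$weeks[w]
      params <- get_params(participants$arm[i], label, participants$sex[i])
      attrs <- list(
        participant = participants$participant[i],
        rmr_kcal_day = participants$rmr_kcal_day[i],
        label = label
      )
      weeks[[paste(participants$participant[i], label, sep = ".")]] <-
        simulate_participant_week(params, attrs, seed = seeds[i, w])
    }
  }
  structure(
    list(participants = participants, weeks = weeks, config = config),
    class = "simulated_trial"
  )
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat(sprintf(
    "<simulated_trial> %d participants (%d intervention / %d control), %d assessment weeks\n",
    nrow(x$participants), sum(x$participants$arm == "intervention"),
    sum(x$participants$arm == "control"), length(x$config$weeks)
  ))
  invisible(x)
}

#' Process a simulated trial into a long table of dimension profiles
#'
#' Runs every raw participant-week through imputation, validity checking
#' and dimension computation. Invalid weeks are excluded and recorded in
#' the `exclusions` attribute with the reason.
#'
#' @param trial A [simulate_trial()] result.
#' @return Data frame with one row per valid participant-week: participant
#'   attributes, `week`, and the six dimension columns. Attribute
#'   `exclusions` is a data frame of excluded weeks.
#' @export
profile_table <- function(trial) {
  stopifnot(inherits(trial, "simulated_trial"))
  rows <- list()
  excl <- list()
  for (key in names(trial$weeks)) {
    raw <- trial$weeks[[key]]
    pw <- process_raw_week(raw)
    meta <- trial$participants[
      trial$participants$participant == raw$participant, ,
      drop = FALSE
    ]
    if (!pw$valid) {
      excl[[key]] <- data.frame(
        participant = raw$participant, week = raw$label,
        reason = sprintf("only %d valid days (< 6)", pw$n_valid_days),
        stringsAsFactors = FALSE
      )
      next
    }
    prof <- as.data.frame(multidimensional_profile(pw))
    rows[[key]] <- data.frame(
      participant = raw$participant, arm = meta$arm, sex = meta$sex,
      weight_status = meta$weight_status, week = raw$label,
      prof[dimension_names()],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl) > 0L) {
    do.call(rbind, excl)
  } else {
    data.frame(
      participant = character(0), week = character(0),
      reason = character(0)
    )
  }
  out
}

#' Draw a profile table directly at the dimension level
#'
#' Samples the same per-participant-week dimension distributions as
#' [simulate_trial()] but skips the minute-level encoding/decoding, which
#' is a deterministic transformation of the draws. Intended for large
#' replicate studies (e.g. type-I-error calibration) where simulating
#' minutes adds nothing but time.
#'
#' @param config A [sim_config()].
#' @return Data frame in the same layout as [profile_table()].
#' @export
simulate_profile_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  participants <- draw_participants(config)
  rows <- list()
  for (w in config$weeks) {
    for (i in seq_len(nrow(participants))) {
      params <- arm_week_params(
        config, participants$arm[i], w, participants$sex[i]
      )
      dims <- draw_week_dimensions(
        params$mean, params$sd, params$mvpa_moderate_cor
      )
      rows[[paste(i, w)]] <- data.frame(
        participant = participants$participant[i],
        arm = participants$arm[i], sex = participants$sex[i],
        weight_status = participants$weight_status[i], week = w,
        as.list(dims), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
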