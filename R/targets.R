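# Traffic-light health targets, activity tagging and forward planning:
# the feedback computations behind a multidimensional activity display.

#' Define the five health targets of the feedback display
#'
#' The five targets are daily calorie burn (kcal/day, at-least), sedentary
#' time (max % of the waking day, at-most), daily moderate-intensity minutes
#' (at-least), weekly MVPA in >=10-minute bouts (at-least) and weekly
#' vigorous activity in >=10-minute bouts (at-least). Default magnitudes
#' follow public-health guideline values and a calorie-burn target of
#' 1.6 x RMR; every target is personalizable.
#'
#' @param rmr_kcal_day Resting metabolic rate used to personalize the
#'   default calorie-burn target.
#' @param calorie_burn_target kcal/day to burn (default `1.6 * rmr`).
#' @param sedentary_target Maximum sedentary share of the waking day (%).
#' @param moderate_target Minutes/day of moderate-intensity activity.
#' @param mvpa_bout_target Minutes/week of bouted MVPA.
#' @param vigorous_bout_target Minutes/week of bouted vigorous activity.
#' @param amber_band Proportional band around a target within which a missed
#'   target still shows amber ("close to target"); default 0.10.
#' @return Object of class `health_targets`.
#' @export
health_targets <- function(rmr_kcal_day = 1600,
                           calorie_burn_target = 1.6 * rmr_kcal_day,
                           sedentary_target = 65,
                           moderate_target = 120,
                           mvpa_bout_target = 150,
                           vigorous_bout_target = 75,
                           amber_band = 0.10) {
  if (calorie_burn_target <= 0 || moderate_target <= 0 ||
    mvpa_bout_target <= 0 || vigorous_bout_target <= 0) {
    stop("all at-least targets must be positive")
  }
  if (sedentary_target <= 0 || sedentary_target > 100) {
    stop("`sedentary_target` must lie in (0, 100]")
  }
  if (amber_band < 0 || amber_band >= 1) stop("`amber_band` must be in [0, 1)")
  structure(
    list(
      calorie_burn_target = calorie_burn_target,
      sedentary_target = sedentary_target,
      moderate_target = moderate_target,
      mvpa_bout_target = mvpa_bout_target,
      vigorous_bout_target = vigorous_bout_target,
      amber_band = amber_band
    ),
    class = "health_targets"
  )
}

traffic_light <- function(value, target, direction, band) {
  if (direction == "at_least") {
    if (value >= target) "green" else if (value >= target * (1 - band)) {
      "amber"
    } else {
      "red"
    }
  } else {
    if (value <= target) "green" else if (value <= target * (1 + band)) {
      "amber"
    } else {
      "red"
    }
  }
}

#' Evaluate traffic-light attainment of the five health targets
#'
#' Green indicates a hit target, amber close to the target (within the
#' proportional amber band) and red a missed target. Sedentary time is the
#' only at-most dimension; all others are at-least.
#'
#' @param profile A [multidimensional_profile()] from a valid week.
#' @param targets A [health_targets()] set.
#' @return Object of class `target_report`: a data frame with one row per
#'   target (`dimension`, `attained`, `target`, `direction`, `status`).
#' @export
evaluate_targets <- function(profile, targets) {
  stopifnot(
    inherits(profile, "dimension_profile"),
    inherits(targets, "health_targets")
  )
  attained <- c(
    calorie_burn = as.numeric(attr(profile, "tee_kcal_day")),
    sedentary = profile$sedentary_pct,
    moderate = profile$moderate_min_day,
    mvpa_bouts = profile$mvpa_bout_min_week,
    vigorous_bouts = profile$vigorous_bout_min_week
  )
  target <- c(
    calorie_burn = targets$calorie_burn_target,
    sedentary = targets$sedentary_target,
    moderate = targets$moderate_target,
    mvpa_bouts = targets$mvpa_bout_target,
    vigorous_bouts = targets$vigorous_bout_target
  )
  direction <- c(
    calorie_burn = "at_least", sedentary = "at_most",
    moderate = "at_least", mvpa_bouts = "at_least",
    vigorous_bouts = "at_least"
  )
  status <- mapply(traffic_light, attained, target, direction,
    MoreArgs = list(band = targets$amber_band)
  )
  structure(
    data.frame(
      dimension = names(attained),
      attained = unname(attained),
      target = unname(target),
      direction = unname(direction),
      status = unname(status),
      stringsAsFactors = FALSE
    ),
    class = c("target_report", "data.frame")
  )
}

#' @export
print.target_report <- function(x, ...) {
  cat("<target_report>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Personalized energy cost of an activity
#'
#' The energy cost of an activity scales the participant's measured resting
#' metabolic rate: `kcal = MET * (rmr/1440) * duration`. One MET for any
#' duration therefore costs exactly the resting rate, consistent with the
#' non-wear imputation rule.
#'
#' @param met_value MET value of the activity (e.g. from the bundled
#'   [met_compendium()]).
#' @param duration_min Duration in minutes.
#' @param rmr_kcal_day Resting metabolic rate, kcal/day.
#' @return Numeric kcal, with attribute `intensity` giving the activity's
#'   intensity class.
#' @examples
#' activity_energy_cost(4, 60, 1440) # 240 kcal
#' @export
activity_energy_cost <- function(met_value, duration_min, rmr_kcal_day) {
  if (any(met_value <= 0) || any(duration_min <= 0) || any(rmr_kcal_day <= 0)) {
    stop("all inputs must be positive")
  }
  kcal <- met_value * (rmr_kcal_day / 1440) * duration_min
  attr(kcal, "intensity") <- as.character(classify_intensity(met_value))
  kcal
}

#' Review (tag) a segment of a day
#'
#' Summarizes the half-open minute interval `[start_minute, end_minute)` of
#' one day of a week: total energy expenditure, mean METs and the minutes
#' spent in each intensity class (the class counts partition the segment).
#'
#' @param week A [validate_week()] participant week.
#' @param day Day index within the week (1-7).
#' @param start_minute,end_minute 0-based minute-of-day offsets delimiting
#'   the half-open segment; `0 <= start < end <= 1440`.
#' @return List with `kcal`, `mean_mets`, `minutes` (named count per
#'   intensity class) and `n_minutes`.
#' @export
tag_segment <- function(week, day, start_minute, end_minute) {
  stopifnot(inherits(week, "participant_week"))
  if (length(day) != 1L || day < 1L || day > 7L) stop("`day` must be 1..7")
  if (start_minute < 0 || end_minute > 1440 || start_minute >= end_minute) {
    stop("segment must satisfy 0 <= start_minute < end_minute <= 1440")
  }
  idx <- (start_minute + 1L):end_minute
  mets <- week$mets[day, idx]
  counts <- table(factor(as.character(classify_intensity(mets)),
    levels = intensity_levels()
  ))
  list(
    kcal = sum(week$kcal[day, idx]),
    mean_mets = mean(mets),
    minutes = as.numeric(counts) |> stats::setNames(intensity_levels()),
    n_minutes = length(idx)
  )
}

#' Describe a planned activity
#'
#' @param name Activity name (for reporting).
#' @param met_value MET value of the activity.
#' @param start Clock time (`"HH:MM"`) at which the activity starts.
#' @param duration Duration in minutes (>= 1).
#' @param days Days of the week (1-7, indices into the participant week) on
#'   which the activity is performed.
#' @return Object of class `planned_activity`.
#' @export
planned_activity <- function(name, met_value, start, duration, days = 1:7) {
  if (met_value <= 0) stop("`met_value` must be positive")
  if (duration < 1) stop("`duration` must be at least 1 minute")
  if (any(days < 1 | days > 7)) stop("`days` must be in 1..7")
  s <- clock_to_minute(start)
  if (s + duration > 1440) stop("activity runs past midnight")
  structure(
    list(
      name = name, met_value = met_value, start = s,
      duration = as.integer(duration), days = as.integer(days)
    ),
    class = "planned_activity"
  )
}

# cadence used for planned minutes, by intensity class code
plan_cadence <- function(code) c(0, 75, 105, 130)[code]

#' Superimpose planned activities on a week
#'
#' Replaces the underlying minutes of the week with the planned activity
#' (METs from the plan, kcal from [activity_energy_cost()] per minute,
#' steps from the intensity-class cadence band), then recomputes the
#' dimension profile and target attainment on the modified week. The
#' original week is not modified.
#'
#' @param week A valid [validate_week()] participant week.
#' @param plans A [planned_activity()] or list of them; planned intervals
#'   must not overlap one another.
#' @param targets A [health_targets()] set.
#' @return List with the hypothetical `profile`
#'   ([multidimensional_profile()]), the `report` ([evaluate_targets()])
#'   and the modified `week`.
#' @export
plan_superimpose <- function(week, plans, targets = health_targets(week$rmr_kcal_day)) {
  assert_valid_week(week)
  if (inherits(plans, "planned_activity")) plans <- list(plans)
  stopifnot(all(vapply(plans, inherits, logical(1), "planned_activity")))

  covered <- matrix(FALSE, 7L, 1440L)
  new_week <- week
  for (p in plans) {
    idx <- (p$start + 1L):(p$start + p$duration)
    for (d in p$days) {
      if (any(covered[d, idx])) {
        stop("planned activities overlap (day ", d, ", '", p$name, "')")
      }
      covered[d, idx] <- TRUE
      code <- intensity_code(p$met_value)
      new_week$mets[d, idx] <- p$met_value
      new_week$kcal[d, idx] <- p$met_value * week$rmr_kcal_day / 1440
      new_week$steps[d, idx] <- plan_cadence(code)
      new_week$imputed[d, idx] <- FALSE
    }
  }
  profile <- multidimensional_profile(new_week)
  list(
    profile = profile,
    report = evaluate_targets(profile, targets),
    week = new_week
  )
}

#' Bundled mini-compendium of activity MET values
#'
#' A small table of common activities with compendium-style MET values used
#' to populate the planning menu. This is a package-curated subset, not the
#' full published compendium.
#'
#' @return Data frame with columns `activity`, `met_value`, `category`.
#' @export
met_compendium <- function() {
  path <- system.file("extdata", "met_compendium.tsv", package = "mdpa")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
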