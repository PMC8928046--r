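# Six health-harnessing physical activity dimensions computed from a valid
# participant week. Daily dimensions are averaged over valid days; weekly
# bouted dimensions are summed over valid days and normalized to a 7-day
# week (7/n_valid), which is exact when all 7 days are valid.

assert_valid_week <- function(week) {
  if (!inherits(week, "participant_week")) {
    stop("expected a participant_week object")
  }
  if (!week$valid) {
    stop(
      "week for participant '", week$participant, "' [", week$label,
      "] is invalid (", week$n_valid_days, " valid days < 6) and is ",
      "excluded from analysis"
    )
  }
  invisible(week)
}

#' Physical activity level (PAL) of a participant week
#'
#' PAL is total daily energy expenditure divided by the resting metabolic
#' rate, averaged over the valid days of the week. A week in which every
#' minute is spent at the resting rate has PAL 1.
#'
#' @param week A valid [validate_week()] participant week.
#' @return Numeric scalar, PAL (unitless, > 0).
#' @export
compute_pal <- function(week) {
  assert_valid_week(week)
  tee <- rowSums(week$kcal[week$day_valid, , drop = FALSE])
  mean(tee / week$rmr_kcal_day)
}

#' Sedentary time as a percentage of the waking day
#'
#' Share of waking-window minutes below 1.8 METs (imputed minutes sit at
#' 1.0 MET and therefore count as sedentary), averaged over valid days.
#'
#' @inheritParams compute_pal
#' @return Numeric scalar in `[0, 100]`.
#' @export
sedentary_percent <- function(week) {
  assert_valid_week(week)
  m <- week$mets[week$day_valid, week$waking$mask, drop = FALSE]
  mean(rowSums(m < met_cutpoints()[["light"]]) / week$waking$length) * 100
}

#' Daily minutes of moderate-intensity activity
#'
#' Counts every minute at or above 3.0 METs (vigorous minutes included),
#' averaged over valid days.
#'
#' @inheritParams compute_pal
#' @return Numeric scalar, minutes per day.
#' @export
moderate_minutes_daily <- function(week) {
  assert_valid_week(week)
  m <- week$mets[week$day_valid, , drop = FALSE]
  mean(rowSums(m >= met_cutpoints()[["moderate"]]))
}

# Minutes accumulated in qualifying bouts within one day's MET vector.
# Strict contiguity by default; `max_interruption` > 0 allows runs separated
# by that many sub-threshold minutes to merge (only qualifying minutes are
# counted toward the bout length).
day_bout_minutes <- function(mets, threshold, min_bout_len, max_interruption) {
  r <- rle(mets >= threshold)
  if (max_interruption <= 0) {
    len <- r$lengths[r$values]
    return(sum(len[len >= min_bout_len]))
  }
  n <- length(r$lengths)
  total <- 0
  cur <- 0 # qualifying minutes in the open bout window
  for (i in seq_len(n)) {
    if (r$values[i]) {
      cur <- cur + r$lengths[i]
    } else {
      bridge <- cur > 0 && r$lengths[i] <= max_interruption &&
        i < n && r$values[i + 1L]
      if (!bridge) {
        if (cur >= min_bout_len) total <- total + cur
        cur <- 0
      }
    }
  }
  if (cur >= min_bout_len) total <- total + cur
  total
}

#' Weekly minutes accumulated in sustained activity bouts
#'
#' Sums, over the week, the lengths of maximal runs of consecutive minutes
#' at or above `met_threshold` whose run length reaches `min_bout_len`
#' minutes. Runs are detected within each calendar day (bouts do not span
#' midnight), the entire maximal run counts (a 23-minute run contributes
#' 23 minutes), and the week total is normalized to 7 days when only 6 days
#' are valid.
#'
#' @inheritParams compute_pal
#' @param met_threshold MET threshold defining the bout: 3.0 for MVPA bouts
#'   or 6.0 for vigorous bouts.
#' @param min_bout_len Minimum qualifying run length in minutes (default 10).
#' @param max_interruption Interruption allowance in minutes: sub-threshold
#'   runs of at most this length between qualifying runs do not break a
#'   bout. The default 0 is strict contiguity.
#' @return Numeric scalar, bouted minutes per week.
#' @export
bouted_minutes <- function(week, met_threshold, min_bout_len = 10,
                           max_interruption = 0) {
  assert_valid_week(week)
  if (min_bout_len < 1) stop("`min_bout_len` must be at least 1 minute")
  days <- which(week$day_valid)
  total <- sum(vapply(
    days,
    function(d) {
      day_bout_minutes(
        week$mets[d, ], met_threshold, min_bout_len,
        max_interruption
      )
    },
    numeric(1)
  ))
  total * 7 / week$n_valid_days
}

#' Mean daily step count
#'
#' @inheritParams compute_pal
#' @return Numeric scalar, steps per day (mean over valid days).
#' @export
mean_daily_steps <- function(week) {
  assert_valid_week(week)
  mean(rowSums(week$steps[week$day_valid, , drop = FALSE]))
}

#' The six physical activity dimensions of a participant week
#'
#' Aggregates [compute_pal()], [sedentary_percent()],
#' [moderate_minutes_daily()], [bouted_minutes()] at 3.0 and 6.0 METs, and
#' [mean_daily_steps()] into one profile.
#'
#' @inheritParams compute_pal
#' @return Object of class `dimension_profile`: a named list with elements
#'   `pal`, `sedentary_pct`, `moderate_min_day`, `vigorous_bout_min_week`,
#'   `mvpa_bout_min_week`, `steps_day`, plus attributes `tee_kcal_day`
#'   (mean daily total energy expenditure), `rmr_kcal_day`, `participant`
#'   and `label`.
#' @export
multidimensional_profile <- function(week) {
  assert_valid_week(week)
  pal <- compute_pal(week)
  prof <- structure(
    list(
      pal = pal,
      sedentary_pct = sedentary_percent(week),
      moderate_min_day = moderate_minutes_daily(week),
      vigorous_bout_min_week = bouted_minutes(week, 6.0),
      mvpa_bout_min_week = bouted_minutes(week, 3.0),
      steps_day = mean_daily_steps(week)
    ),
    class = "dimension_profile",
    tee_kcal_day = pal * week$rmr_kcal_day,
    rmr_kcal_day = week$rmr_kcal_day,
    participant = week$participant,
    label = week$label
  )
  stopifnot(
    prof$pal > 0,
    prof$sedentary_pct >= 0, prof$sedentary_pct <= 100,
    prof$mvpa_bout_min_week >= prof$vigorous_bout_min_week,
    prof$moderate_min_day * 7 >= prof$mvpa_bout_min_week - 1e-9
  )
  prof
}

#' @export
print.dimension_profile <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<dimension_profile> %s [%s]\n",
      "  PAL %.2f | sedentary %.1f%% waking | moderate %.1f min/d\n",
      "  bouted MVPA %.0f min/wk | bouted vigorous %.0f min/wk | ",
      "steps %.0f /d\n"
    ),
    attr(x, "participant"), attr(x, "label"),
    x$pal, x$sedentary_pct, x$moderate_min_day,
    x$mvpa_bout_min_week, x$vigorous_bout_min_week, x$steps_day
  ))
  invisible(x)
}

#' @export
as.data.frame.dimension_profile <- function(x, ...) {
  data.frame(
    participant = attr(x, "participant"), label = attr(x, "label"),
    pal = x$pal, sedentary_pct = x$sedentary_pct,
    moderate_min_day = x$moderate_min_day,
    vigorous_bout_min_week = x$vigorous_bout_min_week,
    mvpa_bout_min_week = x$mvpa_bout_min_week,
    steps_day = x$steps_day,
    stringsAsFactors = FALSE
  )
}

dimension_names <- function() {
  c(
    "pal", "sedentary_pct", "moderate_min_day",
    "vigorous_bout_min_week", "mvpa_bout_min_week", "steps_day"
  )
}
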