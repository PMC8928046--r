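#' Define the assumed waking window of a day
#'
#' Wear-time validity and the sedentary-percentage denominator are assessed
#' against an assumed 16-hour waking day. The window is anchored at fixed
#' clock times, 07:00--23:00 by default, and is configurable.
#'
#' @param start,end Clock times (`"HH:MM"`) delimiting the waking window.
#' @return Object of class `waking_window`: a list with the start/end minute
#'   of day (0-based), the window length in minutes and a 1440-long logical
#'   mask that is `TRUE` for waking minutes.
#' @export
waking_window <- function(start = "07:00", end = "23:00") {
  s <- clock_to_minute(start)
  e <- clock_to_minute(end)
  if (e <= s) stop("waking window must end after it starts (within one day)")
  mask <- rep(FALSE, 1440L)
  mask[(s + 1L):e] <- TRUE
  structure(
    list(start_min = s, end_min = e, length = e - s, mask = mask),
    class = "waking_window"
  )
}

clock_to_minute <- function(x) {
  if (is.numeric(x)) {
    m <- as.integer(x)
  } else {
    parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) stop("clock times must be given as 'HH:MM'")
    m <- as.integer(parts[1L]) * 60L + as.integer(parts[2L])
  }
  if (is.na(m) || m < 0L || m > 1440L) stop("clock time out of range")
  m
}

# Construct a day_profile from complete 1440-minute vectors (internal core,
# shared by the public imputation interface and the simulator's fast path).
new_day_profile <- function(date, mets, kcal, steps, wear, imputed, waking) {
  wfw <- sum(wear[waking$mask]) / waking$length
  structure(
    list(
      date = date, mets = mets, kcal = kcal, steps = steps,
      wear = wear, imputed = imputed, waking = waking,
      wear_fraction_waking = wfw, valid = wfw >= 0.80
    ),
    class = "day_profile"
  )
}

# Core imputation on raw 1440-minute vectors where `wear` marks observed
# minutes; everything else is filled at resting metabolic rate.
impute_day_vectors <- function(date, mets, kcal, steps, wear, rmr_kcal_day,
                               waking) {
  imputed <- !wear
  if (any(imputed)) {
    mets[imputed] <- 1.0
    kcal[imputed] <- rmr_kcal_day / 1440
    steps[imputed] <- 0L
  }
  new_day_profile(date, mets, kcal, steps, wear, imputed, waking)
}

#' Impute non-wear minutes and assemble a complete 24-hour day
#'
#' Raw minute records for one calendar day are completed to exactly 1440
#' minutes. Every minute that is missing from the records or flagged as
#' non-wear is assigned the resting metabolic rate: `kcal = rmr/1440`,
#' `mets = 1.0`, `steps = 0`, and marked as imputed. Observed minutes are
#' never altered. Wear fraction is computed over the waking window only, and
#' the day is valid when at least 80% of waking minutes were worn.
#'
#' @param records Data frame of raw minute records with columns `mets`,
#'   `kcal`, `steps`, `wear` (0/1 or logical) and either `timestamp`
#'   (POSIXct or `"YYYY-MM-DDTHH:MM:SS"` strings) or `minute` (0-based
#'   minute of day). Rows may be missing; missing minutes are treated as
#'   non-wear. A zero-row data frame yields a fully imputed day.
#' @param rmr_kcal_day Resting metabolic rate in kcal/day; must be positive.
#' @param date Calendar date of the day (`Date`); required when `records`
#'   carries no timestamp.
#' @param waking A [waking_window()].
#' @return Object of class `day_profile` with fields `date`, 1440-long
#'   vectors `mets`, `kcal`, `steps`, `wear`, `imputed`, plus
#'   `wear_fraction_waking` and the `valid` flag.
#' @export
impute_nonwear <- function(records, rmr_kcal_day, date = NULL,
                           waking = waking_window()) {
  if (!is.numeric(rmr_kcal_day) || length(rmr_kcal_day) != 1L ||
    is.na(rmr_kcal_day) || rmr_kcal_day <= 0) {
    stop("`rmr_kcal_day` must be a single positive number")
  }
  if (!is.data.frame(records)) stop("`records` must be a data frame")

  if (nrow(records) > 0L && "timestamp" %in% names(records)) {
    ts <- records$timestamp
    if (!inherits(ts, "POSIXct")) {
      ts <- as.POSIXct(as.character(ts),
        format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"
      )
      if (anyNA(ts)) stop("unparseable timestamps (expected ISO-8601)")
    }
    dates <- as.Date(ts, tz = "UTC")
    if (length(unique(dates)) > 1L) {
      stop("records span more than one calendar day")
    }
    if (is.null(date)) date <- dates[1L]
    lt <- as.POSIXlt(ts, tz = "UTC")
    minute <- lt$hour * 60L + lt$min
  } else if (nrow(records) > 0L && "minute" %in% names(records)) {
    minute <- as.integer(records$minute)
    if (any(minute < 0L | minute > 1439L)) stop("minute of day out of range")
  } else {
    minute <- integer(0)
  }
  if (anyDuplicated(minute)) stop("duplicate timestamps in minute records")
  if (is.null(date)) stop("`date` is required when records carry no timestamp")

  mets <- numeric(1440L)
  kcal <- numeric(1440L)
  steps <- integer(1440L)
  wear <- logical(1440L)
  if (length(minute) > 0L) {
    i <- minute + 1L
    w <- as.logical(records$wear)
    if (any(records$mets < 0, na.rm = TRUE) ||
      any(records$kcal < 0, na.rm = TRUE) ||
      any(records$steps < 0, na.rm = TRUE)) {
      stop("mets, kcal and steps must be non-negative")
    }
    wear[i] <- w
    mets[i] <- ifelse(w, records$mets, 0)
    kcal[i] <- ifelse(w, records$kcal, 0)
    steps[i] <- ifelse(w, as.integer(records$steps), 0L)
  }
  impute_day_vectors(date, mets, kcal, steps, wear, rmr_kcal_day, waking)
}

#' Assemble and validity-check seven days into a participant week
#'
#' Flags each day valid when at least 80% of the waking window was worn
#' (768 of 960 minutes under the default 16-hour window) and the week valid
#' when at least 6 of the 7 days are valid.
#'
#' @param days List of exactly 7 [impute_nonwear()] day profiles covering
#'   consecutive calendar dates.
#' @param rmr_kcal_day Resting metabolic rate (kcal/day) of the participant.
#' @param participant,label Identifier of the participant and of the
#'   assessment occasion (e.g. `"baseline"`).
#' @return Object of class `participant_week`: minute matrices (7 x 1440)
#'   `mets`, `kcal`, `steps`, `imputed`, per-day wear fractions and validity
#'   flags, the number of valid days, and the overall `valid` flag.
#' @export
validate_week <- function(days, rmr_kcal_day, participant = "", label = "") {
  if (!is.list(days) || length(days) != 7L) {
    stop("a participant week requires exactly 7 day profiles")
  }
  if (!all(vapply(days, inherits, logical(1), "day_profile"))) {
    stop("`days` must be a list of day_profile objects")
  }
  dates <- as.Date(vapply(days, function(d) as.character(d$date), character(1)))
  if (any(diff(dates) != 1L)) stop("days must cover consecutive dates")
  if (rmr_kcal_day <= 0) stop("`rmr_kcal_day` must be positive")

  grab <- function(field, mode = "numeric") {
    t(vapply(days, function(d) as.vector(d[[field]], mode), vector(mode, 1440L)))
  }
  wfw <- vapply(days, function(d) d$wear_fraction_waking, numeric(1))
  day_valid <- wfw >= 0.80
  structure(
    list(
      participant = participant, label = label, dates = dates,
      mets = grab("mets"), kcal = grab("kcal"), steps = grab("steps"),
      imputed = grab("imputed", "logical"),
      waking = days[[1L]]$waking,
      rmr_kcal_day = rmr_kcal_day,
      wear_fraction_waking = wfw,
      day_valid = day_valid,
      n_valid_days = sum(day_valid),
      valid = sum(day_valid) >= 6L
    ),
    class = "participant_week"
  )
}

#' @export
print.day_profile <- function(x, ...) {
  cat(
    sprintf(
      "<day_profile> %s | wear %.1f%% of waking window | %s | %d imputed min\n",
      format(x$date), 100 * x$wear_fraction_waking,
      if (x$valid) "valid" else "invalid", sum(x$imputed)
    )
  )
  invisible(x)
}

#' @export
print.participant_week <- function(x, ...) {
  cat(sprintf(
    "<participant_week> %s [%s] %s..%s | %d/7 valid days | week %s\n",
    x$participant, x$label, format(x$dates[1]), format(x$dates[7]),
    x$n_valid_days, if (x$valid) "valid" else "invalid"
  ))
  invisible(x)
}

# --- minute CSV dialect ----------------------------------------------------

#' Write raw minute records to CSV
#'
#' Writes the minute CSV dialect used throughout the package: columns
#' `timestamp` (ISO-8601, 1-minute cadence), `mets`, `kcal`, `steps`,
#' `wear` (0/1).
#'
#' @param records Data frame of minute records (as produced by
#'   [raw_week_records()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_minute_csv <- function(records, path) {
  stopifnot(all(c("timestamp", "mets", "kcal", "steps", "wear") %in%
    names(records)))
  out <- data.frame(
    timestamp = format(records$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    mets = sprintf("%.6g", records$mets),
    kcal = sprintf("%.6g", records$kcal),
    steps = as.integer(records$steps),
    wear = as.integer(records$wear)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read raw minute records from CSV
#'
#' Reads the minute CSV dialect written by [write_minute_csv()]. Missing
#' rows are tolerated downstream (treated as non-wear by
#' [impute_nonwear()]); timestamps are UTC-naive local times.
#'
#' @param path CSV file path.
#' @return Data frame with `timestamp` (POSIXct), `mets`, `kcal`, `steps`,
#'   `wear` columns.
#' @export
read_minute_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$timestamp <- as.POSIXct(x$timestamp,
    format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"
  )
  if (anyNA(x$timestamp)) stop("unparseable timestamps in ", path)
  x$wear <- as.integer(x$wear)
  x
}
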