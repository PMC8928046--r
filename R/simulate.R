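# Synthetic minute-level two-arm trial generator.
#
# The generator draws, for every participant-week, a vector of the six
# dimension values from the configured arm/week means and between-person
# SDs, then deterministically encodes those values into a 7 x 1440-minute
# schedule: a sleep block at 0.9 METs outside the waking window, sedentary
# and light runs, scattered 1-9 minute moderate runs, and >=10-minute
# moderate/vigorous bouts whose totals reproduce the drawn values exactly
# (up to the 1-minute grid). Within-class MET levels are solved so the
# day's total energy expenditure matches the drawn PAL. Wear gaps are
# punched out of sedentary runs so that the values recovered by the
# processing pipeline after resting-rate imputation equal the programmed
# ones.

# ---- small numeric helpers ------------------------------------------------

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# integer split of `total` proportional to non-negative weights
# (largest-remainder rounding; exact total)
spread_total <- function(total, weights) {
  k <- length(weights)
  weights <- pmax(weights, 0)
  if (sum(weights) <= 0) weights <- rep(1, k)
  x <- total * weights / sum(weights)
  fl <- floor(x)
  rem <- as.integer(round(total - sum(fl)))
  out <- as.integer(fl)
  if (rem > 0L) {
    top <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    out[top] <- out[top] + 1L
  }
  out
}

# mean-zero multiplicative day-to-day deviations
centered_noise <- function(n, cv) {
  if (cv <= 0) {
    return(rep(0, n))
  }
  e <- stats::rnorm(n, 0, cv)
  e - mean(e)
}

# partition `total` bouted minutes into bout lengths drawn from a truncated
# geometric distribution on {10, ..., 60}; totals are preserved exactly and
# totals below 10 yield no bout
partition_bouts <- function(total, len_mean = 18) {
  total <- as.integer(total)
  if (total < 10L) {
    return(integer(0))
  }
  p <- 1 / max(len_mean - 9, 1)
  lens <- integer(0)
  while (sum(lens) < total) {
    draw <- pmin(10L + stats::rgeom(8L, p), 60L)
    lens <- c(lens, draw)
  }
  k <- which(cumsum(lens) >= total)[1L]
  lens <- lens[seq_len(k)]
  lens[k] <- lens[k] - (sum(lens) - total)
  if (lens[k] < 10L && k > 1L) {
    lens[k - 1L] <- lens[k - 1L] + lens[k]
    lens <- lens[-k]
  }
  lens
}

# split `total` scattered minutes into runs of 1..max_len minutes
split_runs <- function(total, max_len = 9) {
  total <- as.integer(total)
  if (total <= 0L) {
    return(integer(0))
  }
  lens <- integer(0)
  while (sum(lens) < total) {
    lens <- c(lens, sample.int(max_len, 8L, replace = TRUE))
  }
  k <- which(cumsum(lens) >= total)[1L]
  lens <- lens[seq_len(k)]
  lens[k] <- lens[k] - (sum(lens) - total)
  lens[lens > 0L]
}

# ---- one simulated day ----------------------------------------------------

# within-class MET level bounds used when solving for the day's PAL
met_level_base <- c(1.35, 2.35, 4.00, 6.50)
met_level_lo <- c(1.00, 1.82, 3.05, 6.05)
met_level_hi <- c(1.75, 2.95, 5.85, 8.50)

# Build one waking-window class sequence (codes 1 sedentary, 2 light,
# 3 moderate, 4 vigorous) and a wear mask of the same length.
assemble_waking_day <- function(item_len, item_code, s_day, gap_lens,
                                window_len) {
  k <- length(item_len)
  nonact <- window_len - sum(item_len)
  stopifnot(nonact >= k + 1L || k == 0L)

  if (k == 0L) {
    gap_sizes <- nonact
  } else {
    gap_sizes <- 1L + tabulate(
      sample.int(k + 1L, nonact - (k + 1L), replace = TRUE), k + 1L
    )
  }
  # allocate sedentary minutes to inter-item slots (greedy in random order,
  # which yields long contiguous sedentary blocks)
  sed_in <- integer(k + 1L)
  remaining <- s_day
  for (g in sample.int(k + 1L)) {
    take <- min(remaining, gap_sizes[g])
    sed_in[g] <- take
    remaining <- remaining - take
  }

  run_len <- integer(0)
  run_code <- integer(0)
  for (g in seq_len(k + 1L)) {
    sed <- sed_in[g]
    lig <- gap_sizes[g] - sed
    pair_len <- c(sed, lig)
    pair_code <- c(1L, 2L)
    if (stats::runif(1) < 0.5) {
      pair_len <- rev(pair_len)
      pair_code <- rev(pair_code)
    }
    keep <- pair_len > 0L
    run_len <- c(run_len, pair_len[keep])
    run_code <- c(run_code, pair_code[keep])
    if (g <= k) {
      run_len <- c(run_len, item_len[g])
      run_code <- c(run_code, item_code[g])
    }
  }
  class_seq <- rep(run_code, run_len)

  # wear gaps live inside sedentary runs so that resting-rate imputation
  # restores the programmed dimension values exactly
  wear <- rep(TRUE, window_len)
  if (length(gap_lens) > 0L && s_day > 0L) {
    ends <- cumsum(run_len)
    sed_start <- (ends - run_len + 1L)[run_code == 1L]
    sed_len <- run_len[run_code == 1L]
    for (gl in sort(as.integer(gap_lens), decreasing = TRUE)) {
      if (length(sed_len) == 0L) break
      gl <- min(gl, max(sed_len))
      if (gl < 1L) break
      el <- which(sed_len >= gl)
      pick <- el[sample.int(length(el), 1L)]
      off <- sample.int(sed_len[pick] - gl + 1L, 1L) - 1L
      a <- sed_start[pick] + off
      wear[a:(a + gl - 1L)] <- FALSE
      new_start <- c(sed_start[-pick], sed_start[pick], a + gl)
      new_len <- c(sed_len[-pick], off, sed_len[pick] - off - gl)
      keep <- new_len > 0L
      sed_start <- new_start[keep]
      sed_len <- new_len[keep]
    }
  }
  list(class_seq = class_seq, wear = wear)
}

# Solve within-class MET levels so the day's MET-minute total matches the
# drawn PAL, then expand to full 1440-minute raw vectors.
build_raw_day <- function(class_seq, wear, pal_day, steps_day, rmr_kcal_day,
                          waking) {
  window_len <- waking$length
  sleep_len <- 1440L - window_len
  n_gap <- sum(!wear)
  counts <- vapply(1:4, function(code) sum(class_seq == code & wear), 0)

  target <- pal_day * 1440
  fixed <- 0.9 * sleep_len + 1.0 * n_gap
  base_total <- fixed + sum(counts * met_level_base)
  d <- target - base_total
  if (d >= 0) {
    head_room <- sum(counts * (met_level_hi - met_level_base))
    phi <- if (head_room > 0) min(1, d / head_room) else 0
    levels <- met_level_base + phi * (met_level_hi - met_level_base)
  } else {
    head_room <- sum(counts * (met_level_base - met_level_lo))
    phi <- if (head_room > 0) min(1, -d / head_room) else 0
    levels <- met_level_base - phi * (met_level_base - met_level_lo)
  }

  mets_w <- levels[class_seq]
  mets_w[!wear] <- 0

  steps_w <- integer(window_len)
  active <- which(class_seq >= 2L & wear)
  if (length(active) > 0L && steps_day > 0L) {
    cadence <- c(0, 75, 105, 130)[class_seq[active]] *
      stats::runif(length(active), 0.8, 1.2)
    steps_w[active] <- spread_total(steps_day, cadence)
  }

  mets <- rep(0.9, 1440L)
  kcal <- rep(0.9 * rmr_kcal_day / 1440, 1440L)
  steps <- integer(1440L)
  wear_full <- rep(TRUE, 1440L)
  idx <- which(waking$mask)
  mets[idx] <- mets_w
  kcal[idx] <- mets_w * rmr_kcal_day / 1440
  steps[idx] <- steps_w
  wear_full[idx] <- wear
  list(mets = mets, kcal = kcal, steps = steps, wear = wear_full)
}

# ---- dimension draws ------------------------------------------------------

# One participant-week draw of the six dimensions. Daily moderate minutes
# and weekly bouted MVPA are drawn jointly (correlation `cor`) because
# bouted minutes are a subset of all >=3-MET minutes; draws are clamped to
# the feasible region.
draw_week_dimensions <- function(mean, sd, cor) {
  pal <- clamp(stats::rnorm(1, mean[["pal"]], sd[["pal"]]), 0.9, 2.6)
  sed <- clamp(
    stats::rnorm(1, mean[["sedentary_pct"]], sd[["sedentary_pct"]]), 0, 100
  )
  z1 <- stats::rnorm(1)
  z2 <- stats::rnorm(1)
  mod <- max(mean[["moderate_min_day"]] + sd[["moderate_min_day"]] * z1, 0)
  mvpa <- mean[["mvpa_bout_min_week"]] +
    sd[["mvpa_bout_min_week"]] * (cor * z1 + sqrt(1 - cor^2) * z2)
  mvpa <- clamp(mvpa, 0, 7 * mod)
  # vigorous bouts have CV > 1 in calibrated use; a gamma draw matches the
  # configured mean/SD exactly on [0, Inf) where a truncated normal cannot
  vm <- mean[["vigorous_bout_min_week"]]
  vs <- sd[["vigorous_bout_min_week"]]
  vig <- if (vs <= 0 || vm <= 0) {
    vm
  } else {
    stats::rgamma(1, shape = (vm / vs)^2, rate = vm / vs^2)
  }
  vig <- min(vig, mvpa)
  steps <- max(stats::rnorm(1, mean[["steps_day"]], sd[["steps_day"]]), 0)
  c(
    pal = pal, sedentary_pct = sed, moderate_min_day = mod,
    vigorous_bout_min_week = vig, mvpa_bout_min_week = mvpa,
    steps_day = steps
  )
}

# ---- one participant-week -------------------------------------------------

#' Simulate one participant-week of raw minute records
#'
#' Draws the week's six dimension values from the supplied arm/week
#' parameters and encodes them into 7 days of 1-minute epochs with a sleep
#' block at 0.9 METs, sedentary/light/moderate/vigorous runs, steps only in
#' non-sedentary minutes, `kcal = METs x rmr/1440`, and wear gaps punched
#' out of sedentary time. With all SDs at zero and no wear gaps, the
#' dimension values recovered by the processing pipeline equal the
#' configured means exactly (up to the 1-minute grid).
#'
#' @param params Arm/week parameters as returned by [arm_week_params()]: a
#'   list with named `mean` and `sd` vectors over the six dimensions plus
#'   the generator settings (`day_cv`, `mvpa_moderate_cor`, `gaps_per_day`,
#'   `gap_mean_min`, `bout_len_mean`, `waking`, `start_date`).
#' @param attrs Participant attributes: list with `participant`,
#'   `rmr_kcal_day` and optionally `label`.
#' @param seed Optional integer seed for reproducibility of this week.
#' @return Object of class `raw_week`: participant/label metadata and a
#'   list of 7 raw days, each with 1440-long `mets`, `kcal`, `steps`,
#'   `wear` vectors (non-wear minutes carry zeros).
#' @export
simulate_participant_week <- function(params, attrs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  waking <- params$waking
  window_len <- waking$length
  mean <- params$mean
  sd <- params$sd

  budget <- window_len * mean[["sedentary_pct"]] / 100 +
    mean[["moderate_min_day"]]
  if (budget > window_len) {
    stop(
      "infeasible day budget: mean sedentary + active waking minutes (",
      round(budget), ") exceed the waking window (", window_len, " min)"
    )
  }

  dims <- draw_week_dimensions(mean, sd, params$mvpa_moderate_cor)

  vig_bouts <- partition_bouts(
    round(dims[["vigorous_bout_min_week"]]), params$bout_len_mean
  )
  mod_bout_total <- round(dims[["mvpa_bout_min_week"]]) - sum(vig_bouts)
  mod_bouts <- partition_bouts(mod_bout_total, params$bout_len_mean)
  bout_len <- c(vig_bouts, mod_bouts)
  bout_code <- c(rep(4L, length(vig_bouts)), rep(3L, length(mod_bouts)))
  bout_day <- if (length(bout_len) > 0L) {
    sample.int(7L, length(bout_len), replace = TRUE)
  } else {
    integer(0)
  }
  bouts_d <- vapply(
    1:7, function(d) sum(bout_len[bout_day == d]), numeric(1)
  )

  scattered_week <- max(
    0L, as.integer(round(7 * dims[["moderate_min_day"]]) - sum(bout_len))
  )
  eps_m <- centered_noise(7, params$day_cv[["moderate_min_day"]])
  scattered_d <- spread_total(
    scattered_week,
    pmax(dims[["moderate_min_day"]] * (1 + eps_m) - bouts_d, 0)
  )

  eps_s <- centered_noise(7, params$day_cv[["sedentary_pct"]])
  s_week <- round(7 * window_len * dims[["sedentary_pct"]] / 100)
  s_day <- spread_total(s_week, 1 + eps_s)

  pal_d <- dims[["pal"]] * (1 + centered_noise(7, params$day_cv[["pal"]]))
  steps_d <- spread_total(
    round(7 * dims[["steps_day"]]),
    1 + centered_noise(7, params$day_cv[["steps_day"]])
  )

  days <- vector("list", 7L)
  for (d in 1:7) {
    runs <- split_runs(scattered_d[d])
    item_len <- c(bout_len[bout_day == d], runs)
    item_code <- c(bout_code[bout_day == d], rep(3L, length(runs)))
    if (length(item_len) > 1L) {
      ord <- sample.int(length(item_len))
      item_len <- item_len[ord]
      item_code <- item_code[ord]
    }
    k <- length(item_len)
    s_max <- window_len - sum(item_len) - if (k > 0L) k + 1L else 0L
    s_d <- clamp(s_day[d], 0L, max(s_max, 0L))

    n_g <- stats::rpois(1L, params$gaps_per_day)
    gap_lens <- if (n_g > 0L) {
      pmin(1L + stats::rgeom(n_g, 1 / max(params$gap_mean_min, 1)), 180L)
    } else {
      integer(0)
    }

    wk <- assemble_waking_day(item_len, item_code, s_d, gap_lens, window_len)
    days[[d]] <- build_raw_day(
      wk$class_seq, wk$wear, pal_d[d], steps_d[d],
      attrs$rmr_kcal_day, waking
    )
  }

  structure(
    list(
      participant = attrs$participant,
      label = if (is.null(attrs$label)) "" else attrs$label,
      start_date = params$start_date,
      rmr_kcal_day = attrs$rmr_kcal_day,
      waking = waking,
      dims_drawn = dims,
      days = days
    ),
    class = "raw_week"
  )
}

#' @export
print.raw_week <- function(x, ...) {
  cat(sprintf(
    "<raw_week> %s [%s] starting %s | %d non-wear min\n",
    x$participant, x$label, format(x$start_date),
    sum(!vapply(x$days, function(d) d$wear, logical(1440)))
  ))
  invisible(x)
}

#' Flatten a raw simulated week to minute records
#'
#' @param raw A [simulate_participant_week()] result.
#' @return Data frame in the minute CSV dialect: `timestamp`, `mets`,
#'   `kcal`, `steps`, `wear` (0/1), 10080 rows.
#' @export
raw_week_records <- function(raw) {
  stopifnot(inherits(raw, "raw_week"))
  origin <- as.POSIXct(paste(raw$start_date, "00:00:00"), tz = "UTC")
  out <- do.call(rbind, lapply(1:7, function(d) {
    day <- raw$days[[d]]
    data.frame(
      timestamp = origin + ((d - 1L) * 1440L + 0:1439) * 60,
      mets = day$mets, kcal = day$kcal, steps = day$steps,
      wear = as.integer(day$wear)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Process a raw simulated week into a validated participant week
#'
#' Applies the resting-rate imputation and wear validity rules to a
#' simulated raw week; equivalent to round-tripping the raw records through
#' [impute_nonwear()] and [validate_week()].
#'
#' @param raw A [simulate_participant_week()] result.
#' @return A [validate_week()] `participant_week`.
#' @export
process_raw_week <- function(raw) {
  stopifnot(inherits(raw, "raw_week"))
  days <- lapply(1:7, function(d) {
    day <- raw$days[[d]]
    impute_day_vectors(
      raw$start_date + (d - 1L), day$mets, day$kcal, day$steps, day$wear,
      raw$rmr_kcal_day, raw$waking
    )
  })
  validate_week(days, raw$rmr_kcal_day, raw$participant, raw$label)
}
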