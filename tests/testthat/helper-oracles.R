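# Test fixtures and independent oracles, built in code.

# Build a fully worn participant week from a 7 x 1440 METs matrix;
# kcal follows the MET-scaling rule, steps optional.
week_from_mets <- function(mets, rmr = 1600, steps = NULL,
                           waking = waking_window(),
                           participant = "T1", label = "baseline") {
  stopifnot(is.matrix(mets), nrow(mets) == 7L, ncol(mets) == 1440L)
  if (is.null(steps)) steps <- matrix(0L, 7L, 1440L)
  days <- lapply(1:7, function(d) {
    impute_nonwear(
      data.frame(
        minute = 0:1439, mets = mets[d, ], kcal = mets[d, ] * rmr / 1440,
        steps = steps[d, ], wear = 1L
      ),
      rmr_kcal_day = rmr, date = as.Date("2026-01-05") + d - 1L,
      waking = waking
    )
  })
  validate_week(days, rmr, participant, label)
}

# A constant-MET waking day with resting sleep, as a 1440 vector.
day_mets <- function(waking_value = 1.0, waking = waking_window()) {
  x <- rep(0.9, 1440)
  x[waking$mask] <- waking_value
  x
}

# Brute-force bout oracle: minute-by-minute scan for maximal runs of
# qualifying minutes (independent of the rle-based implementation).
brute_bout_minutes <- function(mets, threshold, min_bout_len = 10) {
  total <- 0L
  run <- 0L
  for (m in mets) {
    if (m >= threshold) {
      run <- run + 1L
    } else {
      if (run >= min_bout_len) total <- total + run
      run <- 0L
    }
  }
  if (run >= min_bout_len) total <- total + run
  total
}

# Exhaustive BCa oracle for the mean of a sample of size n (enumerates all
# n^n ordered resamples). Written independently of the package machinery.
exhaustive_bca_mean <- function(x, level = 0.95) {
  n <- length(x)
  grid <- do.call(expand.grid, rep(list(seq_len(n)), n))
  t_star <- apply(grid, 1L, function(idx) mean(x[idx]))
  t0 <- mean(x)
  z0 <- qnorm(mean(t_star < t0))
  theta <- vapply(seq_len(n), function(i) mean(x[-i]), numeric(1))
  dev <- mean(theta) - theta
  a <- sum(dev^3) / (6 * sum(dev^2)^1.5)
  alpha <- (1 - level) / 2
  zq <- qnorm(c(alpha, 1 - alpha))
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  list(
    ci = quantile(t_star, adj, names = FALSE, type = 7),
    z0 = z0, a = a, t_star = t_star
  )
}

# Small generator parameter set with optional overrides (fast fixtures).
test_params <- function(mean = NULL, sd = 0, gaps_per_day = 0,
                        day_cv = 0) {
  base_mean <- c(
    pal = 1.6, sedentary_pct = 68.75, moderate_min_day = 120,
    vigorous_bout_min_week = 30, mvpa_bout_min_week = 450,
    steps_day = 7500
  )
  if (!is.null(mean)) base_mean[names(mean)] <- mean
  dims <- names(base_mean)
  list(
    mean = base_mean,
    sd = stats::setNames(rep(sd, 6), dims)[dims],
    day_cv = c(
      pal = day_cv, sedentary_pct = day_cv,
      moderate_min_day = day_cv, steps_day = day_cv
    ),
    mvpa_moderate_cor = 0.8, gaps_per_day = gaps_per_day,
    gap_mean_min = 15, bout_len_mean = 18, waking = waking_window(),
    start_date = as.Date("2026-01-05")
  )
}

test_attrs <- function(rmr = 1600) {
  list(participant = "T1", rmr_kcal_day = rmr, label = "baseline")
}

# A small, fast trial configuration (identical structure, fewer people).
small_sim_config <- function(seed = 1L, n_intervention = 6L, n_control = 4L,
                             ...) {
  default_sim_config(
    seed = seed, n_intervention = n_intervention,
    n_control = n_control, ...
  )
}

# Long outcome table drawn directly at the dimension level (fast stats
# fixtures): one row per participant and week.
toy_outcome_table <- function(n1 = 20, n2 = 10, delta = 0, seed = 1,
                              sd = 1, weeks = c("baseline", "week12")) {
  set.seed(seed)
  n <- n1 + n2
  arm <- rep(c("intervention", "control"), c(n1, n2))
  rows <- lapply(weeks, function(w) {
    eff <- if (w == "baseline") 0 else delta
    data.frame(
      participant = sprintf("P%02d", seq_len(n)), arm = arm,
      sex = rep(c("female", "male"), length.out = n),
      weight_status = rep(c(0L, 1L), length.out = n), week = w,
      pal = rnorm(n, 1.6, 0.2 * sd) + eff * (arm == "intervention"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
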