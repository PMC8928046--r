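test_that("CI-to-SD calibration follows the normal approximation", {
  s <- data.frame(
    dimension = "pal", arm = c("intervention", "control"),
    week = "baseline", mean = c(1.61, 1.58),
    ci_low = c(1.55, 1.52), ci_high = c(1.66, 1.64)
  )
  out <- calibrate_from_summary(s, c(intervention = 36, control = 15))
  # (0.11 / 3.92) * 6 and (0.12 / 3.92) * sqrt(15), via qnorm(0.975)
  expect_equal(out$sd[1], (1.66 - 1.55) / (2 * qnorm(.975)) * 6,
    tolerance = 1e-12
  )
  expect_equal(out$sd[1], 0.168, tolerance = 0.005)
  expect_equal(out$sd[2], 0.119, tolerance = 0.005)
  expect_equal(out$mean, s$mean)

  s$ci_low <- s$mean
  s$ci_high <- s$mean
  out0 <- calibrate_from_summary(s, c(intervention = 36, control = 15))
  expect_equal(out0$sd, c(0, 0))

  s$ci_low <- s$mean + 1
  expect_error(
    calibrate_from_summary(s, c(intervention = 36, control = 15)),
    "ci_high < ci_low"
  )
})

test_that("zero-variance parameters are recovered exactly by the pipeline", {
  params <- test_params()
  raw <- simulate_participant_week(params, test_attrs(), seed = 21)
  prof <- multidimensional_profile(process_raw_week(raw))
  expect_equal(prof$pal, 1.6, tolerance = 1e-9)
  expect_equal(prof$sedentary_pct, 68.75)
  expect_equal(prof$moderate_min_day, 120)
  expect_equal(prof$vigorous_bout_min_week, 30)
  expect_equal(prof$mvpa_bout_min_week, 450)
  expect_equal(prof$steps_day, 7500)
})

test_that("wear gaps are imputed away without disturbing the dimensions", {
  params <- test_params(gaps_per_day = 3)
  raw <- simulate_participant_week(params, test_attrs(), seed = 22)
  pw <- process_raw_week(raw)
  expect_gt(sum(pw$imputed), 0)
  expect_true(pw$valid)
  prof <- multidimensional_profile(pw)
  expect_equal(prof$pal, 1.6, tolerance = 1e-9)
  expect_equal(prof$sedentary_pct, 68.75)
  expect_equal(prof$moderate_min_day, 120)
  expect_equal(prof$mvpa_bout_min_week, 450)
  expect_equal(prof$steps_day, 7500)
})

test_that("an all-sedentary configuration yields a resting profile", {
  params <- test_params(mean = c(
    pal = (0.9 * 480 + 960) / 1440, sedentary_pct = 100,
    moderate_min_day = 0, vigorous_bout_min_week = 0,
    mvpa_bout_min_week = 0, steps_day = 0
  ))
  raw <- simulate_participant_week(params, test_attrs(), seed = 23)
  prof <- multidimensional_profile(process_raw_week(raw))
  expect_equal(prof$sedentary_pct, 100)
  expect_equal(prof$pal, 1.0, tolerance = 0.05)
  expect_equal(prof$moderate_min_day, 0)
  expect_equal(prof$steps_day, 0)
})

test_that("infeasible day budgets are rejected with a diagnostic", {
  params <- test_params(mean = c(sedentary_pct = 90, moderate_min_day = 200))
  expect_error(
    simulate_participant_week(params, test_attrs(), seed = 1),
    "infeasible day budget"
  )
  bad <- calibrate_from_summary(
    trial_reference_summary(), c(intervention = 36, control = 15)
  )
  bad$mean[bad$dimension == "moderate_min_day"] <- 400
  expect_error(sim_config(bad), "infeasible")
})

test_that("simulated minute records obey the construction contracts", {
  params <- test_params(gaps_per_day = 2)
  params$sd <- c(
    pal = 0.15, sedentary_pct = 8, moderate_min_day = 40,
    vigorous_bout_min_week = 25, mvpa_bout_min_week = 150, steps_day = 1500
  )
  for (seed in 24:28) {
    raw <- simulate_participant_week(params, test_attrs(), seed = seed)
    rec <- raw_week_records(raw)
    expect_equal(nrow(rec), 10080L)
    expect_true(all(diff(as.numeric(rec$timestamp)) == 60))
    # steps only in non-sedentary worn minutes
    stepped <- rec$steps > 0
    expect_true(all(rec$mets[stepped] >= 1.8))
    expect_true(all(rec$wear[stepped] == 1L))
    # kcal follows the MET scaling rule on worn minutes
    worn <- rec$wear == 1L
    expect_equal(rec$kcal[worn], rec$mets[worn] * 1600 / 1440,
      tolerance = 1e-9
    )
    # sleep minutes sit at 0.9 METs
    w <- waking_window()
    sleep_rows <- rep(!w$mask, 7)
    expect_true(all(rec$mets[sleep_rows & worn] == 0.9))
  }
})

test_that("trial simulation is reproducible and respects the allocation", {
  cfg <- small_sim_config(seed = 101)
  t1 <- simulate_trial(cfg)
  t2 <- simulate_trial(cfg)
  expect_identical(t1, t2)
  expect_equal(nrow(t1$participants), 10L)
  expect_equal(sum(t1$participants$arm == "intervention"), 6L)
  expect_equal(
    t1$participants$weight_status,
    as.integer(t1$participants$bmi >= 30)
  )
  # one raw week per participant and assessment
  expect_setequal(
    names(t1$weeks),
    as.vector(outer(t1$participants$participant, cfg$weeks, paste, sep = "."))
  )

  cfg2 <- small_sim_config(seed = 102)
  expect_false(identical(simulate_trial(cfg2), t1))

  full <- default_sim_config(seed = 5)
  expect_equal(full$n_intervention + full$n_control, 51L)
})

test_that("pipeline-recovered means match the generator's draw distribution", {
  # intervention week-12 parameters; the oracle for the pipeline mean is
  # the mean of the (clamped) dimension-draw distribution, estimated at the
  # draw level, and the minute encoding must add no bias beyond it
  cfg <- default_sim_config()
  params <- arm_week_params(cfg, "intervention", "week12")
  set.seed(300)
  draw_oracle <- replicate(
    4000,
    draw_week_dimensions(params$mean, params$sd, params$mvpa_moderate_cor)
  )
  set.seed(301)
  n_rep <- 500
  seeds <- sample.int(2^30, n_rep)
  attrs <- test_attrs()
  rec <- sapply(seq_len(n_rep), function(r) {
    raw <- simulate_participant_week(params, attrs, seed = seeds[r])
    unlist(multidimensional_profile(process_raw_week(raw))[dimension_names()])
  })
  for (dm in dimension_names()) {
    se <- sqrt(
      var(rec[dm, ]) / n_rep + var(draw_oracle[dm, ]) / ncol(draw_oracle)
    )
    expect_lt(
      abs(mean(rec[dm, ]) - mean(draw_oracle[dm, ])),
      3.5 * se + 0.15 # 1-minute-grid quantization allowance
    )
  }
})

test_that("dimension-level and minute-level generators agree in structure", {
  cfg <- small_sim_config(seed = 400)
  tab <- simulate_profile_table(cfg)
  expect_equal(nrow(tab), 10L * 3L)
  expect_setequal(
    names(tab),
    c(
      "participant", "arm", "sex", "weight_status", "week",
      dimension_names()
    )
  )
  expect_true(all(tab$mvpa_bout_min_week >= tab$vigorous_bout_min_week))
  expect_true(all(7 * tab$moderate_min_day >= tab$mvpa_bout_min_week))
  expect_identical(tab, {
    simulate_profile_table(cfg)
  })
})
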