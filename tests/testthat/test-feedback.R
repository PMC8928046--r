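profile_fixture <- function(pal = 1.6, sed = 60, mod = 130, vig = 80,
                            mvpa = 160, steps = 8000, rmr = 1600) {
  structure(
    list(
      pal = pal, sedentary_pct = sed, moderate_min_day = mod,
      vigorous_bout_min_week = vig, mvpa_bout_min_week = mvpa,
      steps_day = steps
    ),
    class = "dimension_profile",
    tee_kcal_day = pal * rmr, rmr_kcal_day = rmr,
    participant = "T1", label = "baseline"
  )
}

test_that("traffic lights follow the amber-band rule in both directions", {
  tg <- health_targets(1600)
  # exactly on target -> green (calorie target 1.6 * 1600 = 2560 = tee)
  rep <- evaluate_targets(profile_fixture(pal = 1.6), tg)
  expect_equal(rep$status[rep$dimension == "calorie_burn"], "green")

  # at-least: 140 vs 150 with 10% band -> amber (140 >= 135)
  rep <- evaluate_targets(profile_fixture(mvpa = 140), tg)
  expect_equal(rep$status[rep$dimension == "mvpa_bouts"], "amber")
  rep <- evaluate_targets(profile_fixture(mvpa = 134), tg)
  expect_equal(rep$status[rep$dimension == "mvpa_bouts"], "red")

  # at-most sedentary: 80% vs 65% -> red (80 > 71.5)
  rep <- evaluate_targets(profile_fixture(sed = 80), tg)
  expect_equal(rep$status[rep$dimension == "sedentary"], "red")
  rep <- evaluate_targets(profile_fixture(sed = 70), tg)
  expect_equal(rep$status[rep$dimension == "sedentary"], "amber")
  rep <- evaluate_targets(profile_fixture(sed = 65), tg)
  expect_equal(rep$status[rep$dimension == "sedentary"], "green")
})

test_that("statuses are monotone in the attained value", {
  tg <- health_targets(1600)
  rank <- c(red = 1, amber = 2, green = 3)
  vals <- seq(50, 250, by = 5)
  st <- vapply(vals, function(v) {
    r <- evaluate_targets(profile_fixture(mvpa = v), tg)
    r$status[r$dimension == "mvpa_bouts"]
  }, character(1))
  expect_true(all(diff(rank[st]) >= 0))
  st_sed <- vapply(vals / 2.5, function(v) {
    r <- evaluate_targets(profile_fixture(sed = v), tg)
    r$status[r$dimension == "sedentary"]
  }, character(1))
  expect_true(all(diff(rank[st_sed]) <= 0))
})

test_that("target-set validation rejects impossible settings", {
  expect_error(health_targets(1600, moderate_target = 0), "positive")
  expect_error(health_targets(1600, sedentary_target = 120), "0, 100")
  expect_error(health_targets(1600, amber_band = 1), "amber_band")
})

test_that("activity energy cost scales the personal resting rate", {
  expect_equal(as.numeric(activity_energy_cost(4, 60, 1440)), 240)
  expect_equal(attr(activity_energy_cost(4, 60, 1440), "intensity"), "moderate")
  # 1 MET is the resting cost for any duration
  expect_equal(as.numeric(activity_energy_cost(1, 37, 1600)), 37 * 1600 / 1440)
  expect_equal(as.numeric(activity_energy_cost(6, 30, 1600)), 200)
  expect_equal(attr(activity_energy_cost(6, 30, 1600), "intensity"), "vigorous")
  expect_error(activity_energy_cost(0, 30, 1600), "positive")
  expect_error(activity_energy_cost(4, -1, 1600), "positive")
})

segment_week <- function() {
  w <- waking_window()
  m <- day_mets(1.0)
  m[which(w$mask)[101:130]] <- 4.0
  week_from_mets(matrix(m, 7, 1440, byrow = TRUE), rmr = 1440)
}

test_that("tagged segments summarize and partition the day", {
  wk <- segment_week()
  whole <- tag_segment(wk, 1, 0, 1440)
  expect_equal(whole$kcal, sum(wk$kcal[1, ]))
  expect_equal(sum(whole$minutes), 1440)

  # the 30 minutes at 4 METs with rmr 1440: 4 kcal/min
  w <- waking_window()
  s0 <- w$start_min + 100L
  seg <- tag_segment(wk, 1, s0, s0 + 30L)
  expect_equal(seg$kcal, 120)
  expect_equal(seg$mean_mets, 4)
  expect_equal(unname(seg$minutes["moderate"]), 30)

  # additivity over a partition of the day
  cuts <- c(0, 300, 700, 1100, 1440)
  parts <- lapply(1:4, function(i) tag_segment(wk, 3, cuts[i], cuts[i + 1]))
  expect_equal(sum(vapply(parts, `[[`, 1, "kcal")), sum(wk$kcal[3, ]))
  expect_equal(
    Reduce(`+`, lapply(parts, `[[`, "minutes")),
    tag_segment(wk, 3, 0, 1440)$minutes
  )

  expect_error(tag_segment(wk, 1, 100, 100), "start_minute < end_minute")
  expect_error(tag_segment(wk, 1, 1400, 1441), "end_minute <= 1440")
  expect_error(tag_segment(wk, 8, 0, 10), "1..7")
})

test_that("superimposing plans raises the affected dimensions as expected", {
  wk <- week_from_mets(matrix(day_mets(1.0), 7, 1440, byrow = TRUE))
  base <- multidimensional_profile(wk)
  tg <- health_targets(wk$rmr_kcal_day)

  res <- plan_superimpose(
    wk, planned_activity("walk", 4.0, "10:00", 30, days = 1:7), tg
  )
  expect_equal(res$profile$moderate_min_day, base$moderate_min_day + 30)
  expect_equal(res$profile$mvpa_bout_min_week, base$mvpa_bout_min_week + 210)
  expect_gte(res$profile$pal, base$pal)
  expect_gt(res$profile$steps_day, base$steps_day)

  # a single-day vigorous plan of bout length counts fully
  res_v <- plan_superimpose(
    wk, planned_activity("run", 6.1, "18:00", 25, days = 3), tg
  )
  expect_equal(
    res_v$profile$vigorous_bout_min_week,
    base$vigorous_bout_min_week + 25
  )

  # the original week is untouched
  expect_equal(multidimensional_profile(wk)$moderate_min_day,
    base$moderate_min_day)
})

test_that("superimposing the underlying behaviour changes nothing", {
  wk <- week_from_mets(matrix(day_mets(2.0), 7, 1440, byrow = TRUE))
  base <- multidimensional_profile(wk)
  res <- plan_superimpose(
    wk, planned_activity("same", 2.0, "09:00", 60, days = 1:7)
  )
  expect_equal(res$profile$pal, base$pal, tolerance = 1e-3)
  expect_equal(res$profile$moderate_min_day, base$moderate_min_day)
  expect_equal(res$profile$sedentary_pct, base$sedentary_pct)
})

test_that("overlapping plans are rejected and plans validate", {
  wk <- week_from_mets(matrix(day_mets(1.0), 7, 1440, byrow = TRUE))
  p1 <- planned_activity("a", 4, "10:00", 30, days = 2)
  p2 <- planned_activity("b", 5, "10:15", 30, days = 2)
  expect_error(plan_superimpose(wk, list(p1, p2)), "overlap")
  # same times on different days are fine
  p3 <- planned_activity("c", 5, "10:15", 30, days = 3)
  expect_silent(plan_superimpose(wk, list(p1, p3)))
  expect_error(planned_activity("x", 0, "10:00", 30), "positive")
  expect_error(planned_activity("x", 4, "10:00", 0), "at least 1")
  expect_error(planned_activity("x", 4, "23:50", 20), "midnight")
})

test_that("the bundled compendium is consistent", {
  cp <- met_compendium()
  expect_true(all(cp$met_value > 0))
  expect_gte(nrow(cp), 20)
  expect_equal(
    as.character(classify_intensity(cp$met_value)) %in%
      c("sedentary", "light", "moderate", "vigorous"),
    rep(TRUE, nrow(cp))
  )
  expect_equal(cp$category, as.character(classify_intensity(cp$met_value)))
})
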