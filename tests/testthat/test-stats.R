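test_that("noise-free additive effects are recovered exactly by ANCOVA", {
  tab <- toy_outcome_table(n1 = 12, n2 = 8, seed = 3)
  base <- tab$pal[tab$week == "baseline"]
  tab$pal[tab$week == "week12"] <-
    base + 0.25 * (tab$arm[tab$week == "week12"] == "intervention")
  fit <- ancova_adjusted_difference(tab, "pal", "week12")
  expect_equal(fit$adjusted_md, 0.25, tolerance = 1e-10)
  expect_equal(fit$n1, 12L)
  expect_equal(fit$n2, 8L)
})

test_that("constant covariates are dropped with a warning", {
  tab <- toy_outcome_table(n1 = 10, n2 = 6, seed = 4)
  tab$weight_status <- 0L
  expect_warning(
    fit <- ancova_adjusted_difference(tab, "pal", "week12"),
    "weight_status"
  )
  expect_true(is.finite(fit$adjusted_md))
})

test_that("degenerate outcome tables are refused", {
  tab <- toy_outcome_table(n1 = 10, n2 = 6, seed = 5)
  expect_error(
    ancova_adjusted_difference(tab[tab$arm == "intervention", ], "pal", "week12"),
    "both arms"
  )
  one <- tab[tab$participant %in% c("P01", "P02", "P11"), ]
  expect_error(ancova_adjusted_difference(one, "pal", "week12"), "at least 2")
})

test_that("the ANCOVA estimator is unbiased under the null", {
  set.seed(11)
  est <- replicate(400, {
    tab <- toy_outcome_table(
      n1 = 36, n2 = 15, delta = 0,
      seed = sample.int(1e8, 1)
    )
    ancova_adjusted_difference(tab, "pal", "week12")$adjusted_md
  })
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(length(est)))
})

test_that("Hedges g applies the closed-form small-sample correction", {
  # J for n = 36/15: 1 - 3/(4*49 - 1) = 1 - 3/195
  tab <- toy_outcome_table(n1 = 36, n2 = 15, seed = 6)
  fu <- tab[tab$week == "week12", ]
  s_pool <- sqrt(
    (35 * var(fu$pal[fu$arm == "intervention"]) +
      14 * var(fu$pal[fu$arm == "control"])) / 49
  )
  g <- hedges_g(tab, 0.09, "pal", "week12")
  expect_equal(g, (1 - 3 / 195) * 0.09 / s_pool, tolerance = 1e-12)
  expect_equal(hedges_g(tab, 0, "pal", "week12"), 0)
  # md 0.09 over pooled SD 0.11 lands in the large-effect range
  expect_equal((1 - 3 / 195) * 0.09 / 0.11, 0.805, tolerance = 0.01)
})

test_that("Hedges g is scale invariant and fails on zero spread", {
  tab <- toy_outcome_table(n1 = 20, n2 = 10, seed = 7)
  g1 <- hedges_g(tab, 0.12, "pal", "week12")
  tab2 <- tab
  tab2$pal <- tab2$pal * 37
  expect_equal(hedges_g(tab2, 0.12 * 37, "pal", "week12"), g1)
  tab3 <- tab
  tab3$pal <- 1.5
  expect_error(hedges_g(tab3, 0.1, "pal", "week12"), "zero")
})

test_that("BCa reduces to the percentile interval for symmetric statistics", {
  set.seed(8)
  x <- rnorm(200)
  stat <- function(d, i) mean(d[i])
  ci <- bca_bootstrap_ci(stat, x, reps = 4000, seed = 9)
  expect_lt(abs(attr(ci, "z0")), 0.08)
  expect_lt(abs(attr(ci, "a")), 0.02)
  set.seed(10)
  idx <- matrix(sample.int(200, 4000 * 200, replace = TRUE), 4000)
  perc <- quantile(apply(idx, 1, function(i) mean(x[i])), c(.025, .975))
  expect_equal(as.numeric(ci), unname(perc), tolerance = 0.02)
})

test_that("BCa is deterministic under a seed and flags degenerate input", {
  x <- rexp(40)
  stat <- function(d, i) mean(d[i])
  ci1 <- bca_bootstrap_ci(stat, x, reps = 500, seed = 12)
  ci2 <- bca_bootstrap_ci(stat, x, reps = 500, seed = 12)
  expect_identical(ci1, ci2)
  expect_warning(
    ci0 <- bca_bootstrap_ci(stat, rep(2, 20), reps = 200, seed = 1),
    "degenerate"
  )
  expect_equal(as.numeric(ci0), c(2, 2))
  expect_error(bca_bootstrap_ci(stat, x, reps = 50), "at least 100")
})

test_that("BCa matches an exhaustive-resample oracle at n = 5", {
  x <- c(1.3, 2.1, 2.4, 4.8, 9.5) # skewed, so z0 and a are non-trivial
  oracle <- exhaustive_bca_mean(x)
  n <- 5L
  grid <- as.matrix(do.call(expand.grid, rep(list(1:n), n)))
  ci <- bca_bootstrap_ci(
    function(d, i) mean(d[i]), x,
    indices = grid
  )
  expect_equal(as.numeric(ci), unname(oracle$ci), tolerance = 1e-10)
  expect_equal(attr(ci, "z0"), oracle$z0, tolerance = 1e-10)
  expect_equal(attr(ci, "a"), oracle$a, tolerance = 1e-10)
  expect_gt(abs(oracle$z0), 1e-4) # the check is not vacuous
})

test_that("BCa agrees with the reference implementation on a fixture", {
  skip_if_not_installed("boot")
  # unstratified skewed sample: both implementations use the plain
  # delete-1 jackknife acceleration here, so they must coincide up to
  # resampling noise
  set.seed(13)
  x <- rgamma(51, 2)
  stat <- function(d, i) mean(d[i])
  b <- boot::boot(x, stat, R = 9999)
  ref <- boot::boot.ci(b, type = "bca")$bca[4:5]
  ci <- bca_bootstrap_ci(stat, x, reps = 9999, seed = 14)
  expect_lt(max(abs(as.numeric(ci) - ref)), 0.03)
})

test_that("adjusted effects combine the ANCOVA, BCa CI and Hedges g", {
  tab <- toy_outcome_table(n1 = 36, n2 = 15, delta = 0.3, seed = 15)
  e <- adjusted_effect(tab, "pal", "week12", reps = 500, seed = 16)
  expect_lte(e$ci_low, e$adjusted_md)
  expect_gte(e$ci_high, e$adjusted_md)
  expect_equal(sign(e$hedges_g), sign(e$adjusted_md))
  expect_equal(e$n1, 36L)
  expect_equal(e$n2, 15L)
  e2 <- adjusted_effect(tab, "pal", "week12", reps = 500, seed = 16)
  expect_identical(e[c("ci_low", "ci_high", "g_ci_low", "g_ci_high")],
    e2[c("ci_low", "ci_high", "g_ci_low", "g_ci_high")])
})

test_that("subgroup descriptives reproduce hand computations", {
  tab <- data.frame(
    participant = rep(c("A", "B", "C", "D"), 2),
    arm = rep(c("intervention", "intervention", "control", "control"), 2),
    sex = rep(c("female", "male", "female", "male"), 2),
    weight_status = 0L,
    week = rep(c("baseline", "week12"), each = 4),
    pal = c(1.5, 1.7, 1.6, 1.8, 1.9, 1.6, 1.4, 1.7)
  )
  d <- subgroup_descriptives(tab, by = "sex", outcomes = "pal")
  cell <- d[d$subgroup == "female" & d$arm == "intervention" &
    d$week == "week12", ]
  expect_equal(cell$mean, 1.9)
  expect_equal(cell$n, 1L)
  expect_true(is.na(cell$sd))

  # single-arm uniform data: subgroup means equal the overall mean
  uni <- tab[tab$arm == "intervention", ]
  uni$pal <- 1.55
  du <- subgroup_descriptives(uni, by = "sex", outcomes = "pal")
  expect_true(all(du$mean[du$n > 0] == 1.55))

  # baseline-activity split: ties at the median go to the low group
  db <- subgroup_descriptives(tab, by = "baseline_activity", outcomes = "pal")
  expect_setequal(unique(db$subgroup), c("low_baseline_pa", "high_baseline_pa"))
  # median baseline pal = 1.65; A (1.5) and C (1.6) are low, B and D high
  low12 <- db[db$subgroup == "low_baseline_pa" & db$week == "week12" &
    db$arm == "control", ]
  expect_equal(low12$mean, 1.4)
})

test_that("a programmed female-only effect shows up in subgroup contrasts", {
  cfg <- default_sim_config(seed = 2026, sex_effect_ratio = 2)
  diffs <- sapply(1:25, function(r) {
    cfg$seed <- cfg$seed + r
    prof <- simulate_profile_table(cfg)
    d <- subgroup_descriptives(prof, by = "sex", outcomes = "pal")
    w12 <- d[d$week == "week12", ]
    get <- function(sg, arm) w12$mean[w12$subgroup == sg & w12$arm == arm]
    c(
      female = get("female", "intervention") - get("female", "control"),
      male = get("male", "intervention") - get("male", "control")
    )
  })
  expect_gt(mean(diffs["female", ]), mean(diffs["male", ]))
})

test_that("the eligibility screen excludes PAL >= 2.0 at baseline", {
  expect_equal(
    eligibility_screen(c(A = 1.99, B = 2.0, C = 1.5))$excluded, "B"
  )
  empty <- eligibility_screen(numeric(0))
  expect_length(empty$included, 0)
  expect_length(empty$excluded, 0)

  set.seed(17)
  pal <- c(runif(52, 1.2, 1.95), c(2.0, 2.1, 2.3, 2.05, 2.6))
  names(pal) <- sprintf("V%02d", 1:57)
  scr <- eligibility_screen(pal)
  expect_length(scr$excluded, 5)
  expect_length(scr$included, 52)
  expect_match(scr$log$reason, "PAL >= 2.0", all = TRUE, fixed = TRUE)
})
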