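# Trial analysis: baseline-adjusted ANCOVA, BCa bootstrap CIs, Hedges g,
# subgroup descriptives and the baseline eligibility screen.

# Build the per-participant analysis frame for one outcome/timepoint from a
# long profile table (participant, arm, sex, weight_status, week, <dims>).
ancova_frame <- function(outcome_table, outcome, timepoint,
                         baseline = "baseline") {
  need <- c("participant", "arm", "week", outcome)
  if (!all(need %in% names(outcome_table))) {
    stop(
      "outcome table must contain columns ",
      paste(need, collapse = ", ")
    )
  }
  fu <- outcome_table[outcome_table$week == timepoint, ]
  bl <- outcome_table[outcome_table$week == baseline, ]
  d <- merge(
    fu[, c("participant", "arm", "sex", "weight_status", outcome)],
    stats::setNames(
      bl[, c("participant", outcome)], c("participant", ".baseline")
    ),
    by = "participant"
  )
  d <- d[stats::complete.cases(d), ]
  d$arm <- factor(d$arm, levels = c("control", "intervention"))
  d$.y <- d[[outcome]]
  if (any(is.na(d$arm))) stop("unknown arm labels in outcome table")
  if (nlevels(droplevels(d$arm)) < 2L) {
    stop("both arms are required for an adjusted difference")
  }
  if (min(table(d$arm)) < 2L) {
    stop("at least 2 participants per arm with complete data are required")
  }
  d
}

# Design matrix with non-informative (constant) covariates dropped.
ancova_design <- function(d, warn = TRUE) {
  covs <- c(".baseline", "sex", "weight_status")
  keep <- covs[vapply(covs, function(v) length(unique(d[[v]])) > 1L, TRUE)]
  if (warn && length(keep) < length(covs)) {
    warning(
      "dropping constant covariate(s): ",
      paste(setdiff(covs, keep), collapse = ", ")
    )
  }
  f <- stats::reformulate(c("arm", keep), response = ".y")
  list(formula = f, x = stats::model.matrix(f[-2L], d), keep = keep)
}

# Fast group-coefficient evaluation on a row subset (bootstrap/jackknife
# workhorse). Falls back to a pivot-safe fit when a covariate collapses in
# the resample.
arm_coef <- function(x, y, idx) {
  xi <- x[idx, , drop = FALSE]
  fit <- stats::.lm.fit(xi, y[idx])
  if (fit$rank == ncol(xi)) {
    return(fit$coefficients[[2L]])
  }
  stats::lm.fit(xi, y[idx])$coefficients[["armintervention"]]
}

#' Baseline-adjusted mean difference between trial arms (ANCOVA)
#'
#' Fits the linear model `follow-up ~ arm + baseline + sex + weight_status`
#' and reports the arm coefficient (intervention minus control), i.e. the
#' mean difference adjusted for the baseline value of the outcome and the
#' stratified randomization factors. Covariates that are constant in the
#' data are dropped with a warning.
#'
#' @param outcome_table Long per-participant-week outcome table as produced
#'   by [profile_table()] (columns `participant`, `arm`, `sex`,
#'   `weight_status`, `week`, and one column per outcome).
#' @param outcome Name of the outcome column.
#' @param timepoint Follow-up assessment label (e.g. `"week12"`).
#' @param baseline Baseline assessment label.
#' @return List of class `ancova_fit`: `adjusted_md`, arm sizes `n1`
#'   (intervention) and `n2` (control), the fitted `model`, and the
#'   analysis `data`.
#' @export
ancova_adjusted_difference <- function(outcome_table, outcome, timepoint,
                                       baseline = "baseline") {
  d <- ancova_frame(outcome_table, outcome, timepoint, baseline)
  des <- ancova_design(d)
  model <- stats::lm(des$formula, data = d)
  structure(
    list(
      outcome = outcome, timepoint = timepoint,
      adjusted_md = unname(stats::coef(model)[["armintervention"]]),
      n1 = sum(d$arm == "intervention"), n2 = sum(d$arm == "control"),
      model = model, data = d
    ),
    class = "ancova_fit"
  )
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf(
    "<ancova_fit> %s at %s: adjusted difference %.4g (n = %d/%d)\n",
    x$outcome, x$timepoint, x$adjusted_md, x$n1, x$n2
  ))
  invisible(x)
}

# ---- BCa bootstrap --------------------------------------------------------

# Shared BCa machinery: observed statistics (vector), bootstrap replicate
# matrix (reps x k) and jackknife matrix (n x k) -> adjusted-percentile
# bounds per component.
bca_core <- function(t0, t_mat, jack_mat, level) {
  alpha <- (1 - level) / 2
  k <- length(t0)
  out <- matrix(NA_real_, k, 2L)
  z0s <- as_num <- numeric(k)
  for (j in seq_len(k)) {
    t <- t_mat[, j]
    if (all(t == t0[j])) {
      warning("degenerate bootstrap distribution; returning point mass")
      out[j, ] <- c(t0[j], t0[j])
      next
    }
    prop <- mean(t < t0[j])
    b <- length(t)
    prop <- min(max(prop, 0.5 / b), 1 - 0.5 / b)
    z0 <- stats::qnorm(prop)
    theta <- jack_mat[, j]
    dev <- mean(theta) - theta
    denom <- 6 * sum(dev^2)^1.5
    a <- if (denom > 0) sum(dev^3) / denom else 0
    zq <- stats::qnorm(c(alpha, 1 - alpha))
    adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
    out[j, ] <- stats::quantile(t, adj, names = FALSE, type = 7)
    z0s[j] <- z0
    as_num[j] <- a
  }
  attr(out, "z0") <- z0s
  attr(out, "a") <- as_num
  out
}

stratified_indices <- function(strata, reps) {
  n <- length(strata)
  groups <- split(seq_len(n), strata)
  idx <- matrix(0L, reps, n)
  col <- 1L
  for (g in groups) {
    m <- length(g)
    idx[, col:(col + m - 1L)] <- matrix(
      g[sample.int(m, reps * m, replace = TRUE)], reps, m
    )
    col <- col + m
  }
  idx
}

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Resamples rows of `data` with replacement (stratified by `strata` when
#' given, preserving e.g. a trial's 36:15 allocation), computes the bias
#' constant `z0` from the proportion of bootstrap statistics below the
#' observed value and the acceleration `a` from the jackknife skewness
#' `a = sum((mean(theta) - theta)^3) / (6 * sum((mean(theta) - theta)^2)^(3/2))`,
#' and returns the adjusted-percentile bounds.
#'
#' @param statistic_fn Function `(data, indices) -> scalar`, evaluated on
#'   row subsets of `data`.
#' @param data Data frame (rows are the resampling unit, e.g.
#'   participants) or vector.
#' @param reps Number of bootstrap replications (>= 100; the reference
#'   analysis uses 5000).
#' @param level Confidence level.
#' @param seed Optional integer seed.
#' @param strata Optional factor defining resampling strata.
#' @param indices Optional `reps x n` integer matrix of resample indices,
#'   overriding random resampling (useful for exhaustive enumeration).
#' @return Numeric vector `c(ci_low, ci_high)` with attributes `z0`, `a`,
#'   `t0` and `reps`.
#' @export
bca_bootstrap_ci <- function(statistic_fn, data, reps = 5000, level = 0.95,
                             seed = NULL, strata = NULL, indices = NULL) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (is.null(indices) && reps < 100) stop("`reps` must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  t0 <- statistic_fn(data, seq_len(n))
  if (is.null(indices)) {
    indices <- if (is.null(strata)) {
      matrix(sample.int(n, reps * n, replace = TRUE), reps, n)
    } else {
      stratified_indices(strata, reps)
    }
  }
  t_mat <- matrix(
    apply(indices, 1L, function(idx) statistic_fn(data, idx)),
    ncol = 1L
  )
  jack <- matrix(
    vapply(
      seq_len(n), function(i) statistic_fn(data, seq_len(n)[-i]),
      numeric(1)
    ),
    ncol = 1L
  )
  ci <- bca_core(t0, t_mat, jack, level)
  structure(
    c(ci_low = ci[1L, 1L], ci_high = ci[1L, 2L]),
    z0 = attr(ci, "z0"), a = attr(ci, "a"), t0 = t0,
    reps = nrow(indices)
  )
}

# ---- Hedges g -------------------------------------------------------------

hedges_j <- function(df) 1 - 3 / (4 * df - 1)

g_from_groups <- function(md, y1, y2) {
  n1 <- length(y1)
  n2 <- length(y2)
  s_pool <- sqrt(
    ((n1 - 1) * stats::var(y1) + (n2 - 1) * stats::var(y2)) / (n1 + n2 - 2)
  )
  if (!is.finite(s_pool) || s_pool <= 0) {
    stop("pooled follow-up SD is zero; Hedges g undefined")
  }
  hedges_j(n1 + n2 - 2) * md / s_pool
}

#' Hedges g effect size for an adjusted mean difference
#'
#' Standardizes the adjusted mean difference by the follow-up SD pooled
#' across arms and applies the small-sample correction
#' `J = 1 - 3 / (4 * (n1 + n2 - 2) - 1)`. Anchors: 0.2 small, 0.5
#' moderate, 0.8 large.
#'
#' @inheritParams ancova_adjusted_difference
#' @param adjusted_md The adjusted mean difference to standardize (from
#'   [ancova_adjusted_difference()]).
#' @return Numeric scalar g.
#' @export
hedges_g <- function(outcome_table, adjusted_md, outcome, timepoint) {
  fu <- outcome_table[outcome_table$week == timepoint, ]
  y1 <- fu[[outcome]][fu$arm == "intervention"]
  y2 <- fu[[outcome]][fu$arm == "control"]
  if (length(y1) < 2L || length(y2) < 2L) {
    stop("both arms need at least 2 observations")
  }
  g_from_groups(adjusted_md, y1, y2)
}

# ---- full adjusted effect -------------------------------------------------

#' Adjusted mean difference with BCa bootstrap CI and Hedges g
#'
#' Runs the ANCOVA, then bootstraps participants (resampled with
#' replacement, stratified by arm so the allocation ratio is preserved) to
#' obtain BCa confidence intervals for the adjusted mean difference and for
#' Hedges g from one shared set of resamples.
#'
#' @inheritParams ancova_adjusted_difference
#' @param reps Bootstrap replications (default 5000, as in the reference
#'   analysis; reduce for speed).
#' @param level Confidence level.
#' @param seed Integer seed for the bootstrap (required: stochastic
#'   procedures are always seeded and logged).
#' @return Object of class `adjusted_effect` with fields `outcome`,
#'   `timepoint`, `adjusted_md`, `ci_low`, `ci_high`, `hedges_g`,
#'   `g_ci_low`, `g_ci_high`, `n1`, `n2`, `reps`, `seed`.
#' @export
adjusted_effect <- function(outcome_table, outcome, timepoint,
                            reps = 5000, level = 0.95, seed,
                            baseline = "baseline") {
  if (missing(seed)) stop("`seed` is required for the bootstrap")
  d <- ancova_frame(outcome_table, outcome, timepoint, baseline)
  des <- ancova_design(d)
  x <- des$x
  y <- d$.y
  int_rows <- d$arm == "intervention"
  stat_both <- function(idx) {
    md <- arm_coef(x, y, idx)
    yi <- y[idx]
    sel <- int_rows[idx]
    g <- tryCatch(
      g_from_groups(md, yi[sel], yi[!sel]),
      error = function(e) NA_real_
    )
    c(md, g)
  }
  n <- nrow(d)
  t0 <- stat_both(seq_len(n))

  set.seed(seed)
  idx_mat <- stratified_indices(d$arm, reps)
  t_mat <- t(apply(idx_mat, 1L, stat_both))
  jack <- t(vapply(seq_len(n), function(i) stat_both(seq_len(n)[-i]),
    numeric(2)
  ))
  ok <- stats::complete.cases(t_mat)
  ci <- bca_core(t0, t_mat[ok, , drop = FALSE], jack, level)

  structure(
    list(
      outcome = outcome, timepoint = timepoint,
      adjusted_md = t0[1L], ci_low = ci[1L, 1L], ci_high = ci[1L, 2L],
      hedges_g = t0[2L], g_ci_low = ci[2L, 1L], g_ci_high = ci[2L, 2L],
      n1 = sum(int_rows), n2 = sum(!int_rows),
      reps = reps, seed = seed, level = level
    ),
    class = "adjusted_effect"
  )
}

#' @export
print.adjusted_effect <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<adjusted_effect> %s at %s\n",
      "  adjusted difference %.4g (%.0f%% BCa CI %.4g to %.4g)\n",
      "  Hedges g %.2f (%.4g to %.4g) | n = %d/%d | %d bootstrap reps\n"
    ),
    x$outcome, x$timepoint, x$adjusted_md, 100 * x$level, x$ci_low,
    x$ci_high, x$hedges_g, x$g_ci_low, x$g_ci_high, x$n1, x$n2, x$reps
  ))
  invisible(x)
}

#' Effects table across outcomes and time points
#'
#' @inheritParams adjusted_effect
#' @param outcomes Outcome columns to analyse (default: the six dimensions).
#' @param timepoints Follow-up labels to analyse.
#' @return Data frame with one row per outcome x timepoint: `outcome`,
#'   `timepoint`, `md`, `ci_low`, `ci_high`, `g`, `g_ci_low`, `g_ci_high`,
#'   `n1`, `n2`, `reps`, `seed`.
#' @export
effects_table <- function(outcome_table, outcomes = dimension_names(),
                          timepoints = c("week6", "week12"),
                          reps = 5000, level = 0.95, seed,
                          baseline = "baseline") {
  if (missing(seed)) stop("`seed` is required for the bootstrap")
  rows <- list()
  k <- 0L
  for (tp in timepoints) {
    for (oc in outcomes) {
      k <- k + 1L
      e <- adjusted_effect(outcome_table, oc, tp,
        reps = reps, level = level, seed = seed + k, baseline = baseline
      )
      rows[[k]] <- data.frame(
        outcome = oc, timepoint = tp, md = e$adjusted_md,
        ci_low = e$ci_low, ci_high = e$ci_high, g = e$hedges_g,
        g_ci_low = e$g_ci_low, g_ci_high = e$g_ci_high,
        n1 = e$n1, n2 = e$n2, reps = e$reps, seed = e$seed,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- subgroups and eligibility -------------------------------------------

#' Unadjusted subgroup descriptives
#'
#' Post hoc descriptive means and SDs per subgroup, arm and time point,
#' either by sex or by baseline activity (participants split at the cohort
#' median baseline PAL; ties go to the low-activity group).
#'
#' @inheritParams ancova_adjusted_difference
#' @param by `"sex"` or `"baseline_activity"`.
#' @param outcomes Outcome columns to summarize.
#' @return Data frame with columns `subgroup`, `arm`, `week`, `outcome`,
#'   `n`, `mean`, `sd`; empty cells are reported with `n = 0` and missing
#'   mean/SD.
#' @export
subgroup_descriptives <- function(outcome_table,
                                  by = c("sex", "baseline_activity"),
                                  outcomes = dimension_names()) {
  by <- match.arg(by)
  d <- outcome_table
  if (by == "sex") {
    d$.subgroup <- d$sex
  } else {
    bl <- d[d$week == "baseline", c("participant", "pal")]
    med <- stats::median(bl$pal)
    bl$.subgroup <- ifelse(bl$pal <= med, "low_baseline_pa",
      "high_baseline_pa"
    )
    d <- merge(d, bl[, c("participant", ".subgroup")], by = "participant")
  }
  cells <- expand.grid(
    subgroup = sort(unique(d$.subgroup)),
    arm = c("intervention", "control"),
    week = unique(d$week),
    outcome = outcomes,
    stringsAsFactors = FALSE
  )
  cells$n <- NA_integer_
  cells$mean <- NA_real_
  cells$sd <- NA_real_
  for (i in seq_len(nrow(cells))) {
    v <- d[[cells$outcome[i]]][
      d$.subgroup == cells$subgroup[i] & d$arm == cells$arm[i] &
        d$week == cells$week[i]
    ]
    cells$n[i] <- length(v)
    if (length(v) > 0L) cells$mean[i] <- mean(v)
    if (length(v) > 1L) cells$sd[i] <- stats::sd(v)
  }
  cells
}

#' Baseline eligibility screen on physical activity level
#'
#' Participants already leading a highly active lifestyle (PAL >= 2.0 at
#' baseline) are excluded; exclusions are logged with the reason.
#'
#' @param baseline_pal Named numeric vector of baseline PAL values (names
#'   are participant ids), or a data frame with `participant` and `pal`
#'   columns.
#' @return List with `included` and `excluded` participant id vectors and a
#'   `log` data frame (`participant`, `pal`, `reason`).
#' @export
eligibility_screen <- function(baseline_pal) {
  if (is.data.frame(baseline_pal)) {
    pal <- stats::setNames(baseline_pal$pal, baseline_pal$participant)
  } else {
    pal <- baseline_pal
  }
  ids <- names(pal)
  if (is.null(ids)) ids <- as.character(seq_along(pal))
  excl <- pal >= 2.0
  list(
    included = ids[!excl],
    excluded = ids[excl],
    log = data.frame(
      participant = ids[excl],
      pal = unname(pal[excl]),
      reason = rep("too active at baseline (PAL >= 2.0)", sum(excl)),
      stringsAsFactors = FALSE
    )
  )
}
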