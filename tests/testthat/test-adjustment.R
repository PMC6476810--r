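make_estimates <- function(subject_id, level, log_hr, se = 0.5,
                           mistake_cat = "NONE",
                           assessment_type = "JEWELS_A",
                           wall_time = as.POSIXct("2026-01-05", tz = "UTC")) {
  n <- max(length(subject_id), length(level), length(log_hr))
  tibble::tibble(
    game_id = sprintf("g%03d", seq_len(n)),
    subject_id = rep_len(subject_id, n),
    assessment_type = rep_len(assessment_type, n),
    level = as.integer(rep_len(level, n)),
    mistake_cat = factor(rep_len(mistake_cat, n),
                         levels = c("NONE", "ONE", "MORE_THAN_ONE")),
    wall_time = rep_len(wall_time, n),
    ref_level = as.integer(rep_len(level, n)),
    log_hr = rep_len(log_hr, n),
    se = rep_len(se, n),
    hr = exp(rep_len(log_hr, n)),
    converged = TRUE, penalized = FALSE
  )
}

test_that("a single observed level fixes the slope to zero with a warning", {
  est <- make_estimates(c("a", "a", "b", "b"), 3, c(-1, -1.2, -0.8, -1.1))
  expect_warning(m <- fit_adjustment(est), "fewer than 2 distinct levels")
  expect_equal(m$level_slope, 0)
  expect_equal(adjust(est, m), est$log_hr)  # adjustment is the identity
})

test_that("an injected level effect is recovered on a balanced design", {
  set.seed(21)
  n_sub <- 30
  levels <- rep(2:5, each = 25)
  est <- do.call(rbind, lapply(seq_len(n_sub), function(s) {
    make_estimates(sprintf("s%02d", s), sample(levels, 20),
                   log_hr = 0, se = 0.4)
  }))
  est$log_hr <- -1 + 0.3 * est$level + rnorm(nrow(est), 0, 0.4)
  m <- fit_adjustment(est)
  expect_equal(m$method, "lmm")
  expect_equal(m$level_slope, 0.3, tolerance = 0.05)
  # after adjustment no level trend remains
  adj <- adjust(est, m)
  expect_lt(abs(coef(lm(adj ~ est$level))[[2]]), 0.05)
})

test_that("between-subject heterogeneity loads on the random intercept", {
  set.seed(22)
  est <- rbind(
    make_estimates("a", rep(2:4, 10), log_hr = rnorm(30, +0.8, 0.1), se = 0.3),
    make_estimates("b", rep(2:4, 10), log_hr = rnorm(30, -0.8, 0.1), se = 0.3))
  m <- fit_adjustment(est)
  expect_gt(m$random_intercept_sd, 0.3)
})

test_that("a lone subject falls back to weighted least squares", {
  est <- make_estimates("solo", rep(2:3, 5), log_hr = rnorm(10), se = 0.5)
  expect_warning(m <- fit_adjustment(est), "single subject")
  expect_equal(m$method, "wls")
})

test_that("mistake categories are translated out alongside the level", {
  m <- structure(list(intercept = 0, level_slope = -0.5,
                      mistake_effects = c(ONE = -0.2, MORE_THAN_ONE = -0.6),
                      random_intercept_sd = 0, residual_sd = 1,
                      baseline_level = 3L, categorical_level = FALSE,
                      level_effects = NULL, method = "lmm", n_obs = 0L),
                 class = "adjustment_model")
  at_baseline <- make_estimates("a", 3, -2.0)
  expect_equal(adjust(at_baseline, m), -2.0)
  # log_hr -2 at level 4, slope -0.5, baseline 3: -2 - (-0.5)(1) = -1.5
  off <- make_estimates("a", 4, -2.0)
  expect_equal(adjust(off, m), -1.5)
  with_mistakes <- make_estimates("a", 3, -2.0, mistake_cat = "MORE_THAN_ONE")
  expect_equal(adjust(with_mistakes, m), -2.0 - (-0.6))
})

test_that("beta values follow the inverse-variance weighting formula", {
  expect_equal(beta_value(c(-1, -3), c(1, 1))$beta, -2)     # equal weights
  bv <- beta_value(c(-1, -3), c(1, sqrt(3)))
  expect_equal(bv$beta, -1.5, tolerance = 1e-12)
  expect_equal(bv$variance, 1 / (1 + 1 / 3), tolerance = 1e-12)
  single <- beta_value(-0.7, 0.4)
  expect_equal(single$beta, -0.7)
  expect_equal(single$variance, 0.16)
  empty <- beta_value(numeric(0), numeric(0))
  expect_true(is.na(empty$beta))
  expect_equal(empty$n, 0L)
})

test_that("beta is scale-equivariant and never noisier than the plain mean", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    v <- rnorm(n); s <- runif(n, 0.1, 2)
    b <- beta_value(v, s)
    b3 <- beta_value(3 * v, s)
    expect_equal(b3$beta, 3 * b$beta)
    var_mean <- sum(s^2) / n^2
    expect_lte(b$variance, var_mean + 1e-12)
  }
})

test_that("weekly windows anchor at each subject's first game", {
  t0 <- as.POSIXct("2026-01-05 10:00:00", tz = "UTC")
  est <- make_estimates("a", 3, c(-1, -2, -1.5), se = 0.5)
  est$wall_time <- t0 + c(0, 2, 9) * 86400  # days 0, 2, 9
  m <- suppressWarnings(fit_adjustment(est))
  wk <- weekly_betas(est, m)
  expect_equal(sort(unique(wk$week_index)), c(1L, 2L))
  expect_equal(wk$n_games[wk$week_index == 1], 2L)

  # a single-window subject reproduces the study-wide beta
  est1 <- est; est1$wall_time <- t0 + c(0, 1, 2) * 86400
  wk1 <- weekly_betas(est1, m)
  sw <- study_betas(est1, m)
  expect_equal(nrow(wk1), 1L)
  expect_equal(wk1$beta, sw$beta)
  expect_equal(wk1$variance, sw$variance)
})

test_that("beta tables and adjustment models serialise", {
  est <- make_estimates(rep(c("a", "b"), each = 6), rep(2:4, 4),
                        log_hr = rnorm(12), se = 0.5)
  m <- fit_adjustment(est)
  betas <- study_betas(est, m)
  f <- withr::local_tempfile(fileext = ".csv")
  write_betas(betas, f)
  expect_equal(as.data.frame(read_betas(f)), as.data.frame(betas),
               tolerance = 1e-12)
  fy <- withr::local_tempfile(fileext = ".yaml")
  write_adjustment(m, fy)
  obj <- yaml::read_yaml(fy)
  expect_equal(obj$baseline_level, m$baseline_level)
  expect_equal(obj$level_slope, m$level_slope, tolerance = 1e-6)
})
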