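test_that("reference tap times are per-index means of control games", {
  one <- make_game("c1", c(1, 2, 3), subject_id = "C1")
  expect_equal(build_reference(one, "JEWELS_A", 3)$tap_times, c(1, 2, 3))

  two <- rbind(make_game("c1", c(1, 2, 3), subject_id = "C1"),
               make_game("c2", c(3, 4, 5), subject_id = "C2"))
  ref <- build_reference(two, "JEWELS_A", 3)
  expect_equal(ref$tap_times, c(2, 3, 4))
  expect_equal(ref$n_source_games, 2L)

  # orderedness is checked, not assumed: these means happen to be increasing
  cross <- rbind(make_game("c1", c(1, 4), subject_id = "C1"),
                 make_game("c2", c(3, 2), subject_id = "C2"))
  expect_equal(build_reference(cross, "JEWELS_A", 2)$tap_times, c(2, 3))

  flat <- rbind(make_game("c1", c(1, 4), subject_id = "C1"),
                make_game("c2", c(5, 2), subject_id = "C2"))
  expect_error(build_reference(flat, "JEWELS_A", 2), "strictly increasing")

  expect_error(build_reference(one, "JEWELS_B", 3), "no completed control games")
})

test_that("find_reference prefers exact level, then nearest (ties up)", {
  games <- rbind(make_game("c1", c(1, 2), subject_id = "C1"),
                 make_game("c2", c(1, 2, 3, 4), subject_id = "C1"))
  refs <- build_reference_set(games)
  expect_equal(find_reference(refs, "JEWELS_A", 2)$level, 2L)
  expect_equal(find_reference(refs, "JEWELS_A", 4)$level, 4L)
  expect_equal(find_reference(refs, "JEWELS_A", 3)$level, 4L)  # tie -> higher
  expect_null(find_reference(refs, "JEWELS_B", 2))
})

test_that("partial likelihood at log HR 0 sums -log(risk-set size)", {
  d <- encode_pair(list(level = 2, tap_times = c(2, 4)),
                   list(level = 2, tap_times = c(1, 3)))
  # risk sets at event times 1, 2, 3, 4 have sizes 4, 3, 2, 1
  expect_equal(partial_likelihood(d, 0), -sum(log(c(4, 3, 2, 1))))

  d2 <- encode_pair(list(level = 2, tap_times = c(1.5, 3)),
                    list(level = 3, tap_times = c(1, 2, 3)))
  sizes <- vapply(d2$time[d2$status == 1], function(t) sum(d2$time >= t),
                  numeric(1))
  expect_equal(partial_likelihood(d2, 0), -sum(log(sizes)))
})

test_that("identical units make 0 a stationary point of the partial likelihood", {
  g <- list(level = 3, tap_times = c(1, 2.2, 4.1))
  d <- encode_pair(g, g)
  h <- 1e-6
  deriv <- (partial_likelihood(d, h) - partial_likelihood(d, -h)) / (2 * h)
  expect_lt(abs(deriv), 1e-6)
})

test_that("cox_fit maximises the partial likelihood it reports", {
  d <- encode_pair(list(level = 2, tap_times = c(2, 4)),
                   list(level = 2, tap_times = c(1, 3)))
  fit <- cox_fit(d)
  b_grid <- grid_argmax(d)
  expect_lt(abs(fit$log_hr - b_grid), 1e-5)
  expect_gt(partial_likelihood(d, fit$log_hr), partial_likelihood(d, 0))
})

test_that("cox_fit agrees with survival::coxph under Breslow ties", {
  set.seed(7)
  for (i in 1:25) {
    d <- random_pair_dataset()
    if (sum(d$status[d$unit == "REFERENCE"]) == 0 ||
        sum(d$status[d$unit == "ASSESSMENT"]) == 0) next
    fit <- cox_fit(d)
    if (fit$penalized) next
    df <- data.frame(time = d$time, status = d$status,
                     x = as.numeric(d$unit == "ASSESSMENT"))
    cph <- survival::coxph(survival::Surv(time, status) ~ x, data = df,
                           ties = "breslow")
    expect_equal(fit$log_hr, unname(coef(cph)), tolerance = 1e-5)
    expect_equal(fit$se, sqrt(vcov(cph)[1, 1]), tolerance = 1e-5)
  }
})

test_that("scoring any game against itself gives log HR 0", {
  set.seed(11)
  for (lv in 1:5) {
    g <- list(level = lv, tap_times = cumsum(rexp(lv, 0.7)))
    fit <- cox_fit(encode_pair(g, g))
    expect_lt(abs(fit$log_hr), 1e-6)
  }
})

test_that("swapping unit labels negates the log hazard ratio", {
  set.seed(13)
  for (i in 1:20) {
    la <- sample(2:4, 1); lr <- sample(2:4, 1)
    a <- list(level = la, tap_times = cumsum(rexp(la, 1)))
    r <- list(level = lr, tap_times = cumsum(rexp(lr, 0.6)))
    f1 <- cox_fit(encode_pair(a, r))
    f2 <- cox_fit(encode_pair(r, a))
    expect_equal(f1$log_hr, -f2$log_hr, tolerance = 1e-6)
  }
})

test_that("slowing the assessment strictly decreases its hazard ratio", {
  ref <- list(level = 3, tap_times = c(1, 2, 3))
  base <- list(level = 3, tap_times = c(1.1, 2.3, 3.2))
  hr0 <- cox_fit(encode_pair(base, ref))$hr
  for (c_slow in c(1.5, 2, 3)) {
    hr <- cox_fit(encode_pair(list(level = 3, tap_times = base$tap_times * c_slow),
                              ref))$hr
    expect_lt(hr, hr0)
  }
  for (c_fast in c(0.5, 0.8)) {
    hr <- cox_fit(encode_pair(list(level = 3, tap_times = base$tap_times * c_fast),
                              ref))$hr
    expect_gt(hr, hr0)
  }
})

test_that("standard errors shrink (weakly) as the level grows at fixed HR", {
  ses <- vapply(2:6, function(L) {
    ref <- list(level = L, tap_times = seq_len(L))
    asmt <- list(level = L, tap_times = seq_len(L) * 1.3)
    cox_fit(encode_pair(asmt, ref))$se
  }, numeric(1))
  expect_true(all(diff(ses) <= 1e-12))
})

test_that("monotone likelihoods are detected and ridge-penalised", {
  # assessment finishes before any reference jewel is tapped: separation
  d <- encode_pair(list(level = 3, tap_times = c(1, 2, 3)),
                   list(level = 3, tap_times = c(10, 11, 12)))
  fit <- cox_fit(d)
  expect_true(fit$penalized)
  expect_true(is.finite(fit$log_hr))
  expect_gt(fit$se, 0)
  expect_gt(fit$log_hr, 0)  # assessment is the faster unit
})

test_that("cox_fit rejects degenerate inputs", {
  d <- encode_pair(list(level = 2, tap_times = c(1, 2)),
                   list(level = 2, tap_times = c(1, 3)))
  d_no_ev <- d
  d_no_ev$status[d_no_ev$unit == "REFERENCE"] <- 0L
  expect_error(cox_fit(d_no_ev), "zero events")
  d_bad <- d
  d_bad$time[1] <- Inf
  expect_error(cox_fit(d_bad), "non-finite")
})

test_that("score_all scores every completed game and reports the rest", {
  games <- rbind(
    make_game("c1", c(1, 2, 3), subject_id = "C1"),
    make_game("g1", c(2, 4, 6), subject_id = "P1"),
    make_game("g2", c(1, 2), subject_id = "P1"),
    make_game("g3", c(1, 2), level = 3, subject_id = "P1"),          # incomplete
    make_game("g4", c(1, 2, 3), subject_id = "P1",
              assessment_type = "JEWELS_B")                          # no reference
  )
  refs <- build_reference_set(games[games$subject_id == "C1", ])
  expect_warning(est <- score_all(games, refs), "could not be scored")
  expect_equal(sort(est$game_id), c("c1", "g1", "g2"))
  expect_equal(est$log_hr[est$game_id == "c1"], 0, tolerance = 1e-8)
  report <- attr(est, "report")
  expect_setequal(report$game_id, c("g3", "g4"))
  expect_match(report$reason[report$game_id == "g3"], "incomplete")
  expect_match(report$reason[report$game_id == "g4"], "no reference")

  expect_warning(empty <- score_all(games[0, ], refs), "no games")
  expect_equal(nrow(empty), 0L)
})

test_that("estimate tables round-trip through CSV", {
  games <- rbind(make_game("c1", c(1, 2, 3), subject_id = "C1"),
                 make_game("g1", c(2, 4, 6), subject_id = "P1", n_mistakes = 2L))
  refs <- build_reference_set(games[games$subject_id == "C1", ])
  est <- score_all(games, refs)
  f <- withr::local_tempfile(fileext = ".csv")
  write_estimates(est, f)
  back <- read_estimates(f)
  expect_equal(as.data.frame(back), as.data.frame(est), tolerance = 1e-12,
               ignore_attr = "report")
})
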