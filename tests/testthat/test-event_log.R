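test_that("event logs round-trip through CSV and JSON-lines field for field", {
  sim <- simulate_study(sim_config(seed = 5, n_control = 2, n_patient = 2,
                                   weeks = 2))
  for (fmt in c("csv", "jsonl")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_events(sim$events, f, format = fmt)
    back <- read_events(f, format = fmt)
    expect_equal(as.data.frame(back), as.data.frame(sim$events),
                 tolerance = 1e-12)
  }
})

test_that("a well-formed CSV parses to one TouchEvent per row, in file order", {
  ev <- make_events("g1", c(1, 2.5, 4), level = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, f)
  got <- read_events(f)
  expect_equal(nrow(got), 3L)
  expect_equal(got$t_seconds, c(1, 2.5, 4))
  expect_equal(got$game_id, rep("g1", 3))
})

test_that("a header-only file yields an empty event table", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("subject_id", "game_id", "assessment_type", "level",
                     "wall_time_start", "t_seconds", "item", "correct"),
                   collapse = ","), f)
  expect_equal(nrow(read_events(f)), 0L)
  fj <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), fj)
  expect_equal(nrow(read_events(fj)), 0L)
})

test_that("schema and parse errors are reported with the offending row", {
  ev <- make_events("g1", c(1, 2, 3))
  f <- withr::local_tempfile(fileext = ".csv")

  bad <- as.data.frame(ev)
  bad$correct <- c("TRUE", "maybe", "TRUE")
  bad$wall_time_start <- format(bad$wall_time_start, "%Y-%m-%dT%H:%M:%SZ")
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_events(f), "row 2.*maybe")

  bad2 <- as.data.frame(ev)
  bad2$t_seconds <- c("1", "soon", "3")
  bad2$wall_time_start <- format(bad2$wall_time_start, "%Y-%m-%dT%H:%M:%SZ")
  write.csv(bad2, f, row.names = FALSE)
  expect_error(read_events(f), "timestamp in row 2")

  bad3 <- bad2[, setdiff(names(bad2), "item")]
  write.csv(bad3, f, row.names = FALSE)
  expect_error(read_events(f), "missing column.*item")
})

test_that("epoch-millisecond clocks are rebased to seconds from game start", {
  ev <- make_events("g1", c(0, 1.5, 4))
  raw <- as.data.frame(ev)
  raw$t_seconds <- 1.7e12 + c(0, 1500, 4000)  # epoch ms
  raw$wall_time_start <- 1.7e12               # epoch ms wall clock
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw, f, row.names = FALSE)
  got <- read_events(f)
  expect_equal(got$t_seconds, c(0, 1.5, 4))
  expect_equal(as.numeric(got$wall_time_start), rep(1.7e9, 3))
})

test_that("assemble_games builds tap times, mistakes and completion flags", {
  ev <- rbind(
    make_events("g1", c(1, 2.5, 4), level = 3),
    make_events("g2", c(1, 3), level = 2, mistake_times = 1.2),
    make_events("g3", c(0.5, 1.5), level = 3)  # only 2 of 3 taps
  )
  games <- assemble_games(ev)
  expect_equal(nrow(games), 3L)
  g1 <- games[games$game_id == "g1", ]
  expect_equal(g1$tap_times[[1]], c(1, 2.5, 4))
  expect_equal(g1$n_mistakes, 0L)
  expect_true(g1$completed)
  g2 <- games[games$game_id == "g2", ]
  expect_equal(g2$n_mistakes, 1L)
  expect_equal(g2$tap_times[[1]], c(1, 3))
  expect_equal(as.character(g2$mistake_cat), "ONE")
  g3 <- games[games$game_id == "g3", ]
  expect_false(g3$completed)
})

test_that("assemble_games rejects integrity violations", {
  too_many <- make_events("g1", c(1, 2, 3), level = 2)
  expect_error(assemble_games(too_many), "correct taps but level")
  backwards <- make_events("g1", c(1, 2, 3))
  backwards$t_seconds <- c(3, 2, 1)
  expect_error(assemble_games(backwards), "non-monotone")
})

test_that("assemble_games is stable under permutation of whole-game blocks", {
  ev <- rbind(make_events("a", c(1, 2), level = 2),
              make_events("b", c(2, 4, 6), level = 3, mistake_times = 3),
              make_events("c", c(0.5, 1)))
  g1 <- assemble_games(ev)
  blocks <- split(seq_len(nrow(ev)), ev$game_id)
  ev2 <- ev[unlist(blocks[c("c", "a", "b")]), ]
  g2 <- assemble_games(ev2)
  g2 <- g2[match(g1$game_id, g2$game_id), ]
  expect_equal(as.data.frame(g1), as.data.frame(g2), ignore_attr = TRUE)
})

test_that("mistake counts collapse to three categories", {
  expect_equal(as.character(mistake_category(c(0, 1, 2, 7))),
               c("NONE", "ONE", "MORE_THAN_ONE", "MORE_THAN_ONE"))
  # all counts >= 2 are indistinguishable
  cats <- mistake_category(2:25)
  expect_true(all(cats == "MORE_THAN_ONE"))
  expect_error(mistake_category(-1), "non-negative")
})

test_that("weekly streams round-trip through long-format CSV", {
  streams <- tibble::tibble(
    subject_id = c("P01", "P01", "P02"), week_index = c(1L, 2L, 1L),
    stream = c("step_count", "step_count", "survey_score"),
    value = c(7000, 6500.5, NA))
  f <- withr::local_tempfile(fileext = ".csv")
  write_weekly_streams(streams, f)
  expect_equal(as.data.frame(read_weekly_streams(f)), as.data.frame(streams))
})
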