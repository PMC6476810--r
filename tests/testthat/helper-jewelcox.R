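# Shared fixtures and the independent brute-force Cox oracle.

# Build a game-record tibble row without going through event logs.
make_game <- function(game_id, tap_times, level = length(tap_times),
                      subject_id = "S1", assessment_type = "JEWELS_A",
                      n_mistakes = 0L,
                      wall_time = as.POSIXct("2026-01-05 09:00:00", tz = "UTC")) {
  taps <- as.numeric(tap_times)
  tibble::tibble(
    subject_id = subject_id, game_id = game_id,
    assessment_type = assessment_type, level = as.integer(level),
    wall_time = wall_time, tap_times = list(taps),
    n_mistakes = as.integer(n_mistakes),
    mistake_cat = mistake_category(n_mistakes),
    completed = length(taps) == level,
    completion_time = max(taps)
  )
}

# Touch-event rows for one game (correct taps only unless mistakes given).
make_events <- function(game_id, tap_times, level = length(tap_times),
                        subject_id = "S1", assessment_type = "JEWELS_A",
                        mistake_times = numeric(0),
                        wall = "2026-01-05T09:00:00Z") {
  t <- c(tap_times, mistake_times)
  ok <- c(rep(TRUE, length(tap_times)), rep(FALSE, length(mistake_times)))
  ord <- order(t)
  tibble::tibble(
    subject_id = subject_id, game_id = game_id,
    assessment_type = assessment_type, level = as.integer(level),
    wall_time_start = as.POSIXct(wall, tz = "UTC",
                                 tryFormats = "%Y-%m-%dT%H:%M:%OSZ"),
    t_seconds = t[ord],
    item = ifelse(ok[ord], "1", "X"),
    correct = ok[ord]
  )
}

# A random two-game encoded dataset with levels <= max_lv.
random_pair_dataset <- function(max_lv = 4) {
  la <- sample(1:max_lv, 1)
  lr <- sample(1:max_lv, 1)
  asmt <- list(level = la, tap_times = cumsum(rexp(la, rate = runif(1, 0.3, 2))))
  ref <- list(level = lr, tap_times = cumsum(rexp(lr, rate = runif(1, 0.3, 2))))
  encode_pair(asmt, ref)
}

# Brute-force oracle: iteratively refined grid maximisation of the exported
# Breslow log partial likelihood. Independent of the Newton path in cox_fit.
grid_argmax <- function(data, lower = -10, upper = 10, points = 2001,
                        rounds = 3) {
  for (r in seq_len(rounds)) {
    grid <- seq(lower, upper, length.out = points)
    ll <- partial_likelihood(data, grid)
    i <- which.max(ll)
    h <- grid[2] - grid[1]
    lower <- grid[i] - 2 * h
    upper <- grid[i] + 2 * h
  }
  grid[i]
}
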