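# Survival encoding: games -> at-risk/event/censor records, KM curves.
#
# Convention: the jewels on screen are the at-risk units, all entering at
# time 0 of the game; each correct tap is an event at its within-game time.
# When two games of different difficulty levels are compared, the lower-level
# game is padded with administratively censored pseudo-jewels at its
# completion time, up to the pairwise maximum level, so both units carry the
# same number of records.

#' Construct a survival dataset
#'
#' Low-level constructor for the two-unit survival representation used by
#' [cox_fit()]. Most users should call [encode_pair()] instead.
#'
#' @param unit Character vector, `"REFERENCE"` or `"ASSESSMENT"`.
#' @param time Positive event/censor times (seconds from game start).
#' @param status 1 for an observed tap (event), 0 for administrative censor.
#' @param tap_index Within-unit tap index.
#' @param max_level The larger of the two compared games' levels.
#' @return A `survival_dataset`: a data frame with the four columns above and
#'   a `max_level` attribute.
#' @export
survival_dataset <- function(unit, time, status, tap_index, max_level) {
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(unit %in% c("REFERENCE", "ASSESSMENT"))) {
    stop("unit must be REFERENCE or ASSESSMENT")
  }
  structure(
    list(unit = as.character(unit), time = as.numeric(time),
         status = as.integer(status), tap_index = as.integer(tap_index)),
    class = c("survival_dataset", "data.frame"),
    row.names = seq_along(unit),
    max_level = as.integer(max_level)
  )
}

# Accept a game-record tibble row, a plain list(level, tap_times), or a
# reference path, and return list(level, tap_times, completion_time).
as_game_path <- function(x, censor_incomplete = FALSE) {
  if (inherits(x, "reference_path")) {
    return(list(level = x$level, tap_times = x$tap_times,
                completed = TRUE, last_time = max(x$tap_times)))
  }
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single game record")
    taps <- x$tap_times[[1]]
    completed <- if ("completed" %in% names(x)) x$completed[[1]] else length(taps) == x$level[[1]]
    return(list(level = x$level[[1]], tap_times = taps, completed = completed,
                last_time = if (length(taps)) max(taps) else NA_real_))
  }
  if (is.list(x)) {
    taps <- x$tap_times
    completed <- if (!is.null(x$completed)) x$completed else length(taps) == x$level
    return(list(level = x$level, tap_times = taps, completed = completed,
                last_time = if (length(taps)) max(taps) else NA_real_))
  }
  stop("cannot interpret object as a game path")
}

#' Encode an assessment/reference pair as survival data
#'
#' Each of a game's correct taps becomes an event record at its tap time,
#' with the game's jewels as the at-risk units (all at risk from time 0). If
#' the two games differ in difficulty level, the lower-level game additionally
#' contributes `max_level - level` censored records at its completion time —
#' the administrative censoring that makes games of different levels
#' comparable in one Cox model.
#'
#' @param assessment A completed game record (one row of the
#'   [assemble_games()] table, or a list with `level` and `tap_times`).
#' @param reference The reference path (see [build_reference()]) or another
#'   completed game.
#' @param max_level Censoring horizon level; defaults to the pairwise maximum
#'   of the two levels. Supply a larger value to censor against a global
#'   maximum instead.
#' @param censor_incomplete If `TRUE`, an incomplete assessment is encoded
#'   with its observed taps as events and the remaining jewels censored at the
#'   last observed tap; if `FALSE` (default) incomplete games are an error.
#' @return A [survival_dataset()] with `2 * max_level` records.
#' @export
#' @examples
#' ref <- list(level = 3, tap_times = c(1, 2, 3))
#' asmt <- list(level = 2, tap_times = c(1.5, 3))
#' encode_pair(asmt, ref)
encode_pair <- function(assessment, reference, max_level = NULL,
                        censor_incomplete = FALSE) {
  a <- as_game_path(assessment)
  r <- as_game_path(reference)
  for (side in list(a, r)) {
    if (!side$completed && !censor_incomplete) {
      stop("incomplete game: set censor_incomplete = TRUE to censor at the ",
           "last observed tap")
    }
    if (length(side$tap_times) == 0L) stop("game has no correct taps to encode")
  }
  if (is.null(max_level)) max_level <- max(a$level, r$level)
  max_level <- as.integer(max_level)
  if (max_level < max(a$level, r$level)) {
    stop("max_level must be at least the larger game level")
  }
  one_unit <- function(side, label) {
    k <- length(side$tap_times)
    n_cens <- max_level - k
    list(unit = rep(label, k + n_cens),
         time = c(side$tap_times, rep(side$last_time, n_cens)),
         status = c(rep(1L, k), rep(0L, n_cens)),
         tap_index = seq_len(k + n_cens))
  }
  ua <- one_unit(a, "ASSESSMENT")
  ur <- one_unit(r, "REFERENCE")
  survival_dataset(unit = c(ur$unit, ua$unit), time = c(ur$time, ua$time),
                   status = c(ur$status, ua$status),
                   tap_index = c(ur$tap_index, ua$tap_index),
                   max_level = max_level)
}

#' Kaplan-Meier curve of a single game
#'
#' With `L = level` jewels at risk from time 0 and no censoring, the
#' product-limit curve of a completed game steps down by `1/L` at each tap
#' time (tied taps drop the curve by the tie multiplicity), reaching 0 at the
#' completion time. Games with identical tap-time multisets and levels have
#' identical curves regardless of their mistake counts.
#'
#' @param game A completed game record (see [encode_pair()] for accepted
#'   forms).
#' @return A `km_curve`: list with `times` (ordered distinct tap times),
#'   `survival` (value of the step function just after each time), and
#'   `level`. The curve is 1 on `[0, times[1])`.
#' @export
#' @examples
#' km_curve(list(level = 3, tap_times = c(1, 2, 3)))
km_curve <- function(game) {
  g <- as_game_path(game)
  if (length(g$tap_times) == 0L) stop("game has no tap times")
  fit <- survival::survfit(
    survival::Surv(g$tap_times, rep(1L, length(g$tap_times))) ~ 1)
  structure(list(times = fit$time, survival = fit$surv, level = g$level),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve
#'
#' @param curve A `km_curve`.
#' @param t Times at which to evaluate the right-continuous step function.
#' @return Survival probabilities `S(t)`.
#' @export
km_survival <- function(curve, t) {
  vapply(t, function(tt) {
    i <- sum(curve$times <= tt)
    if (i == 0L) 1 else curve$survival[[i]]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve (level", x$level, "game)\n")
  print(data.frame(time = x$times, survival = x$survival))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  t <- c(0, x$times)
  s <- c(1, x$survival)
  graphics::plot(t, s, type = "s", ylim = c(0, 1),
                 xlab = "seconds from game start", ylab = "S(t)", ...)
  invisible(x)
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat("Survival dataset (max level ", attr(x, "max_level"), ")\n", sep = "")
  print(as.data.frame(unclass(x)[c("unit", "time", "status", "tap_index")]))
  invisible(x)
}

#' Write a survival dataset to CSV
#'
#' Long-format dump (`unit,time,status,tap_index`) for inspection or
#' cross-checking against external survival software.
#'
#' @param data A [survival_dataset()].
#' @param path Output CSV path.
#' @export
write_survival_csv <- function(data, path) {
  df <- as.data.frame(unclass(data)[c("unit", "time", "status", "tap_index")])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
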