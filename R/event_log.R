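# Touch-event logs: schema, validation, readers/writers, game assembly.
#
# One row per screen touch:
#   subject_id, game_id, assessment_type (JEWELS_A | JEWELS_B), level,
#   wall_time_start (ISO-8601 or epoch ms), t_seconds (within-game time,
#   seconds or epoch ms), item, correct.

EVENT_COLUMNS <- c("subject_id", "game_id", "assessment_type", "level",
                   "wall_time_start", "t_seconds", "item", "correct")

ASSESSMENT_TYPES <- c("JEWELS_A", "JEWELS_B")

MISTAKE_LEVELS <- c("NONE", "ONE", "MORE_THAN_ONE")

#' Read a touch-event log
#'
#' Reads a per-tap event log in CSV or JSON-lines form into the canonical
#' touch-event table. Wall-clock game start times may be ISO-8601 strings or
#' epoch milliseconds; within-game timestamps may be seconds from game start
#' or epoch milliseconds, and are normalised to seconds from game start at
#' parse time (phone logs are typically epoch-based).
#'
#' @param path Path to the event log.
#' @param format `"csv"` or `"jsonl"`; default guesses from the file
#'   extension.
#' @return A tibble with columns `subject_id`, `game_id`, `assessment_type`,
#'   `level`, `wall_time_start` (UTC `POSIXct`), `t_seconds`, `item`,
#'   `correct`, in file order.
#' @seealso [write_events()], [assemble_games()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_events(fig2_fixture_events(), f)
#' ev <- read_events(f)
#' head(ev)
read_events <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("event log not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  raw <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      as.data.frame(matrix(character(), 0, length(EVENT_COLUMNS),
                           dimnames = list(NULL, EVENT_COLUMNS)))
    } else {
      rows <- lapply(seq_along(lines), function(i) {
        rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                        error = function(e) stop("malformed JSON on line ", i,
                                                 ": ", conditionMessage(e)))
        lapply(rec, as.character)
      })
      do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
    }
  }
  missing_cols <- setdiff(EVENT_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("event log schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) return(empty_events())

  parse_num <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad) > 0L) {
      stop("parse error: non-numeric ", what, " in row ", bad[[1]],
           " (value \"", x[[bad[[1]]]], "\")")
    }
    out
  }
  level <- parse_num(raw$level, "level")
  t_raw <- parse_num(raw$t_seconds, "timestamp")
  correct <- parse_logical(raw$correct)
  wall <- parse_wall_time(raw$wall_time_start)

  bad_type <- which(!raw$assessment_type %in% ASSESSMENT_TYPES)
  if (length(bad_type) > 0L) {
    stop("parse error: unknown assessment_type \"",
         raw$assessment_type[[bad_type[[1]]]], "\" in row ", bad_type[[1]])
  }
  if (any(level < 1 | level != floor(level))) {
    stop("parse error: level must be a positive integer (row ",
         which(level < 1 | level != floor(level))[[1]], ")")
  }

  # Epoch-millisecond within-game clocks: rebase per game to seconds from
  # the game's first event.
  for (g in unique(raw$game_id)) {
    idx <- which(raw$game_id == g)
    if (all(t_raw[idx] > 1e11)) {
      t_raw[idx] <- (t_raw[idx] - min(t_raw[idx])) / 1000
    }
  }
  if (any(t_raw < 0)) {
    stop("parse error: negative within-game timestamp in row ",
         which(t_raw < 0)[[1]])
  }

  tibble(
    subject_id = as.character(raw$subject_id),
    game_id = as.character(raw$game_id),
    assessment_type = raw$assessment_type,
    level = as.integer(level),
    wall_time_start = wall,
    t_seconds = t_raw,
    item = as.character(raw$item),
    correct = correct
  )
}

empty_events <- function() {
  tibble(
    subject_id = character(), game_id = character(),
    assessment_type = character(), level = integer(),
    wall_time_start = as.POSIXct(character(), tz = "UTC"),
    t_seconds = numeric(), item = character(), correct = logical()
  )
}

parse_logical <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(lx))
  out[lx %in% c("true", "t", "1")] <- TRUE
  out[lx %in% c("false", "f", "0")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    stop("parse error: row ", bad[[1]], " has non-boolean correct value \"",
         x[[bad[[1]]]], "\"")
  }
  as.logical(out)
}

parse_wall_time <- function(x) {
  x <- trimws(as.character(x))
  num <- suppressWarnings(as.numeric(x))
  if (all(!is.na(num))) {
    # epoch: milliseconds if implausibly large for seconds
    secs <- ifelse(num > 1e11, num / 1000, num)
    return(as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"))
  }
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  if (any(is.na(out))) {
    stop("parse error: unparseable wall_time_start in row ", which(is.na(out))[[1]])
  }
  out
}

#' Write a touch-event log
#'
#' Inverse of [read_events()]: writes the canonical event table as CSV or
#' JSON-lines with ISO-8601 wall-clock times, so that reading the file back
#' reproduces the table field for field (wall times at whole-second
#' precision).
#'
#' @param events Event tibble as returned by [read_events()] or
#'   [simulate_study()].
#' @param path Output path.
#' @param format `"csv"`, `"jsonl"`, or `"auto"` (from extension).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  out <- as.data.frame(events[, EVENT_COLUMNS])
  out$wall_time_start <- format(out$wall_time_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (format == "csv") {
    write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(out))) {
      writeLines(jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
    }
  }
  invisible(path)
}

#' Assemble touch events into per-game records
#'
#' Groups validated touch events by game and produces one record per game:
#' the ordered correct-tap times, the mistake count and its category, and a
#' completion flag (a game is complete when the number of correct taps equals
#' its level, i.e. every jewel was tapped). Incomplete games are retained and
#' flagged, never silently dropped.
#'
#' @param events Event tibble (see [read_events()]).
#' @return A game-record tibble with columns `subject_id`, `game_id`,
#'   `assessment_type`, `level`, `wall_time`, `tap_times` (list column of
#'   correct-tap times in seconds), `n_mistakes`, `mistake_cat`, `completed`,
#'   and `completion_time` (`NA` for games with no correct tap).
#' @details Within a game, event times must be non-decreasing; more correct
#'   taps than the level is a data-integrity error. Tied tap times are
#'   permitted (they are measure-zero for continuous clocks) and handled by
#'   the Breslow convention downstream.
#' @export
assemble_games <- function(events) {
  if (nrow(events) == 0L) return(empty_games())
  gid <- factor(events$game_id, levels = unique(events$game_id))
  idx_list <- split(seq_len(nrow(events)), gid)
  n <- length(idx_list)
  subject_id <- character(n); game_id <- character(n)
  assessment_type <- character(n); level <- integer(n)
  wall_time <- rep(events$wall_time_start[1], n)
  tap_times <- vector("list", n)
  n_mistakes <- integer(n); completed <- logical(n); completion_time <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    i <- idx_list[[k]]
    for (col in c("subject_id", "assessment_type", "level")) {
      if (length(unique(events[[col]][i])) != 1L) {
        stop("data-integrity error: game ", names(idx_list)[k],
             " has inconsistent ", col)
      }
    }
    t <- events$t_seconds[i]
    if (is.unsorted(t)) {
      stop("data-integrity error: non-monotone event times within game ",
           names(idx_list)[k])
    }
    ok <- events$correct[i]
    lv <- events$level[i][[1]]
    if (sum(ok) > lv) {
      stop("data-integrity error: game ", names(idx_list)[k], " has ",
           sum(ok), " correct taps but level ", lv)
    }
    subject_id[k] <- events$subject_id[i][[1]]
    game_id[k] <- names(idx_list)[k]
    assessment_type[k] <- events$assessment_type[i][[1]]
    level[k] <- lv
    wall_time[k] <- events$wall_time_start[i][[1]]
    tap_times[[k]] <- t[ok]
    n_mistakes[k] <- sum(!ok)
    completed[k] <- sum(ok) == lv
    if (sum(ok) > 0L) completion_time[k] <- max(t[ok])
  }
  tibble(
    subject_id = subject_id, game_id = game_id,
    assessment_type = assessment_type, level = level,
    wall_time = wall_time, tap_times = tap_times,
    n_mistakes = n_mistakes,
    mistake_cat = mistake_category(n_mistakes),
    completed = completed, completion_time = completion_time
  )
}

empty_games <- function() {
  tibble(
    subject_id = character(), game_id = character(),
    assessment_type = character(), level = integer(),
    wall_time = as.POSIXct(character(), tz = "UTC"),
    tap_times = list(), n_mistakes = integer(),
    mistake_cat = factor(character(), levels = MISTAKE_LEVELS),
    completed = logical(), completion_time = numeric()
  )
}

#' Categorise a mistake count
#'
#' The number of incorrect touches in a game is treated as a categorical
#' variable with three levels: no mistake, exactly one, and more than one
#' (all counts of two or more collapse to a single level). A consequence is
#' that games with the same Kaplan-Meier curve but, say, 2 and 7 mistakes are
#' scored identically.
#'
#' @param n_mistakes Non-negative integer vector of mistake counts.
#' @return A factor with levels `NONE`, `ONE`, `MORE_THAN_ONE`.
#' @export
#' @examples
#' mistake_category(c(0, 1, 2, 7))
mistake_category <- function(n_mistakes) {
  if (any(is.na(n_mistakes)) || any(n_mistakes < 0) ||
      any(n_mistakes != floor(n_mistakes))) {
    stop("n_mistakes must be non-negative integers")
  }
  factor(ifelse(n_mistakes == 0, "NONE",
                ifelse(n_mistakes == 1, "ONE", "MORE_THAN_ONE")),
         levels = MISTAKE_LEVELS)
}

#' Read or write long-format weekly streams
#'
#' Weekly companion streams (survey scores, step counts, weekly beta values)
#' are stored long: one row per `(subject_id, week_index, stream)` with a
#' numeric `value` (missing entries allowed).
#'
#' @param path CSV path.
#' @return `read_weekly_streams()`: a tibble with columns `subject_id`,
#'   `week_index`, `stream`, `value`.
#' @export
read_weekly_streams <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "week_index", "stream", "value")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("weekly-stream schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  tibble(
    subject_id = as.character(raw$subject_id),
    week_index = as.integer(raw$week_index),
    stream = as.character(raw$stream),
    value = as.numeric(raw$value)
  )
}

#' @rdname read_weekly_streams
#' @param streams Long-format weekly-stream tibble.
#' @export
write_weekly_streams <- function(streams, path) {
  write.csv(as.data.frame(streams[, c("subject_id", "week_index", "stream", "value")]),
            path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
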