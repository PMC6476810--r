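# End-to-end pipeline: in-memory driver plus file-based stage commands
# (the command-line wrapper in inst/cli/jewelcox.R is a thin shell over the
# pipeline_* functions).

#' Run the full scoring and comparison pipeline in memory
#'
#' events -> games -> control reference paths -> per-game Cox hazard ratios
#' -> level/mistake adjustment -> study-wide (and optionally weekly) beta
#' values -> per-assessment group comparison.
#'
#' @param events Touch-event tibble ([read_events()] / [simulate_study()]).
#' @param groups Tibble with `subject_id` and `group`
#'   (`"control"`/`"patient"`), e.g. the simulation truth table.
#' @param weekly Also compute weekly betas.
#' @param anchor Week-window anchor for the weekly betas (see
#'   [weekly_betas()]).
#' @param leave_one_out Score each control subject against a reference
#'   rebuilt without that subject's own games (default `FALSE`: everyone is
#'   scored against the pooled control reference).
#' @param test Group test passed to [compare_groups()].
#' @param verbose Per-game log lines from [score_all()].
#' @return List with `games`, `references`, `estimates`, `model`, `betas`
#'   (study-wide), `weekly` (or `NULL`), and `comparisons` (one
#'   [compare_groups()] result per assessment type present).
#' @export
#' @examples
#' sim <- simulate_study(sim_config(seed = 3, n_control = 4, n_patient = 4,
#'                                  weeks = 3))
#' res <- analyze_study(sim$events, sim$truth)
#' res$comparisons$JEWELS_B
analyze_study <- function(events, groups, weekly = FALSE,
                          anchor = "first_game", leave_one_out = FALSE,
                          test = "welch", verbose = FALSE) {
  games <- assemble_games(events)
  control_ids <- groups$subject_id[groups$group == "control"]
  control_games <- games[games$subject_id %in% control_ids, ]
  references <- build_reference_set(control_games)
  if (leave_one_out) {
    est_list <- lapply(unique(games$subject_id), function(s) {
      refs_s <- if (s %in% control_ids && length(unique(control_games$subject_id)) > 1) {
        build_reference_set(control_games[control_games$subject_id != s, ])
      } else references
      suppressWarnings(score_all(games[games$subject_id == s, ], refs_s,
                                 verbose = verbose))
    })
    estimates <- do.call(rbind, est_list)
  } else {
    estimates <- suppressWarnings(score_all(games, references, verbose = verbose))
  }
  baseline <- modal_level(control_games$level[control_games$completed])
  model <- suppressWarnings(fit_adjustment(estimates, baseline_level = baseline))
  betas <- study_betas(estimates, model)
  weekly_tab <- if (weekly) weekly_betas(estimates, model, anchor = anchor) else NULL
  grp <- setNames(groups$group, groups$subject_id)
  comparisons <- list()
  for (type in sort(unique(betas$assessment_type))) {
    b <- betas[betas$assessment_type == type, ]
    g <- grp[b$subject_id]
    if (sum(g == "control", na.rm = TRUE) >= 2 &&
        sum(g == "patient", na.rm = TRUE) >= 2) {
      comparisons[[type]] <- compare_groups(
        b$beta[g == "control"], b$beta[g == "patient"],
        test = test, assessment_type = type)
    }
  }
  list(games = games, references = references, estimates = estimates,
       model = model, betas = betas, weekly = weekly_tab,
       comparisons = comparisons)
}

resolve_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  dir
}

log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), " ", ...)
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  invisible(msg)
}

write_resolved_config <- function(cfg, dir, stage) {
  obj <- lapply(unclass(cfg), function(v) {
    if (inherits(v, "POSIXct")) format(v, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC") else v
  })
  writeLines(yaml::as.yaml(obj), file.path(dir, paste0(stage, "_config.yaml")))
}

#' File-based pipeline stages
#'
#' Each stage reads and writes plain-text artifacts so runs are inspectable
#' and reproducible; every stage drops a resolved-config YAML and appends to
#' `pipeline.log` beside its outputs.
#'
#' \describe{
#'   \item{`pipeline_simulate`}{writes `events.csv` (or `.jsonl`),
#'     `streams.csv`, `truth.csv` (includes the group labels used
#'     downstream).}
#'   \item{`pipeline_score`}{events + groups -> `estimates.csv`.}
#'   \item{`pipeline_beta`}{estimates -> `betas.csv`, `weekly_betas.csv`,
#'     `adjustment.yaml`.}
#'   \item{`pipeline_compare`}{betas + groups -> `comparison.json`.}
#'   \item{`pipeline_correlate`}{weekly betas + streams ->
#'     `correlations_<subject>.csv` per requested subject.}
#' }
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @param format `"csv"` or `"jsonl"` event-log format.
#' @return Each stage invisibly returns the path(s) it wrote.
#' @name pipeline
#' @export
pipeline_simulate <- function(out_dir, config = sim_config(),
                              format = c("csv", "jsonl")) {
  format <- match.arg(format)
  resolve_dir(out_dir)
  sim <- simulate_study(config)
  events_path <- file.path(out_dir, paste0("events.", format))
  write_events(sim$events, events_path, format = format)
  write_weekly_streams(sim$streams, file.path(out_dir, "streams.csv"))
  write.csv(as.data.frame(sim$truth), file.path(out_dir, "truth.csv"),
            row.names = FALSE, quote = TRUE)
  write_resolved_config(config, out_dir, "simulate")
  log_line(file.path(out_dir, "pipeline.log"),
           "simulate: seed ", config$seed, ", ",
           length(unique(sim$events$game_id)), " games, ",
           nrow(sim$events), " events -> ", events_path)
  invisible(c(events = events_path,
              streams = file.path(out_dir, "streams.csv"),
              truth = file.path(out_dir, "truth.csv")))
}

#' @rdname pipeline
#' @param events_path Event log (CSV or JSON-lines).
#' @param groups_path CSV with `subject_id,group` columns (the simulation
#'   `truth.csv` works as-is).
#' @param leave_one_out See [analyze_study()].
#' @export
pipeline_score <- function(events_path, groups_path, out_dir,
                           leave_one_out = FALSE) {
  resolve_dir(out_dir)
  events <- read_events(events_path)
  groups <- read.csv(groups_path, stringsAsFactors = FALSE)
  games <- assemble_games(events)
  control_games <- games[games$subject_id %in%
                           groups$subject_id[groups$group == "control"], ]
  references <- build_reference_set(control_games)
  estimates <- score_all(games, references)
  out_path <- file.path(out_dir, "estimates.csv")
  write_estimates(estimates, out_path)
  report <- attr(estimates, "report")
  log <- file.path(out_dir, "pipeline.log")
  log_line(log, "score: ", nrow(estimates), " games scored, ",
           nrow(report), " skipped (", events_path, ")")
  for (i in seq_len(nrow(report))) {
    log_line(log, "score: skipped ", report$game_id[[i]], ": ",
             report$reason[[i]])
  }
  invisible(out_path)
}

#' @rdname pipeline
#' @param estimates_path CSV written by `pipeline_score`.
#' @param baseline_level Baseline level for [fit_adjustment()]; default the
#'   modal level among the estimates.
#' @param anchor Week-window anchor for the weekly table: `"first_game"`, or
#'   an ISO-8601 timestamp string for a common origin.
#' @export
pipeline_beta <- function(estimates_path, out_dir, baseline_level = NULL,
                          anchor = "first_game") {
  resolve_dir(out_dir)
  estimates <- read_estimates(estimates_path)
  if (nrow(estimates) == 0L) {
    warning("no estimates; writing empty beta table")
    paths <- file.path(out_dir, c("betas.csv", "weekly_betas.csv"))
    for (p in paths) write_betas(empty_beta_table(), p)
    return(invisible(paths))
  }
  if (is.character(anchor) && anchor != "first_game") {
    anchor <- as.POSIXct(anchor, tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%d"))
  }
  model <- fit_adjustment(estimates, baseline_level = baseline_level)
  betas <- study_betas(estimates, model)
  weekly <- weekly_betas(estimates, model, anchor = anchor)
  paths <- c(betas = file.path(out_dir, "betas.csv"),
             weekly = file.path(out_dir, "weekly_betas.csv"),
             model = file.path(out_dir, "adjustment.yaml"))
  write_betas(betas, paths[["betas"]])
  write_betas(weekly, paths[["weekly"]])
  write_adjustment(model, paths[["model"]])
  log_line(file.path(out_dir, "pipeline.log"),
           "beta: ", nrow(betas), " study-wide + ", nrow(weekly),
           " weekly beta values")
  invisible(paths)
}

empty_beta_table <- function() {
  tibble(subject_id = character(), assessment_type = character(),
         window = character(), week_index = integer(), beta = numeric(),
         variance = numeric(), n_games = integer())
}

#' @rdname pipeline
#' @param betas_path CSV written by `pipeline_beta`.
#' @param test `"welch"` or `"wilcoxon"`.
#' @export
pipeline_compare <- function(betas_path, groups_path, out_dir,
                             test = "welch") {
  resolve_dir(out_dir)
  betas <- read_betas(betas_path)
  betas <- betas[betas$window == "STUDY_WIDE", ]
  groups <- read.csv(groups_path, stringsAsFactors = FALSE)
  grp <- setNames(groups$group, groups$subject_id)
  out <- list()
  for (type in sort(unique(betas$assessment_type))) {
    b <- betas[betas$assessment_type == type, ]
    g <- grp[b$subject_id]
    cmp <- compare_groups(b$beta[g == "control"], b$beta[g == "patient"],
                          test = test, assessment_type = type)
    out[[type]] <- unclass(cmp)
  }
  out_path <- file.path(out_dir, "comparison.json")
  jsonlite::write_json(out, out_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_line(file.path(out_dir, "pipeline.log"),
           "compare: ", length(out), " assessment type(s) -> ", out_path)
  invisible(out_path)
}

#' @rdname pipeline
#' @param weekly_betas_path CSV of weekly betas from `pipeline_beta`.
#' @param streams_path Long-format weekly-stream CSV.
#' @param subjects Subjects to correlate; default all subjects with weekly
#'   betas.
#' @param min_overlap Minimum overlapping weeks per correlation cell.
#' @export
pipeline_correlate <- function(weekly_betas_path, streams_path, out_dir,
                               subjects = NULL, min_overlap = 3) {
  resolve_dir(out_dir)
  weekly <- read_betas(weekly_betas_path)
  streams <- rbind(read_weekly_streams(streams_path),
                   betas_to_streams(weekly))
  if (is.null(subjects)) subjects <- sort(unique(weekly$subject_id))
  paths <- character(0)
  for (s in subjects) {
    corr <- tryCatch(
      weekly_correlations(streams, s, min_overlap = min_overlap),
      error = function(e) NULL)
    if (is.null(corr)) next
    p <- file.path(out_dir, paste0("correlations_", s, ".csv"))
    write_correlations(corr, p)
    paths <- c(paths, p)
  }
  log_line(file.path(out_dir, "pipeline.log"),
           "correlate: wrote ", length(paths), " matrix file(s)")
  invisible(paths)
}
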