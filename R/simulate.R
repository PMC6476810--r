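# Synthetic-study generator.
#
# Generative model: within a game of level L, the L inter-tap gaps are
# exponential with per-tap log-rate
#
#   log rate = log(base_tap_rate) + level_effect * L + group effect
#              + subject effect [+ weekly cognition offset]
#
# so the constant-hazard base case is exactly the model under which the Cox
# encoding is correctly specified, and a subject's expected log hazard ratio
# against the control-derived reference equals their group + subject effect.
# Incorrect touches are injected per tap with a fixed probability; weekly
# survey-score and step-count streams can be linearly coupled to the weekly
# cognition offset.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' 17 controls and 18 patients over 12 weeks; patients complete roughly three
#' times as many assessments (2.0/wk on the A task and 22/12 per week on B,
#' vs 8/12 per week for controls on both); the patient effect is null on the
#' simple task and substantially negative on the task-switching task.
#'
#' @param seed Integer seed; the whole study is reproducible from it.
#' @param n_control,n_patient Group sizes.
#' @param weeks Study duration in weeks.
#' @param games_per_week Named list `control`/`patient`, each a named numeric
#'   vector over `JEWELS_A`/`JEWELS_B` of weekly Poisson game rates.
#' @param level_probs Named probability vector over difficulty levels
#'   (default levels 2-5).
#' @param base_tap_rate Taps per second for the reference process (default
#'   0.5/s, i.e. a 2-second mean inter-tap gap).
#' @param level_effect Additive change in per-tap log rate per unit level
#'   (busier screens are slightly slower; default -0.05).
#' @param group_effect_A,group_effect_B Patient shifts in per-tap log hazard
#'   (defaults 0 and -0.8).
#' @param subject_sd Between-subject sd of the per-subject log-rate offset.
#' @param weekly_sd Sd of the per-subject-week cognition offset (default 0:
#'   no within-subject drift).
#' @param mistake_prob Per-tap probability of an incorrect touch.
#' @param step_base,step_sd,step_coupling Weekly step-count stream: mean,
#'   noise sd, and linear coupling to the weekly cognition offset
#'   (steps per unit log hazard).
#' @param survey_base,survey_sd,survey_coupling Weekly symptom-survey stream,
#'   same roles.
#' @param start_date Study start (UTC).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_control = 17L, n_patient = 18L,
                       weeks = 12L,
                       games_per_week = list(
                         control = c(JEWELS_A = 8 / 12, JEWELS_B = 8 / 12),
                         patient = c(JEWELS_A = 2, JEWELS_B = 22 / 12)),
                       level_probs = c("2" = 0.2, "3" = 0.3, "4" = 0.3,
                                       "5" = 0.2),
                       base_tap_rate = 0.5,
                       level_effect = -0.05,
                       group_effect_A = 0,
                       group_effect_B = -0.8,
                       subject_sd = 0.3,
                       weekly_sd = 0,
                       mistake_prob = 0.05,
                       step_base = 7000, step_sd = 800, step_coupling = 0,
                       survey_base = 10, survey_sd = 2, survey_coupling = 0,
                       start_date = as.POSIXct("2026-01-05", tz = "UTC")) {
  cfg <- list(seed = as.integer(seed), n_control = as.integer(n_control),
              n_patient = as.integer(n_patient), weeks = as.integer(weeks),
              games_per_week = games_per_week, level_probs = level_probs,
              base_tap_rate = base_tap_rate, level_effect = level_effect,
              group_effect_A = group_effect_A, group_effect_B = group_effect_B,
              subject_sd = subject_sd, weekly_sd = weekly_sd,
              mistake_prob = mistake_prob,
              step_base = step_base, step_sd = step_sd,
              step_coupling = step_coupling,
              survey_base = survey_base, survey_sd = survey_sd,
              survey_coupling = survey_coupling,
              start_date = start_date)
  problems <- character()
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(cfg$weeks >= 1, "weeks must be >= 1")
  chk(cfg$n_control >= 0 && cfg$n_patient >= 0, "group sizes must be >= 0")
  chk(cfg$base_tap_rate > 0, "base_tap_rate must be > 0")
  chk(all(unlist(cfg$games_per_week) >= 0), "game rates must be >= 0")
  chk(all(cfg$level_probs >= 0) && abs(sum(cfg$level_probs) - 1) < 1e-8,
      "level_probs must be a probability vector")
  chk(cfg$mistake_prob >= 0 && cfg$mistake_prob <= 1,
      "mistake_prob must be in [0, 1]")
  chk(cfg$subject_sd >= 0 && cfg$weekly_sd >= 0,
      "subject_sd and weekly_sd must be >= 0")
  chk(cfg$step_sd >= 0 && cfg$survey_sd >= 0, "stream sds must be >= 0")
  if (length(problems) > 0L) {
    stop("invalid simulation config: ", paste(problems, collapse = "; "))
  }
  structure(cfg, class = "sim_config")
}

# Jewel label of the k-th correct tap.
tap_item <- function(assessment_type, k) {
  if (assessment_type == "JEWELS_A") return(as.character(k))
  ifelse(k %% 2 == 1, as.character((k + 1) / 2), LETTERS[k / 2])
}

#' Simulate a complete synthetic study
#'
#' Draws weekly game counts, per-game difficulty levels and exponential
#' inter-tap gaps, injects incorrect touches, and generates companion weekly
#' survey and step-count streams, together with a ground-truth table of every
#' subject's true log-hazard offset. Byte-identical output for a given
#' config (including its seed).
#'
#' @param config A [sim_config()].
#' @return A `jewel_study` list:
#'   \describe{
#'     \item{events}{touch-event tibble in the [read_events()] schema}
#'     \item{streams}{long weekly-stream tibble (`step_count`,
#'       `survey_score`)}
#'     \item{truth}{per-subject tibble: `group`, `subject_effect`,
#'       `true_log_hr_A`, `true_log_hr_B`}
#'     \item{weekly_truth}{per subject-week true cognition offset
#'       (subject effect + weekly offset)}
#'     \item{config}{the generating config}
#'   }
#' @export
#' @examples
#' sim <- simulate_study(sim_config(seed = 7, n_control = 3, n_patient = 3,
#'                                  weeks = 2))
#' head(sim$events)
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- c(rep("control", config$n_control), rep("patient", config$n_patient))
  subject_id <- c(sprintf("C%02d", seq_len(config$n_control)),
                  sprintf("P%02d", seq_len(config$n_patient)))
  ns <- length(subject_id)
  subject_effect <- rnorm(ns, 0, config$subject_sd)
  truth <- tibble(
    subject_id = subject_id, group = groups, subject_effect = subject_effect,
    true_log_hr_A = ifelse(groups == "patient", config$group_effect_A, 0) +
      subject_effect,
    true_log_hr_B = ifelse(groups == "patient", config$group_effect_B, 0) +
      subject_effect
  )
  if (ns == 0L) {
    return(structure(list(events = empty_events(),
                          streams = tibble(subject_id = character(),
                                           week_index = integer(),
                                           stream = character(),
                                           value = numeric()),
                          truth = truth,
                          weekly_truth = tibble(subject_id = character(),
                                                week_index = integer(),
                                                cognition = numeric()),
                          config = config), class = "jewel_study"))
  }
  weekly_offset <- matrix(rnorm(ns * config$weeks, 0, config$weekly_sd),
                          ns, config$weeks)

  # --- per-game metadata ------------------------------------------------
  lv_values <- as.integer(names(config$level_probs))
  meta <- list(subject = character(), group = character(), type = character(),
               week = integer())
  for (s in seq_len(ns)) {
    rates <- config$games_per_week[[groups[[s]]]]
    for (type in names(rates)) {
      counts <- rpois(config$weeks, rates[[type]])
      wk <- rep(seq_len(config$weeks), counts)
      k <- length(wk)
      if (k == 0L) next
      meta$subject <- c(meta$subject, rep(subject_id[[s]], k))
      meta$group <- c(meta$group, rep(groups[[s]], k))
      meta$type <- c(meta$type, rep(type, k))
      meta$week <- c(meta$week, wk)
    }
  }
  ng <- length(meta$subject)
  if (ng == 0L) {
    events <- empty_events()
  } else {
    level <- sample(lv_values, ng, replace = TRUE, prob = config$level_probs)
    sidx <- match(meta$subject, subject_id)
    geff <- ifelse(meta$group == "patient",
                   ifelse(meta$type == "JEWELS_A", config$group_effect_A,
                          config$group_effect_B), 0)
    log_rate <- log(config$base_tap_rate) + config$level_effect * level +
      geff + subject_effect[sidx] +
      weekly_offset[cbind(sidx, meta$week)]
    wall <- config$start_date + (meta$week - 1) * 7 * 86400 +
      round(runif(ng, 0, 7 * 86400 - 1))
    game_id <- sprintf("G%06d", seq_len(ng))

    # correct taps: one rexp draw for all gaps, per-game cumulative sums
    gidx <- rep(seq_len(ng), level)
    gaps <- rexp(length(gidx), rate = rep(exp(log_rate), level))
    cs <- cumsum(gaps)
    t_tap <- cs - rep(c(0, cs[cumsum(level)])[seq_len(ng)], level)
    tap_k <- sequence(level)
    completion <- t_tap[cumsum(level)]

    # incorrect touches, uniform over the game's duration
    n_mist <- rbinom(ng, level, config$mistake_prob)
    midx <- rep(seq_len(ng), n_mist)
    t_mist <- runif(length(midx), 0, completion[midx])

    ev_game <- c(gidx, midx)
    ev_t <- c(t_tap, t_mist)
    ev_correct <- c(rep(TRUE, length(gidx)), rep(FALSE, length(midx)))
    ev_item <- c(unlist(lapply(seq_len(ng), function(g)
      tap_item(meta$type[[g]], seq_len(level[[g]])))),
      rep("X", length(midx)))
    ord <- order(ev_game, ev_t)
    events <- tibble(
      subject_id = meta$subject[ev_game][ord],
      game_id = game_id[ev_game][ord],
      assessment_type = meta$type[ev_game][ord],
      level = level[ev_game][ord],
      wall_time_start = wall[ev_game][ord],
      t_seconds = ev_t[ord],
      item = ev_item[ord],
      correct = ev_correct[ord]
    )
  }

  # --- companion weekly streams ----------------------------------------
  cog <- sweep(weekly_offset, 1, subject_effect, "+")
  sw <- expand.grid(s = seq_len(ns), w = seq_len(config$weeks))
  steps <- config$step_base + config$step_coupling * cog[cbind(sw$s, sw$w)] +
    rnorm(nrow(sw), 0, config$step_sd)
  survey <- config$survey_base +
    config$survey_coupling * cog[cbind(sw$s, sw$w)] +
    rnorm(nrow(sw), 0, config$survey_sd)
  streams <- tibble(
    subject_id = rep(subject_id[sw$s], 2),
    week_index = rep(sw$w, 2),
    stream = rep(c("step_count", "survey_score"), each = nrow(sw)),
    value = c(steps, survey)
  )
  weekly_truth <- tibble(subject_id = subject_id[sw$s], week_index = sw$w,
                         cognition = cog[cbind(sw$s, sw$w)])

  structure(list(events = events, streams = streams, truth = truth,
                 weekly_truth = weekly_truth, config = config),
            class = "jewel_study")
}

#' @export
print.jewel_study <- function(x, ...) {
  cat("Synthetic jewels study: ", x$config$n_control, " controls + ",
      x$config$n_patient, " patients, ", x$config$weeks, " weeks\n", sep = "")
  cat("  ", length(unique(x$events$game_id)), " games, ",
      nrow(x$events), " touch events\n", sep = "")
  invisible(x)
}

#' Deterministic worked-example fixture (reference, B, C)
#'
#' A fixed triple of level-mismatched games for the worked example used
#' throughout the documentation and tests: a level-3 reference path (control
#' subject, taps at 1, 2, 3 s); assessment C at the same level but uniformly
#' slower (taps at 2, 4, 6 s), finishing later than the reference; and
#' assessment B at level 2, slower per tap (taps at 1.5, 3 s) but finishing
#' exactly at the reference's completion time — comparable only through
#' level-based censoring. Scoring the triple yields `HR_C < HR_B < 1`.
#'
#' @return `fig2_fixture()`: a 3-row game-record tibble (games `REF`, `B`,
#'   `C`); `fig2_fixture_events()`: the same fixture as a touch-event table.
#' @export
fig2_fixture <- function() {
  assemble_games(fig2_fixture_events())
}

#' @rdname fig2_fixture
#' @export
fig2_fixture_events <- function() {
  wall <- as.POSIXct("2026-01-05 12:00:00", tz = "UTC")
  tibble(
    subject_id = c(rep("control", 3), rep("subject1", 5)),
    game_id = c(rep("REF", 3), rep("B", 2), rep("C", 3)),
    assessment_type = "JEWELS_A",
    level = c(rep(3L, 3), rep(2L, 2), rep(3L, 3)),
    wall_time_start = wall,
    t_seconds = c(1, 2, 3, 1.5, 3, 2, 4, 6),
    item = c("1", "2", "3", "1", "2", "1", "2", "3"),
    correct = TRUE
  )
}
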