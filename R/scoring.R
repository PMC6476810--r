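# Scoring: control-derived reference paths and the pairwise Cox fit.
#
# The hazard ratio of a game against the reference path is the exponentiated
# coefficient of a two-group Cox proportional-hazards model on the encoded
# survival records (ASSESSMENT = 1 vs REFERENCE = 0), with Breslow handling
# of ties. The fit is a one-parameter problem: with a binary covariate the
# Breslow log partial likelihood reduces to
#
#   l(b) = d1 * b - sum_events log(n0(t) + n1(t) * exp(b))
#
# where d1 is the number of assessment events and n0(t), n1(t) are the
# reference/assessment risk-set counts at each event time. l is concave, so a
# damped Newton iteration on the analytic score converges globally; monotone
# likelihoods (the two-unit analogue of complete separation) are detected
# from the sign of the score at the search bounds and handled with a weak
# ridge penalty.

#' Build a control-derived reference path
#'
#' The reference path for an assessment type and difficulty level is the
#' pseudo-game whose k-th tap time is the arithmetic mean of the k-th
#' correct-tap times over completed control games of that type and level
#' (cumulative times, not inter-tap gaps: averaging cumulative times
#' preserves monotonicity whenever every source game is monotone).
#'
#' @param control_games Game-record tibble of control games (see
#'   [assemble_games()]); incomplete games are ignored.
#' @param assessment_type `"JEWELS_A"` or `"JEWELS_B"`.
#' @param level Difficulty level (number of jewels).
#' @return A `reference_path`: list with `assessment_type`, `level`,
#'   `tap_times`, `n_source_games`.
#' @export
#' @examples
#' g <- fig2_fixture()
#' build_reference(g[g$subject_id == "control", ], "JEWELS_A", 3)
build_reference <- function(control_games, assessment_type, level) {
  keep <- control_games$assessment_type == assessment_type &
    control_games$level == level & control_games$completed
  src <- control_games[keep, ]
  if (nrow(src) == 0L) {
    stop("no completed control games of type ", assessment_type, " at level ",
         level, "; pool adjacent levels or supply an interpolated reference")
  }
  taps <- do.call(rbind, src$tap_times)
  ref_times <- colMeans(taps)
  if (any(diff(ref_times) <= 0)) {
    stop("reference tap times are not strictly increasing at level ", level,
         " (", assessment_type, "); check the source games")
  }
  structure(list(assessment_type = assessment_type, level = as.integer(level),
                 tap_times = as.numeric(ref_times),
                 n_source_games = nrow(src)),
            class = "reference_path")
}

#' @export
print.reference_path <- function(x, ...) {
  cat("Reference path: ", x$assessment_type, " level ", x$level, " (mean of ",
      x$n_source_games, " control game", if (x$n_source_games != 1) "s", ")\n",
      sep = "")
  cat("  tap times:", paste(signif(x$tap_times, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Build reference paths for every observed type/level combination
#'
#' @inheritParams build_reference
#' @return A `reference_set`: named list of [build_reference()] results keyed
#'   by `"<type>/<level>"`.
#' @export
build_reference_set <- function(control_games) {
  src <- control_games[control_games$completed, ]
  if (nrow(src) == 0L) stop("no completed control games to build references from")
  combos <- unique(src[, c("assessment_type", "level")])
  refs <- lapply(seq_len(nrow(combos)), function(i) {
    build_reference(src, combos$assessment_type[[i]], combos$level[[i]])
  })
  names(refs) <- paste0(combos$assessment_type, "/", combos$level)
  structure(refs, class = "reference_set")
}

#' Look up the reference path for a game
#'
#' Exact type/level match when available; otherwise the nearest available
#' level of the same assessment type (ties resolved towards the higher
#' level), relying on level-based censoring in [encode_pair()] to keep
#' mixed-level comparisons valid.
#'
#' @param references A `reference_set`.
#' @param assessment_type,level The game's type and level.
#' @return A `reference_path`, or `NULL` when the set contains no path of
#'   that assessment type.
#' @export
find_reference <- function(references, assessment_type, level) {
  if (inherits(references, "reference_path")) {
    return(if (references$assessment_type == assessment_type) references else NULL)
  }
  same_type <- Filter(function(r) r$assessment_type == assessment_type, references)
  if (length(same_type) == 0L) return(NULL)
  levels_avail <- vapply(same_type, function(r) r$level, integer(1))
  d <- abs(levels_avail - level)
  cand <- which(d == min(d))
  if (length(cand) > 1L) cand <- cand[which.max(levels_avail[cand])]
  same_type[[cand]]
}

#' Cox log partial likelihood of a survival dataset
#'
#' Breslow log partial likelihood of the two-group model at a given log
#' hazard ratio, computed by direct summation over risk sets. Exposed so that
#' brute-force maximisation can serve as an independent check on [cox_fit()].
#' At `log_hr = 0` each event contributes `-log(risk-set size)`.
#'
#' @param data A [survival_dataset()].
#' @param log_hr Log hazard ratio(s) at which to evaluate; vectorised.
#' @return Log partial likelihood value(s).
#' @export
partial_likelihood <- function(data, log_hr) {
  if (any(!is.finite(data$time))) stop("non-finite times in survival dataset")
  x <- as.numeric(data$unit == "ASSESSMENT")
  ev <- which(data$status == 1L)
  if (length(ev) == 0L) stop("dataset has no events")
  ll <- numeric(length(log_hr))
  for (i in ev) {
    at_risk <- data$time >= data$time[[i]]
    xr <- x[at_risk]
    # log sum_j exp(x_j * b) over the risk set, for each b
    denom <- vapply(log_hr, function(b) log(sum(exp(xr * b))), numeric(1))
    ll <- ll + x[[i]] * log_hr - denom
  }
  ll
}

# Risk-set counts at each event record: n0/n1 = reference/assessment units
# still at risk, x = event's group indicator.
cox_counts <- function(data) {
  x <- data$unit == "ASSESSMENT"
  ev <- which(data$status == 1L)
  t_ev <- data$time[ev]
  n1 <- vapply(t_ev, function(tt) sum(data$time >= tt & x), numeric(1))
  n0 <- vapply(t_ev, function(tt) sum(data$time >= tt & !x), numeric(1))
  list(n0 = n0, n1 = n1, d1 = sum(x[ev]), n_events = length(ev))
}

# Damped Newton on the (optionally ridge-penalised) Breslow score.
cox_newton <- function(n0, n1, d1, lambda = 0, b0 = 0, tol = 1e-10,
                       max_iter = 100L) {
  ll_fun <- function(b) d1 * b - sum(log(n0 + n1 * exp(b))) - lambda * b^2 / 2
  b <- b0
  ll <- ll_fun(b)
  for (it in seq_len(max_iter)) {
    p <- n1 * exp(b) / (n0 + n1 * exp(b))
    U <- d1 - sum(p) - lambda * b
    I <- sum(p * (1 - p)) + lambda
    if (abs(U) < tol) break
    if (I <= 0) break
    step <- U / I
    step <- max(min(step, 2), -2)  # trust region: l is concave but flat tails
    b_new <- b + step
    ll_new <- ll_fun(b_new)
    h <- 1
    while (ll_new < ll && h > 1e-8) {  # step halving
      h <- h / 2
      b_new <- b + h * step
      ll_new <- ll_fun(b_new)
    }
    if (abs(b_new - b) < 1e-14) { b <- b_new; break }
    b <- b_new
    ll <- ll_new
  }
  p <- n1 * exp(b) / (n0 + n1 * exp(b))
  U <- d1 - sum(p) - lambda * b
  I <- sum(p * (1 - p)) + lambda
  list(log_hr = b, score = U, info = I, converged = abs(U) < 1e-6)
}

#' Fit the pairwise Cox model
#'
#' Maximises the Breslow partial likelihood of the two-group model
#' (ASSESSMENT vs REFERENCE) on an encoded survival dataset and returns the
#' log hazard ratio with its standard error from the observed information at
#' the maximum. A monotone likelihood — the score still bounded away from
#' zero at the search bounds, the two-unit analogue of complete separation —
#' triggers a refit with a weak ridge penalty on the coefficient and sets
#' `penalized = TRUE`.
#'
#' @param data A [survival_dataset()] with at least one event in each unit.
#' @param bound Monotone-likelihood guard: penalise if the unpenalised
#'   maximiser falls outside `[-bound, bound]`. Default 10.
#' @param ridge Ridge penalty weight used by the guard. Default 0.1.
#' @return An `hr_estimate`: list with `log_hr`, `se`, `hr`, `converged`,
#'   `penalized`, `n_events`, `max_level`.
#' @export
#' @examples
#' ref <- list(level = 3, tap_times = c(1, 2, 3))
#' cox_fit(encode_pair(list(level = 3, tap_times = c(2, 4, 6)), ref))
cox_fit <- function(data, bound = 10, ridge = 0.1) {
  if (any(!is.finite(data$time))) stop("non-finite times in survival dataset")
  for (u in c("REFERENCE", "ASSESSMENT")) {
    if (sum(data$status == 1L & data$unit == u) == 0L) {
      stop("unit ", u, " has zero events; cannot fit the Cox model")
    }
  }
  cc <- cox_counts(data)
  score_at <- function(b) cc$d1 - sum(cc$n1 * exp(b) / (cc$n0 + cc$n1 * exp(b)))
  monotone <- score_at(-bound) < 0 || score_at(bound) > 0
  if (!monotone) {
    fit <- cox_newton(cc$n0, cc$n1, cc$d1, lambda = 0)
    monotone <- abs(fit$log_hr) > bound
  }
  penalized <- FALSE
  if (monotone) {
    fit <- cox_newton(cc$n0, cc$n1, cc$d1, lambda = ridge)
    penalized <- TRUE
  }
  se <- if (fit$info > 0) 1 / sqrt(fit$info) else NA_real_
  structure(list(log_hr = fit$log_hr, se = se, hr = exp(fit$log_hr),
                 converged = fit$converged, penalized = penalized,
                 n_events = cc$n_events,
                 max_level = attr(data, "max_level")),
            class = "hr_estimate")
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(sprintf("Cox hazard-ratio estimate: HR = %.4f (log HR = %.4f, se = %.4f)%s\n",
              x$hr, x$log_hr, x$se,
              if (x$penalized) " [ridge-penalized]" else ""))
  invisible(x)
}

#' Score every game against its reference
#'
#' Runs [encode_pair()] + [cox_fit()] for each completed game, matching each
#' game to the reference path of its assessment type via [find_reference()].
#' Games that cannot be scored (no reference of their type, incomplete
#' without `censor_incomplete`, degenerate fits) are collected into a report
#' attached as the `"report"` attribute — never silently dropped.
#'
#' @param games Game-record tibble (see [assemble_games()]).
#' @param references A `reference_set` (or single `reference_path`).
#' @param censor_incomplete Score incomplete games by censoring at their last
#'   observed tap (default `FALSE`: incomplete games are reported, not
#'   scored).
#' @param verbose Log one line per game.
#' @return Tibble with one row per scored game: `game_id`, `subject_id`,
#'   `assessment_type`, `level`, `mistake_cat`, `wall_time`, `ref_level`,
#'   `log_hr`, `se`, `hr`, `converged`, `penalized`; `report` attribute lists
#'   skipped games with reasons.
#' @export
score_all <- function(games, references, censor_incomplete = FALSE,
                      verbose = FALSE) {
  n <- nrow(games)
  if (n == 0L) {
    warning("no games to score")
    return(empty_estimates())
  }
  log_hr <- se <- rep(NA_real_, n)
  converged <- penalized <- rep(NA, n)
  ref_level <- rep(NA_integer_, n)
  skipped <- character(n)
  for (i in seq_len(n)) {
    g <- games[i, ]
    if (!g$completed[[1]] && !censor_incomplete) {
      skipped[i] <- "incomplete game"
      next
    }
    ref <- find_reference(references, g$assessment_type[[1]], g$level[[1]])
    if (is.null(ref)) {
      skipped[i] <- paste0("no reference for type ", g$assessment_type[[1]])
      next
    }
    fit <- tryCatch(
      cox_fit(encode_pair(g, ref, censor_incomplete = censor_incomplete)),
      error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      skipped[i] <- fit
      next
    }
    log_hr[i] <- fit$log_hr
    se[i] <- fit$se
    converged[i] <- fit$converged
    penalized[i] <- fit$penalized
    ref_level[i] <- ref$level
    if (verbose) {
      message(sprintf("scored %s (%s level %d): log HR %.3f (se %.3f)",
                      g$game_id[[1]], g$assessment_type[[1]], g$level[[1]],
                      fit$log_hr, fit$se))
    }
  }
  ok <- !nzchar(skipped)
  est <- tibble(
    game_id = games$game_id, subject_id = games$subject_id,
    assessment_type = games$assessment_type, level = games$level,
    mistake_cat = games$mistake_cat, wall_time = games$wall_time,
    ref_level = ref_level, log_hr = log_hr, se = se, hr = exp(log_hr),
    converged = converged, penalized = penalized
  )[ok, ]
  report <- tibble(game_id = games$game_id[!ok], reason = skipped[!ok])
  if (nrow(report) > 0L) {
    warning(nrow(report), " game(s) could not be scored; see attr(x, 'report')")
  }
  attr(est, "report") <- report
  est
}

empty_estimates <- function() {
  est <- tibble(
    game_id = character(), subject_id = character(),
    assessment_type = character(), level = integer(),
    mistake_cat = factor(character(), levels = MISTAKE_LEVELS),
    wall_time = as.POSIXct(character(), tz = "UTC"),
    ref_level = integer(), log_hr = numeric(), se = numeric(), hr = numeric(),
    converged = logical(), penalized = logical()
  )
  attr(est, "report") <- tibble(game_id = character(), reason = character())
  est
}

#' Read or write a hazard-ratio estimate table
#'
#' CSV round trip for the [score_all()] output (wall times ISO-8601,
#' `mistake_cat` as text).
#'
#' @param estimates Estimate tibble.
#' @param path CSV path.
#' @export
write_estimates <- function(estimates, path) {
  df <- as.data.frame(estimates)
  df$wall_time <- format(df$wall_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df$mistake_cat <- as.character(df$mistake_cat)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  tibble(
    game_id = as.character(raw$game_id),
    subject_id = as.character(raw$subject_id),
    assessment_type = raw$assessment_type,
    level = as.integer(raw$level),
    mistake_cat = factor(raw$mistake_cat, levels = MISTAKE_LEVELS),
    wall_time = as.POSIXct(raw$wall_time, tz = "UTC",
                           tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                          "%Y-%m-%d %H:%M:%OS")),
    ref_level = as.integer(raw$ref_level),
    log_hr = raw$log_hr, se = raw$se, hr = raw$hr,
    converged = as.logical(raw$converged), penalized = as.logical(raw$penalized)
  )
}
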