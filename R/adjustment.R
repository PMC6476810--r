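# Level/mistake adjustment of log hazard ratios and inverse-variance
# aggregation into per-subject "beta values".

#' Fit the level/mistake adjustment model
#'
#' Games are played at heterogeneous difficulty levels, and raw log hazard
#' ratios drift with level; to compare subjects against a common baseline the
#' log hazard ratios are adjusted through a linear mixed model
#'
#'   `log_hr ~ level + mistake_cat + (1 | subject_id)`
#'
#' fitted by REML with observations weighted by `1/se^2` (the Cox standard
#' errors). Level enters linearly by default; `categorical_level = TRUE`
#' replaces the slope with one effect per observed level. The mistake effect
#' is estimated here rather than inside the pairwise Cox fit, which cannot
#' identify it from a two-unit comparison.
#'
#' @param estimates Estimate tibble from [score_all()]; non-converged rows
#'   are dropped with a message.
#' @param baseline_level Level that adjusted values are translated to;
#'   default is the modal level among the estimates (use the modal control
#'   level when calling from a pipeline).
#' @param categorical_level Model level as a factor instead of linearly.
#' @return An `adjustment_model` with elements `intercept`, `level_slope`,
#'   `mistake_effects` (named vector, `ONE` and `MORE_THAN_ONE` vs `NONE`),
#'   `random_intercept_sd`, `residual_sd`, `baseline_level`, `method`
#'   (`"lmm"` or `"wls"`), and for categorical fits `level_effects`.
#' @details With fewer than two distinct levels the slope is fixed at 0 with
#'   a warning; with a single subject the random intercept is inestimable and
#'   the fit falls back to weighted least squares.
#' @export
fit_adjustment <- function(estimates, baseline_level = NULL,
                           categorical_level = FALSE) {
  est <- estimates[!is.na(estimates$log_hr) & is.finite(estimates$se) &
                     estimates$se > 0, ]
  if ("converged" %in% names(est)) {
    n_bad <- sum(!est$converged, na.rm = TRUE)
    if (n_bad > 0L) message("dropping ", n_bad, " non-converged estimate(s)")
    est <- est[est$converged %in% TRUE, ]
  }
  if (nrow(est) == 0L) stop("no usable estimates to fit the adjustment model")
  if (is.null(baseline_level)) baseline_level <- modal_level(est$level)

  df <- data.frame(
    y = est$log_hr,
    level = est$level,
    flevel = factor(est$level),
    mistake_cat = droplevels(est$mistake_cat),
    subject = factor(est$subject_id),
    w = 1 / est$se^2
  )
  n_levels <- length(unique(df$level))
  use_level <- n_levels >= 2
  if (!use_level) {
    warning("fewer than 2 distinct levels; level adjustment fixed to identity")
  }
  use_mistakes <- nlevels(df$mistake_cat) >= 2
  rhs <- c(if (use_level && !categorical_level) "level",
           if (use_level && categorical_level) "flevel",
           if (use_mistakes) "mistake_cat")
  fixed <- paste("y ~", if (length(rhs)) paste(rhs, collapse = " + ") else "1")

  n_subjects <- length(unique(df$subject))
  method <- if (n_subjects >= 2) "lmm" else "wls"
  if (method == "lmm") {
    fit <- tryCatch(
      suppressMessages(lme4::lmer(
        stats::as.formula(paste(fixed, "+ (1 | subject)")),
        data = df, weights = w, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = "ignore",
                                    calc.derivs = FALSE))),
      error = function(e) NULL)
    if (is.null(fit)) method <- "wls"
  }
  if (method == "wls") {
    if (n_subjects < 2) {
      warning("single subject: random intercept inestimable, ",
              "falling back to weighted least squares")
    }
    fit <- stats::lm(stats::as.formula(fixed), data = df, weights = w)
  }

  coefs <- if (method == "lmm") lme4::fixef(fit) else stats::coef(fit)
  getc <- function(nm) if (nm %in% names(coefs)) unname(coefs[[nm]]) else 0
  mistake_effects <- c(ONE = getc("mistake_catONE"),
                       MORE_THAN_ONE = getc("mistake_catMORE_THAN_ONE"))
  level_effects <- NULL
  level_slope <- 0
  if (use_level && categorical_level) {
    lv <- sort(unique(df$level))
    level_effects <- setNames(
      vapply(lv, function(l) getc(paste0("flevel", l)), numeric(1)),
      as.character(lv))
  } else if (use_level) {
    level_slope <- getc("level")
  }
  if (method == "lmm") {
    vc <- as.data.frame(lme4::VarCorr(fit))
    ri_sd <- vc$sdcor[vc$grp == "subject"][1]
    res_sd <- stats::sigma(fit)
  } else {
    ri_sd <- NA_real_
    res_sd <- stats::sigma(fit)
  }
  structure(list(
    intercept = getc("(Intercept)"),
    level_slope = level_slope,
    mistake_effects = mistake_effects,
    random_intercept_sd = ri_sd,
    residual_sd = res_sd,
    baseline_level = as.integer(baseline_level),
    categorical_level = isTRUE(categorical_level) && use_level,
    level_effects = level_effects,
    method = method,
    n_obs = nrow(df)
  ), class = "adjustment_model")
}

modal_level <- function(levels) {
  tab <- table(levels)
  as.integer(names(tab)[which.max(tab)])
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat("Level/mistake adjustment model (", x$method, ", n = ", x$n_obs, ")\n",
      sep = "")
  if (x$categorical_level) {
    cat("  level effects:",
        paste(names(x$level_effects), signif(x$level_effects, 3),
              sep = "=", collapse = ", "), "\n")
  } else {
    cat("  level slope:", signif(x$level_slope, 4),
        "per level (baseline", x$baseline_level, ")\n")
  }
  cat("  mistake effects: ONE =", signif(x$mistake_effects[["ONE"]], 3),
      ", >1 =", signif(x$mistake_effects[["MORE_THAN_ONE"]], 3), "\n")
  cat("  random intercept sd:", signif(x$random_intercept_sd, 3),
      " residual sd:", signif(x$residual_sd, 3), "\n")
  invisible(x)
}

#' Translate estimates to the baseline level and zero-mistake category
#'
#' Subtracts the fitted level effect relative to `baseline_level` and the
#' mistake-category effect, leaving the log hazard ratio a game at the
#' baseline level with no mistakes would be expected to produce.
#'
#' @param estimates Estimate tibble (rows of the [score_all()] output).
#' @param model An [fit_adjustment()] model.
#' @return Numeric vector of adjusted log hazard ratios.
#' @export
adjust <- function(estimates, model) {
  lev <- estimates$level
  if (model$categorical_level) {
    eff <- function(l) {
      key <- as.character(l)
      miss <- !key %in% names(model$level_effects)
      if (any(miss)) stop("no level effect estimated for level ",
                          paste(unique(l[miss]), collapse = ", "))
      unname(model$level_effects[key])
    }
    level_term <- eff(lev) - eff(rep(model$baseline_level, length(lev)))
  } else {
    level_term <- model$level_slope * (lev - model$baseline_level)
  }
  mk <- as.character(estimates$mistake_cat)
  mistake_term <- ifelse(mk == "NONE", 0, model$mistake_effects[mk])
  estimates$log_hr - level_term - unname(mistake_term)
}

#' Inverse-variance weighted summary ("beta value")
#'
#' Fixed-effect meta-analytic pooling of adjusted log hazard ratios:
#' `beta = sum(w * v) / sum(w)` with `w = 1/se^2`, and pooled variance
#' `1 / sum(w)`. This is the minimum-variance convex combination of the
#' inputs.
#'
#' @param values Adjusted log hazard ratios.
#' @param ses Their standard errors (finite, positive).
#' @return List with `beta`, `variance`, `n`. An empty input yields a missing
#'   beta (`NA`), not zero.
#' @export
#' @examples
#' beta_value(c(-1, -3), c(1, sqrt(3)))  # beta = -1.5
beta_value <- function(values, ses) {
  keep <- is.finite(values) & is.finite(ses) & ses > 0
  values <- values[keep]; ses <- ses[keep]
  if (length(values) == 0L) {
    return(list(beta = NA_real_, variance = NA_real_, n = 0L))
  }
  w <- 1 / ses^2
  list(beta = sum(w * values) / sum(w), variance = 1 / sum(w),
       n = length(values))
}

#' Study-wide beta values per subject
#'
#' Adjusts every estimate with [adjust()] and pools within each
#' `(subject, assessment_type)` by inverse-variance weighting. The two
#' assessment types are aggregated entirely separately.
#'
#' @param estimates Estimate tibble from [score_all()].
#' @param model An [fit_adjustment()] model.
#' @return Tibble with `subject_id`, `assessment_type`, `window`
#'   (`"STUDY_WIDE"`), `week_index` (`NA`), `beta`, `variance`, `n_games`.
#' @export
study_betas <- function(estimates, model) {
  pool_betas(estimates, model, weekly = FALSE)
}

#' Weekly beta values per subject
#'
#' Games are binned into 7-day windows anchored, by default, at each
#' subject's first observed game (not calendar weeks), so weekly values track
#' change relative to each subject's own baseline; weeks with no games are
#' simply absent (missing, not zero). The study-wide adjustment model is
#' reused across weeks.
#'
#' @inheritParams study_betas
#' @param anchor `"first_game"` (default) anchors each subject's windows at
#'   their own first game. Supply a single `POSIXct` origin instead to bin
#'   every subject on the same week grid — required when the weekly betas
#'   will be correlated against other streams collected on a common weekly
#'   schedule, where per-subject anchors would misalign the windows.
#' @return Tibble as [study_betas()] but with `window = "WEEK"` and the
#'   1-based `week_index`.
#' @export
weekly_betas <- function(estimates, model, anchor = "first_game") {
  pool_betas(estimates, model, weekly = TRUE, anchor = anchor)
}

pool_betas <- function(estimates, model, weekly, anchor = "first_game") {
  est <- estimates[!is.na(estimates$log_hr) & is.finite(estimates$se), ]
  if (nrow(est) == 0L) {
    return(tibble(subject_id = character(), assessment_type = character(),
                  window = character(), week_index = integer(),
                  beta = numeric(), variance = numeric(), n_games = integer()))
  }
  adj <- adjust(est, model)
  if (weekly) {
    origin <- if (inherits(anchor, "POSIXct")) {
      rep(as.numeric(anchor), nrow(est))
    } else {
      first_seen <- tapply(as.numeric(est$wall_time), est$subject_id, min)
      unname(first_seen[est$subject_id])
    }
    days <- (as.numeric(est$wall_time) - origin) / 86400
    week <- as.integer(floor(days / 7) + 1)
  } else {
    week <- rep(NA_integer_, nrow(est))
  }
  key <- paste(est$subject_id, est$assessment_type, week, sep = "\r")
  idx <- split(seq_len(nrow(est)), key)
  rows <- lapply(idx, function(i) {
    bv <- beta_value(adj[i], est$se[i])
    list(subject_id = est$subject_id[[i[1]]],
         assessment_type = est$assessment_type[[i[1]]],
         week_index = week[[i[1]]], beta = bv$beta, variance = bv$variance,
         n_games = bv$n)
  })
  pull <- function(what, proto) unname(vapply(rows, `[[`, proto, what))
  out <- tibble(
    subject_id = pull("subject_id", character(1)),
    assessment_type = pull("assessment_type", character(1)),
    window = if (weekly) "WEEK" else "STUDY_WIDE",
    week_index = pull("week_index", integer(1)),
    beta = pull("beta", numeric(1)),
    variance = pull("variance", numeric(1)),
    n_games = pull("n_games", integer(1))
  )
  out[order(out$subject_id, out$assessment_type, out$week_index), ]
}

#' Weekly beta values as long-format streams
#'
#' Reshapes a [weekly_betas()] table into the long weekly-stream format
#' (stream names `beta_A` / `beta_B`) so cognition can be correlated with
#' survey and step-count streams via [weekly_correlations()].
#'
#' @param betas A [weekly_betas()] tibble.
#' @return Long tibble with `subject_id`, `week_index`, `stream`, `value`.
#' @export
betas_to_streams <- function(betas) {
  wk <- betas[betas$window == "WEEK", ]
  tibble(
    subject_id = wk$subject_id,
    week_index = wk$week_index,
    stream = ifelse(wk$assessment_type == "JEWELS_A", "beta_A", "beta_B"),
    value = wk$beta
  )
}

#' Read or write a beta-value table
#'
#' @param betas Beta tibble ([study_betas()] / [weekly_betas()]).
#' @param path CSV path.
#' @export
write_betas <- function(betas, path) {
  write.csv(as.data.frame(betas), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_betas
#' @export
read_betas <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  tibble(
    subject_id = as.character(raw$subject_id),
    assessment_type = raw$assessment_type,
    window = raw$window,
    week_index = as.integer(raw$week_index),
    beta = raw$beta, variance = raw$variance,
    n_games = as.integer(raw$n_games)
  )
}

#' Dump adjustment-model coefficients as YAML
#'
#' @param model An [fit_adjustment()] model.
#' @param path Output path.
#' @export
write_adjustment <- function(model, path) {
  obj <- unclass(model)
  obj$mistake_effects <- as.list(obj$mistake_effects)
  if (!is.null(obj$level_effects)) obj$level_effects <- as.list(obj$level_effects)
  writeLines(yaml::as.yaml(obj), path)
  invisible(path)
}
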