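# Group comparison of beta values and per-subject weekly cross-stream
# correlation matrices.

#' Compare study-wide beta values between groups
#'
#' Two-sided two-sample location test on per-subject study-wide betas:
#' Welch's t-test by default, with a rank-based alternative
#' (`test = "wilcoxon"`) behind a flag.
#'
#' @param betas_control,betas_patient Numeric vectors of per-subject betas
#'   (at least 2 per group).
#' @param test `"welch"` or `"wilcoxon"`.
#' @param assessment_type Optional label carried into the result.
#' @return A `group_comparison`: list with `assessment_type`, `mean_control`,
#'   `mean_patient`, `statistic`, `p_value`, `n_control`, `n_patient`,
#'   `test`.
#' @export
#' @examples
#' compare_groups(rnorm(17, -1.9, 1), rnorm(18, -1.9, 1))
compare_groups <- function(betas_control, betas_patient,
                           test = c("welch", "wilcoxon"),
                           assessment_type = NA_character_) {
  test <- match.arg(test)
  betas_control <- betas_control[is.finite(betas_control)]
  betas_patient <- betas_patient[is.finite(betas_patient)]
  if (length(betas_control) < 2 || length(betas_patient) < 2) {
    stop("each group needs at least 2 beta values")
  }
  if (test == "welch") {
    ht <- tryCatch(t.test(betas_control, betas_patient),
                   error = function(e) NULL)
    if (is.null(ht)) {  # both groups constant: degenerate but well-defined
      same <- isTRUE(all.equal(mean(betas_control), mean(betas_patient)))
      ht <- list(statistic = c(t = if (same) 0 else Inf),
                 p.value = if (same) 1 else 0)
    }
  } else {
    ht <- suppressWarnings(wilcox.test(betas_control, betas_patient))
  }
  structure(list(
    assessment_type = assessment_type,
    mean_control = mean(betas_control),
    mean_patient = mean(betas_patient),
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n_control = length(betas_control),
    n_patient = length(betas_patient),
    test = test
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison", if (!is.na(x$assessment_type)) paste0("(", x$assessment_type, ")"),
      "\n")
  cat(sprintf("  mean beta: control %.3f (n=%d), patient %.3f (n=%d)\n",
              x$mean_control, x$n_control, x$mean_patient, x$n_patient))
  cat(sprintf("  %s test: statistic %.3f, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  invisible(x)
}

#' Per-subject weekly cross-stream correlation matrix
#'
#' Pairwise correlations across weekly windows between every pair of streams
#' (weekly betas, survey scores, step counts, ...) for one subject, using
#' pairwise-complete weeks. Cells with fewer than `min_overlap` overlapping
#' weeks are reported missing — never zero — and the per-cell overlap count
#' is returned alongside the coefficients.
#'
#' @param streams Long weekly-stream tibble (`subject_id`, `week_index`,
#'   `stream`, `value`), e.g. [simulate_study()]'s streams bound with
#'   [betas_to_streams()].
#' @param subject_id Subject to analyse.
#' @param min_overlap Minimum overlapping weeks per cell (default 3).
#' @param method Correlation coefficient (default `"pearson"`).
#' @return A `weekly_corr`: list with `subject_id`, `r` (correlation matrix,
#'   symmetric, unit diagonal), `n` (per-cell overlap counts).
#' @export
weekly_correlations <- function(streams, subject_id, min_overlap = 3,
                                method = "pearson") {
  s <- streams[streams$subject_id == subject_id & !is.na(streams$value), ]
  if (nrow(s) == 0L) stop("no stream data for subject ", subject_id)
  streams_present <- sort(unique(s$stream))
  weeks <- sort(unique(s$week_index))
  wide <- matrix(NA_real_, length(weeks), length(streams_present),
                 dimnames = list(weeks, streams_present))
  wide[cbind(match(s$week_index, weeks), match(s$stream, streams_present))] <- s$value
  p <- ncol(wide)
  r <- diag(1, p); nmat <- matrix(0L, p, p)
  dimnames(r) <- dimnames(nmat) <- list(streams_present, streams_present)
  diag(nmat) <- colSums(!is.na(wide))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (j <= i) next
    ok <- complete.cases(wide[, c(i, j)])
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    if (sum(ok) >= min_overlap) {
      rij <- suppressWarnings(cor(wide[ok, i], wide[ok, j], method = method))
      r[i, j] <- r[j, i] <- rij
    } else {
      r[i, j] <- r[j, i] <- NA_real_
    }
  }
  structure(list(subject_id = subject_id, r = r, n = nmat,
                 method = method, min_overlap = min_overlap),
            class = "weekly_corr")
}

#' @export
print.weekly_corr <- function(x, ...) {
  cat("Weekly cross-stream correlations for subject ", x$subject_id,
      " (", x$method, ", min overlap ", x$min_overlap, " weeks)\n", sep = "")
  print(round(x$r, 3))
  invisible(x)
}

#' @export
plot.weekly_corr <- function(x, ...) {
  p <- ncol(x$r)
  z <- x$r[, p:1, drop = FALSE]
  graphics::image(seq_len(p), seq_len(p), z, zlim = c(-1, 1),
                  col = grDevices::hcl.colors(41, "Blue-Red 3", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = paste("Weekly correlations:", x$subject_id), ...)
  graphics::axis(1, at = seq_len(p), labels = rownames(z), las = 2)
  graphics::axis(2, at = seq_len(p), labels = colnames(z), las = 1)
  invisible(x)
}

#' Write a correlation matrix (and overlap counts) to CSV
#'
#' @param corr A [weekly_correlations()] result.
#' @param path Output CSV path; overlap counts go to `<path>` with suffix
#'   `_n` before the extension.
#' @export
write_correlations <- function(corr, path) {
  write.csv(as.data.frame(corr$r), path, row.names = TRUE, quote = FALSE)
  npath <- sub("(\\.[^.]*)?$", "_n\\1", path)
  write.csv(as.data.frame(corr$n), npath, row.names = TRUE, quote = FALSE)
  invisible(path)
}
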