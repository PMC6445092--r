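#' Per-run performance, cue congruence and confidence
#'
#' Computes the dependent variables for one cued test run.  A trial is
#' *cue-congruent* when the stimulus shown is the one the cue predicts (the
#' scheduled 75% of trials at the default validity).  Percent correct (CR)
#' is computed separately within the cue-congruent and cue-incongruent
#' subsets, and the cue congruence index is their difference,
#' `CCI = CR_CC - CR_CI`.  A CCI of 0 means the cue had no influence on
#' responses; responding with the cue's predicted stimulus on every trial
#' gives the upper bound of 100.
#'
#' For continuous responses in `[-1, 1]` (sign = choice, magnitude =
#' confidence), correctness is sign match and mean confidence is the mean
#' absolute response.
#'
#' @param trials Data frame of trial records for a single run, with columns
#'   `cue`, `true_stimulus`, `decision`/`correct`, optionally
#'   `response_value`.
#' @return An object of class `run_metrics`: list with `performance` (0-100),
#'   `cci` (-100..100), `cr_cc`, `cr_ci`, `mean_confidence` (or `NA`),
#'   `n_trials`, `n_cue_congruent_trials`, `n_cue_incongruent_trials`.
#' @examples
#' trials <- data.frame(cue = rep(c(0, 1), each = 8),
#'                      true_stimulus = rep(c(0, 1), each = 8),
#'                      correct = rep(c(1, 0), times = 8))
#' run_metrics(trials)
#' @export
run_metrics <- function(trials) {
  need <- c("cue", "true_stimulus")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  correct <- trial_correctness(trials)
  congruent <- trials$cue == trials$true_stimulus
  n_cc <- sum(congruent)
  n_ci <- sum(!congruent)
  if (n_cc == 0L || n_ci == 0L) {
    stop("CCI undefined: run has no cue-",
         if (n_cc == 0L) "congruent" else "incongruent", " trials",
         call. = FALSE)
  }
  cr_cc <- 100 * mean(correct[congruent])
  cr_ci <- 100 * mean(correct[!congruent])
  conf <- NA_real_
  if (!is.null(trials$response_value) && !all(is.na(trials$response_value))) {
    conf <- mean(abs(trials$response_value))
  }
  structure(list(
    performance = 100 * mean(correct),
    cci = cr_cc - cr_ci,
    cr_cc = cr_cc, cr_ci = cr_ci,
    mean_confidence = conf,
    n_trials = nrow(trials),
    n_cue_congruent_trials = n_cc,
    n_cue_incongruent_trials = n_ci
  ), class = "run_metrics")
}

# correctness per trial: stored column, or binary decision match, or sign
# match for continuous responses
trial_correctness <- function(trials) {
  if (!is.null(trials$correct)) return(as.numeric(trials$correct))
  if (!is.null(trials$response_value) &&
      !all(is.na(trials$response_value))) {
    chosen <- as.integer(trials$response_value > 0)
    return(as.numeric(chosen == trials$true_stimulus))
  }
  if (!is.null(trials$decision)) {
    return(as.numeric(trials$decision == trials$true_stimulus))
  }
  stop("trial table needs a correct, decision or response_value column",
       call. = FALSE)
}

#' @export
print.run_metrics <- function(x, ...) {
  cat(sprintf(
    "<run_metrics> performance=%.2f%% CCI=%.2f (CR_CC=%.2f, CR_CI=%.2f), n=%d\n",
    x$performance, x$cci, x$cr_cc, x$cr_ci, x$n_trials))
  invisible(x)
}

#' Metric table for a cohort trial log
#'
#' Computes [run_metrics()] for every subject x session x test run of a
#' trial log, returning one row per cell.  Intervention-run rows of the log
#' are ignored except that `mean_confidence` can optionally be computed for
#' them too (`include_intervention = TRUE`), which the confidence analysis
#' uses.
#'
#' @param trials Cohort trial-log data frame (columns as written by
#'   [simulate_cohort()] / [generate_behavior_cohort()]).
#' @param include_intervention Also emit rows for intervention runs
#'   (performance and confidence only; CCI is `NA` for uncued runs).
#' @return Data frame with columns `subject_id`, `session_feedback`,
#'   `run_index`, `time` (test-run number 1..n), `run_type`, `performance`,
#'   `cci`, `cr_cc`, `cr_ci`, `mean_confidence`, `n_trials`.
#' @export
cohort_metrics <- function(trials, include_intervention = FALSE) {
  need <- c("subject_id", "session_feedback", "run_index", "run_type",
            "cue", "true_stimulus")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- if (include_intervention) rep(TRUE, nrow(trials)) else
    trials$run_type == "test"
  tl <- trials[keep, , drop = FALSE]
  key <- interaction(tl$subject_id, tl$session_feedback, tl$run_index,
                     drop = TRUE, lex.order = TRUE)
  pieces <- split(seq_len(nrow(tl)), key)
  rows <- lapply(pieces, function(idx) {
    chunk <- tl[idx, , drop = FALSE]
    is_test <- chunk$run_type[1L] == "test"
    conf <- NA_real_
    if (!is.null(chunk$response_value) &&
        !all(is.na(chunk$response_value))) {
      conf <- mean(abs(chunk$response_value))
    }
    if (is_test) {
      m <- run_metrics(chunk)
      data.frame(subject_id = chunk$subject_id[1L],
                 session_feedback = chunk$session_feedback[1L],
                 run_index = chunk$run_index[1L],
                 run_type = "test",
                 performance = m$performance, cci = m$cci,
                 cr_cc = m$cr_cc, cr_ci = m$cr_ci,
                 mean_confidence = m$mean_confidence,
                 n_trials = m$n_trials, stringsAsFactors = FALSE)
    } else {
      correct <- trial_correctness(chunk)
      data.frame(subject_id = chunk$subject_id[1L],
                 session_feedback = chunk$session_feedback[1L],
                 run_index = chunk$run_index[1L],
                 run_type = "intervention",
                 performance = 100 * mean(correct), cci = NA_real_,
                 cr_cc = NA_real_, cr_ci = NA_real_,
                 mean_confidence = conf,
                 n_trials = nrow(chunk), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$subject_id, out$session_feedback, out$run_index), ]
  # test-run number within session (time 1..n_test_runs)
  out$time <- NA_integer_
  is_test <- out$run_type == "test"
  key2 <- paste(out$subject_id, out$session_feedback)
  out$time[is_test] <- stats::ave(rep(1L, sum(is_test)), key2[is_test],
                                  FUN = cumsum)
  rownames(out) <- NULL
  out[, c("subject_id", "session_feedback", "run_index", "time", "run_type",
          "performance", "cci", "cr_cc", "cr_ci", "mean_confidence",
          "n_trials")]
}

#' Ordinary least-squares slope across test runs
#'
#' Fits a linear function of metric value against test-run number
#' (1, 2, ..., n) and returns its slope, in metric units per run.
#'
#' @param values Numeric vector of per-run metric values in run order.
#' @return Scalar OLS slope.
#' @export
ols_slope <- function(values) {
  n <- length(values)
  if (n < 2L || anyNA(values)) {
    stop("need >= 2 non-missing per-run values in run order", call. = FALSE)
  }
  x <- seq_len(n)
  sum((x - mean(x)) * (values - mean(values))) / sum((x - mean(x))^2)
}

#' Session-wise slopes of the dependent variables
#'
#' @param metrics Metric rows for one subject x session (test runs only),
#'   in run order, as produced by [cohort_metrics()].
#' @param n_test_runs Expected number of test runs.
#' @return List with `performance_slope`, `cci_slope`, `confidence_slope`
#'   (`NA` when no confidence is available), class `session_slopes`.
#' @export
session_slopes <- function(metrics, n_test_runs = 4L) {
  if (nrow(metrics) != n_test_runs) {
    stop("expected exactly ", n_test_runs, " test-run metric rows, got ",
         nrow(metrics), call. = FALSE)
  }
  metrics <- metrics[order(metrics$time), , drop = FALSE]
  conf <- metrics$mean_confidence
  structure(list(
    performance_slope = ols_slope(metrics$performance),
    cci_slope = ols_slope(metrics$cci),
    confidence_slope = if (all(is.na(conf))) NA_real_ else ols_slope(conf)
  ), class = "session_slopes")
}

#' Per-subject session slopes for a cohort
#'
#' @param metrics A [cohort_metrics()] table (test-run rows are used).
#' @return Data frame with one row per subject x session and columns
#'   `subject_id`, `session_feedback`, `performance_slope`, `cci_slope`,
#'   `confidence_slope`.
#' @export
cohort_slopes <- function(metrics) {
  tm <- metrics[metrics$run_type == "test", , drop = FALSE]
  key <- interaction(tm$subject_id, tm$session_feedback, drop = TRUE,
                     lex.order = TRUE)
  pieces <- split(seq_len(nrow(tm)), key)
  rows <- lapply(pieces, function(idx) {
    chunk <- tm[idx, , drop = FALSE]
    s <- session_slopes(chunk, n_test_runs = nrow(chunk))
    data.frame(subject_id = chunk$subject_id[1L],
               session_feedback = chunk$session_feedback[1L],
               performance_slope = s$performance_slope,
               cci_slope = s$cci_slope,
               confidence_slope = s$confidence_slope,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feedback-type by time linear-contrast interaction
#'
#' Tests whether the linear change of a dependent variable across the test
#' runs differs between the corrupted and uncorrupted sessions.  Per subject
#' and session a linear contrast score `L = sum(w_t * y_t)` is formed with
#' weights `(-3, -1, 1, 3)`; a paired t-test of `L_corrupted -
#' L_uncorrupted` across subjects gives `F = t^2` with df `(1, n - 1)` and
#' partial eta squared `F / (F + n - 1)`.  This equals the linear-trend
#' interaction contrast of the two-way repeated-measures ANOVA for a 2 x 4
#' within-subject design.
#'
#' @param metrics A [cohort_metrics()] table; every subject must have both
#'   sessions with all test runs.
#' @param variable Which dependent variable to contrast.
#' @param weights Linear contrast weights, one per test run.  Scaling them
#'   by a positive constant does not change F, p or partial eta squared.
#' @return An object of class `contrast_result`: list with `F`, `df1`,
#'   `df2`, `p`, `partial_eta_sq`, `t`, `mean_contrast_diff`, `n_subjects`.
#' @export
linear_interaction_test <- function(metrics,
                                    variable = c("performance", "cci",
                                                 "mean_confidence"),
                                    weights = c(-3, -1, 1, 3)) {
  variable <- match.arg(variable)
  tm <- metrics[metrics$run_type == "test", , drop = FALSE]
  ntr <- length(weights)
  L <- contrast_scores(tm, variable, weights)
  if (is.null(L)) {
    stop("every subject needs both sessions with all ", ntr, " test runs",
         call. = FALSE)
  }
  d <- L$corrupted - L$uncorrupted
  n <- length(d)
  se <- stats::sd(d) / sqrt(n)
  tv <- if (se == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else mean(d) / se
  Fv <- tv^2
  df2 <- n - 1L
  structure(list(
    F = Fv, df1 = 1L, df2 = df2,
    p = stats::pf(Fv, 1, df2, lower.tail = FALSE),
    partial_eta_sq = if (is.infinite(Fv)) 1 else Fv / (Fv + df2),
    t = tv,
    mean_contrast_diff = mean(d),
    n_subjects = n
  ), class = "contrast_result")
}

# per-subject contrast scores for both sessions; NULL if unbalanced
contrast_scores <- function(tm, variable, weights) {
  ntr <- length(weights)
  subj <- sort(unique(tm$subject_id))
  out <- list(corrupted = numeric(length(subj)),
              uncorrupted = numeric(length(subj)))
  for (fb in names(out)) {
    sub <- tm[tm$session_feedback == fb, , drop = FALSE]
    sub <- sub[order(sub$subject_id, sub$time), , drop = FALSE]
    if (nrow(sub) != length(subj) * ntr ||
        !identical(sort(unique(sub$subject_id)), subj)) {
      return(NULL)
    }
    y <- matrix(sub[[variable]], nrow = ntr)
    if (anyNA(y)) return(NULL)
    out[[fb]] <- drop(crossprod(y, weights))
  }
  out
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "Linear fbtype x time interaction: F(%d,%d) = %.3f, p = %.3g, partial eta^2 = %.3f\n",
    x$df1, x$df2, x$F, x$p, x$partial_eta_sq))
  invisible(x)
}

#' One-sample t-test of session-wise slopes
#'
#' @param slopes Numeric vector of per-subject slopes for one session type.
#' @return Object of class `slope_test`: list with `mean_slope`,
#'   `standard_error`, `t`, `df`, `p`, `n`.
#' @export
slope_t_test <- function(slopes) {
  slopes <- slopes[!is.na(slopes)]
  n <- length(slopes)
  if (n < 2L) stop("need at least 2 slopes", call. = FALSE)
  m <- mean(slopes)
  se <- stats::sd(slopes) / sqrt(n)
  tv <- if (se == 0) 0 else m / se
  structure(list(
    mean_slope = m, standard_error = se, t = tv, df = n - 1L,
    p = if (se == 0 && m == 0) 1 else
      2 * stats::pt(abs(tv), n - 1L, lower.tail = FALSE),
    n = n
  ), class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("slope: M = %.3f, SE = %.3f, t(%d) = %.3f, p = %.3g\n",
              x$mean_slope, x$standard_error, x$df, x$t, x$p))
  invisible(x)
}

#' Paired test of confidence in test vs intervention runs
#'
#' For datasets with continuous responses, computes per subject the mean
#' confidence over intervention runs minus the mean over test runs within
#' one session type (negative values = confidence drops during the
#' intervention), and runs a paired t-test across subjects.
#'
#' @param metrics A [cohort_metrics()] table computed with
#'   `include_intervention = TRUE`.
#' @param feedback Session type to analyse.
#' @return Object of class `slope_test` (mean difference, SE, t, df, p).
#' @export
confidence_intervention_test <- function(metrics,
                                         feedback = c("corrupted",
                                                      "uncorrupted")) {
  feedback <- match.arg(feedback)
  m <- metrics[metrics$session_feedback == feedback, , drop = FALSE]
  if (all(is.na(m$mean_confidence))) {
    stop("no confidence data: dataset has binary responses", call. = FALSE)
  }
  subj <- sort(unique(m$subject_id))
  diffs <- vapply(subj, function(s) {
    sm <- m[m$subject_id == s, , drop = FALSE]
    ct <- sm$mean_confidence[sm$run_type == "test"]
    ci <- sm$mean_confidence[sm$run_type == "intervention"]
    if (!length(ci) || !length(ct)) return(NA_real_)
    mean(ci) - mean(ct)
  }, numeric(1))
  if (anyNA(diffs)) {
    stop("both run types with confidence are required per subject",
         call. = FALSE)
  }
  res <- slope_t_test(diffs)
  names(res)[names(res) == "mean_slope"] <- "mean_slope"
  res
}

#' Full cohort analysis
#'
#' Convenience wrapper running the whole pipeline on a cohort trial log:
#' per-run metrics, per-subject session slopes, slope t-tests per session
#' type, and the fbtype x time linear-contrast interaction for performance
#' and CCI (and confidence when available).
#'
#' @param trials Cohort trial-log data frame.
#' @return List with elements `metrics`, `slopes`, `slope_tests` (nested by
#'   variable and session type), `interactions` (by variable), and
#'   `run_means` (cohort mean of each variable per session x run).
#' @export
analyze_cohort <- function(trials) {
  metrics <- cohort_metrics(trials,
                            include_intervention =
                              "response_value" %in% names(trials))
  slopes <- cohort_slopes(metrics)
  vars <- c(performance = "performance_slope", cci = "cci_slope")
  slope_tests <- list()
  for (v in names(vars)) {
    slope_tests[[v]] <- lapply(
      stats::setNames(nm = c("corrupted", "uncorrupted")),
      function(fb) slope_t_test(
        slopes[[vars[[v]]]][slopes$session_feedback == fb]))
  }
  interactions <- list(
    performance = linear_interaction_test(metrics, "performance"),
    cci = linear_interaction_test(metrics, "cci")
  )
  tm <- metrics[metrics$run_type == "test", , drop = FALSE]
  run_means <- stats::aggregate(
    tm[, c("performance", "cci", "mean_confidence")],
    by = list(session_feedback = tm$session_feedback, time = tm$time),
    FUN = mean)
  list(metrics = metrics, slopes = slopes, slope_tests = slope_tests,
       interactions = interactions, run_means = run_means)
}
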