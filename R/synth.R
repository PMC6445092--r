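#' Configuration for the synthetic behavioural-data generator
#'
#' The generator produces human-like trial-level datasets with the session /
#' run structure of the behavioural experiments (two sessions per subject,
#' four cued test runs interleaved with three uncued intervention runs) and
#' configurable effect sizes, so the analysis pipeline can be validated by
#' parameter recovery without any human data.  Effects enter directly
#' through the per-run correct-response rates in cue-congruent and
#' cue-incongruent trials, not through a latent observer, which keeps the
#' generator an independent route from the observer simulation.
#'
#' Defaults correspond to the first experiment's printed group statistics:
#' 34 subjects, ~80% baseline accuracy (the staircase target), performance
#' slopes -3.05 (corrupted) and -0.05 (uncorrupted) percent/run, CCI slopes
#' 2.76 and -0.41 points/run.  Between-subject slope dispersion defaults
#' reproduce the printed standard errors (0.66 and 1.14 at n = 34).
#'
#' @param n_subjects Number of subjects.
#' @param response_mode `"binary"` (choice only) or `"continuous"` (signed
#'   response in `[-1, 1]` encoding choice and confidence).
#' @param baseline_performance Percent correct in test run 1.
#' @param performance_slope_corrupted,performance_slope_uncorrupted
#'   Performance change, percent per run.
#' @param cci_baseline CCI in test run 1, points.
#' @param cci_slope_corrupted,cci_slope_uncorrupted CCI change, points/run.
#' @param subject_perf_slope_sd,subject_cci_slope_sd Between-subject SD of
#'   the subject-level true slopes (percent/run, points/run).
#' @param run_noise_sd Extra run-level Gaussian noise on the performance
#'   target, percent.
#' @param cue_validity Scheduled cue-stimulus contingency in test runs.
#' @param trials_per_test_run,trials_per_intervention_run Trials per run
#'   (even).
#' @param n_test_runs,n_intervention_runs Run counts (alternating design).
#' @param intervention_performance Percent correct governing uncued
#'   intervention-run responses.
#' @param confidence_mean_test,confidence_mean_intervention Mean confidence
#'   (continuous mode) in test and intervention runs of the corrupted
#'   session; the uncorrupted session uses `confidence_mean_test` minus
#'   `confidence_uncorrupted_drop` in interventions.
#' @param confidence_uncorrupted_drop Intervention-run confidence drop in
#'   the uncorrupted session.
#' @param confidence_concentration Concentration (a + b) of the Beta
#'   distribution from which confidence magnitudes are drawn before
#'   rescaling to `[0.03, 1]`.
#' @return An object of class `behavior_config`.
#' @export
behavior_config <- function(n_subjects = 34L,
                            response_mode = c("binary", "continuous"),
                            baseline_performance = 80,
                            performance_slope_corrupted = -3.05,
                            performance_slope_uncorrupted = -0.05,
                            cci_baseline = 5,
                            cci_slope_corrupted = 2.76,
                            cci_slope_uncorrupted = -0.41,
                            subject_perf_slope_sd = 3.5,
                            subject_cci_slope_sd = 6,
                            run_noise_sd = 2,
                            cue_validity = 0.75,
                            trials_per_test_run = 64L,
                            trials_per_intervention_run = 128L,
                            n_test_runs = 4L, n_intervention_runs = 3L,
                            intervention_performance = 80,
                            confidence_mean_test = 0.51,
                            confidence_mean_intervention = 0.35,
                            confidence_uncorrupted_drop = 0.06,
                            confidence_concentration = 8) {
  response_mode <- match.arg(response_mode)
  cfg <- list(
    n_subjects = as.integer(n_subjects), response_mode = response_mode,
    baseline_performance = baseline_performance,
    performance_slope_corrupted = performance_slope_corrupted,
    performance_slope_uncorrupted = performance_slope_uncorrupted,
    cci_baseline = cci_baseline,
    cci_slope_corrupted = cci_slope_corrupted,
    cci_slope_uncorrupted = cci_slope_uncorrupted,
    subject_perf_slope_sd = subject_perf_slope_sd,
    subject_cci_slope_sd = subject_cci_slope_sd,
    run_noise_sd = run_noise_sd,
    cue_validity = cue_validity,
    trials_per_test_run = as.integer(trials_per_test_run),
    trials_per_intervention_run = as.integer(trials_per_intervention_run),
    n_test_runs = as.integer(n_test_runs),
    n_intervention_runs = as.integer(n_intervention_runs),
    intervention_performance = intervention_performance,
    confidence_mean_test = confidence_mean_test,
    confidence_mean_intervention = confidence_mean_intervention,
    confidence_uncorrupted_drop = confidence_uncorrupted_drop,
    confidence_concentration = confidence_concentration
  )
  stopifnot(cfg$n_subjects >= 1L, cfg$trials_per_test_run %% 2L == 0L,
            cfg$trials_per_intervention_run %% 2L == 0L,
            cfg$n_intervention_runs == cfg$n_test_runs - 1L,
            cfg$cue_validity > 0, cfg$cue_validity < 1)
  # the configured mean trajectories must be feasible response rates
  for (fb in c("corrupted", "uncorrupted")) {
    ps <- if (fb == "corrupted") cfg$performance_slope_corrupted else
      cfg$performance_slope_uncorrupted
    cs <- if (fb == "corrupted") cfg$cci_slope_corrupted else
      cfg$cci_slope_uncorrupted
    for (r in seq_len(cfg$n_test_runs)) {
      cr_targets(cfg$baseline_performance + ps * (r - 1),
                 cfg$cci_baseline + cs * (r - 1), cfg$cue_validity,
                 strict = TRUE,
                 where = sprintf(" in %s session, run %d", fb, r))
    }
  }
  structure(cfg, class = "behavior_config")
}

# derive (p_cc, p_ci) from performance and CCI targets (percent / points)
# under the scheduled contingency v: v*p_cc + (1-v)*p_ci = perf and
# p_cc - p_ci = cci.  Subject-level noise is absorbed by clipping to
# [0.02, 0.98] before trial sampling; infeasibility of the *configured mean
# trajectory* is checked at config time (see behavior_config).
cr_targets <- function(perf, cci, validity, clip = c(0.02, 0.98),
                       strict = FALSE, where = "") {
  p_cc <- (perf + (1 - validity) * cci) / 100
  p_ci <- (perf - validity * cci) / 100
  if (strict && (p_cc < 0 || p_cc > 1 || p_ci < 0 || p_ci > 1)) {
    stop("infeasible performance/CCI target", where,
         sprintf(" (CR_CC = %.1f%%, CR_CI = %.1f%%)", 100 * p_cc,
                 100 * p_ci), call. = FALSE)
  }
  c(cc = min(max(p_cc, clip[1L]), clip[2L]),
    ci = min(max(p_ci, clip[1L]), clip[2L]))
}

# confidence magnitudes: Beta with the given mean and concentration,
# rescaled to [0.03, 1]
draw_confidence <- function(n, mean_conf, concentration) {
  lo <- 0.03
  m <- (mean_conf - lo) / (1 - lo)
  m <- min(max(m, 0.02), 0.98)
  a <- m * concentration
  b <- (1 - m) * concentration
  lo + (1 - lo) * stats::rbeta(n, a, b)
}

#' Generate a synthetic behavioural cohort
#'
#' Draws an analysis-ready trial log for `n_subjects` subjects, each with a
#' corrupted and an uncorrupted session.  For every subject x session x
#' test run, target correct-response rates in cue-congruent and
#' cue-incongruent trials are derived from the configured performance and
#' CCI trajectories (subject-level slopes jitter around the configured means
#' by the configured SDs), trial outcomes are Bernoulli, and the trial
#' schedule realises the cue contingency exactly.  Intervention runs are
#' uncued, at the configured intervention performance.  In continuous mode
#' each trial additionally carries a signed response in `[-1, 1]` whose
#' magnitude (confidence, in `[0.03, 1]`) is Beta-distributed with the
#' configured run-type mean and whose sign encodes the drawn choice.
#'
#' @param config A [behavior_config()].
#' @param seed Integer seed.
#' @return Trial-log data frame with the same schema as
#'   [simulate_cohort()] plus `response_value` in continuous mode.
#' @export
generate_behavior_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "behavior_config"))
  set.seed(seed)
  v <- config$cue_validity
  continuous <- config$response_mode == "continuous"
  logs <- list()
  k <- 0L
  for (i in seq_len(config$n_subjects)) {
    for (fb in c("corrupted", "uncorrupted")) {
      pslope <- stats::rnorm(1,
        if (fb == "corrupted") config$performance_slope_corrupted else
          config$performance_slope_uncorrupted,
        config$subject_perf_slope_sd)
      cslope <- stats::rnorm(1,
        if (fb == "corrupted") config$cci_slope_corrupted else
          config$cci_slope_uncorrupted,
        config$subject_cci_slope_sd)
      conf_test <- config$confidence_mean_test
      conf_intv <- if (fb == "corrupted") config$confidence_mean_intervention
        else config$confidence_mean_test - config$confidence_uncorrupted_drop
      run_index <- 0L
      for (r in seq_len(config$n_test_runs)) {
        run_index <- run_index + 1L
        perf_r <- config$baseline_performance + pslope * (r - 1) +
          stats::rnorm(1, 0, config$run_noise_sd)
        cci_r <- config$cci_baseline + cslope * (r - 1)
        p <- cr_targets(perf_r, cci_r, v)
        sched <- cue_schedule(config$trials_per_test_run, v)
        pr <- ifelse(sched$congruent, p[["cc"]], p[["ci"]])
        correct <- stats::rbinom(length(pr), 1L, pr)
        decision <- ifelse(correct == 1L, sched$stimulus,
                           1L - sched$stimulus)
        tr <- empty_trial_log(config$trials_per_test_run)
        tr$run_index <- run_index
        tr$run_type <- "test"
        tr$cue <- sched$cue
        tr$cuevote <- sched$cue
        tr$true_stimulus <- sched$stimulus
        tr$feedback_label <- sched$stimulus
        tr$sensvote <- NA_real_
        tr$prediction <- NA_real_
        tr$decision <- as.integer(decision)
        tr$correct <- as.integer(correct)
        tr$cue_congruent <- as.integer(decision == sched$cue)
        if (continuous) {
          conf <- draw_confidence(nrow(tr), conf_test,
                                  config$confidence_concentration)
          tr$response_value <- (2 * tr$decision - 1) * conf
        }
        k <- k + 1L
        tr$subject_id <- i
        tr$session_feedback <- fb
        logs[[k]] <- tr
        if (r < config$n_test_runs) {
          run_index <- run_index + 1L
          nt <- config$trials_per_intervention_run
          stim <- balanced_stimuli(nt)
          corr <- stats::rbinom(nt, 1L, config$intervention_performance / 100)
          dec <- ifelse(corr == 1L, stim, 1L - stim)
          ti <- empty_trial_log(nt)
          ti$run_index <- run_index
          ti$run_type <- "intervention"
          ti$cue <- NA_integer_
          ti$cuevote <- NA_integer_
          ti$true_stimulus <- stim
          ti$feedback_label <- if (fb == "corrupted")
            corruption_schedule(stim, 0.5) else stim
          ti$sensvote <- NA_real_
          ti$prediction <- NA_real_
          ti$decision <- as.integer(dec)
          ti$correct <- as.integer(corr)
          ti$cue_congruent <- NA_integer_
          if (continuous) {
            conf <- draw_confidence(nt, conf_intv,
                                    config$confidence_concentration)
            ti$response_value <- (2 * ti$decision - 1) * conf
          }
          k <- k + 1L
          ti$subject_id <- i
          ti$session_feedback <- fb
          logs[[k]] <- ti
        }
      }
    }
  }
  out <- do.call(rbind, logs)
  rownames(out) <- NULL
  out
}
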