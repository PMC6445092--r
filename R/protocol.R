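#' Simulation configuration
#'
#' Collects the parameters of the artificial-observer experiment: the two
#' stimulus-evidence distributions, trial-batch size, pre-training amount,
#' run structure, cue validity, and the corrupted-feedback fraction.
#'
#' Defaults are the study conditions of the simulated experiment: evidence
#' classes N(0, 4) ("target absent") and N(0.5, 4) ("target present"), 40
#' evidence samples per trial, pre-training with 20 stimulus presentations
#' per class (each presentation contributing a full trial batch of
#' `samples_per_trial` draws), four 64-trial cued test runs interleaved with
#' three 128-trial uncued intervention runs, 75% cue validity, and exact
#' half mislabelling per stimulus type in corrupted intervention runs.
#'
#' @param mean_absent,mean_present Means of the evidence distributions N0
#'   and N1.
#' @param variance Common variance of the evidence distributions.
#' @param samples_per_trial Evidence samples collected per trial.
#' @param pretrain_trials Pre-training stimulus presentations per class.
#' @param pretrain_samples_per_trial Draws contributed by each pre-training
#'   presentation; defaults to `samples_per_trial`.
#' @param n_test_runs,n_intervention_runs Run counts; the session alternates
#'   test and intervention runs starting and ending with a test run, so
#'   `n_intervention_runs` must equal `n_test_runs - 1`.
#' @param trials_per_test_run,trials_per_intervention_run Trials per run;
#'   both must be even so stimulus balance and exact half-mislabelling are
#'   realisable.
#' @param cue_validity Probability that the cue's associated stimulus is the
#'   one presented (scheduled exactly per run).
#' @param corrupted_fraction Fraction of trials of each stimulus type whose
#'   feedback label is flipped in corrupted intervention runs.
#' @param n_subjects Number of artificial subjects in a cohort.
#' @param prior Initial `ng_belief` hyperparameters before pre-training, as
#'   a named list; the default is a weakly informative symmetric prior
#'   located at the midpoint of the class means.
#' @param cumulative_fit Logical; if `TRUE`, decision weights in test run r
#'   are fitted on the pooled trials of test runs 1..r instead of run r
#'   alone.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(mean_absent = 0, mean_present = 0.5, variance = 4,
                       samples_per_trial = 40L,
                       pretrain_trials = 20L,
                       pretrain_samples_per_trial = samples_per_trial,
                       n_test_runs = 4L, n_intervention_runs = 3L,
                       trials_per_test_run = 64L,
                       trials_per_intervention_run = 128L,
                       cue_validity = 0.75, corrupted_fraction = 0.5,
                       n_subjects = 1000L,
                       prior = list(mu = (mean_absent + mean_present) / 2,
                                    kappa = 0.1, alpha = 1, beta = 1),
                       cumulative_fit = FALSE) {
  cfg <- list(
    mean_absent = mean_absent, mean_present = mean_present,
    variance = variance,
    samples_per_trial = as.integer(samples_per_trial),
    pretrain_trials = as.integer(pretrain_trials),
    pretrain_samples_per_trial = as.integer(pretrain_samples_per_trial),
    n_test_runs = as.integer(n_test_runs),
    n_intervention_runs = as.integer(n_intervention_runs),
    trials_per_test_run = as.integer(trials_per_test_run),
    trials_per_intervention_run = as.integer(trials_per_intervention_run),
    cue_validity = cue_validity, corrupted_fraction = corrupted_fraction,
    n_subjects = as.integer(n_subjects), prior = prior,
    cumulative_fit = isTRUE(cumulative_fit)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$variance > 0, cfg$samples_per_trial >= 1L,
            cfg$pretrain_trials >= 0L,
            cfg$n_test_runs >= 1L,
            cfg$trials_per_test_run >= 2L,
            cfg$trials_per_intervention_run >= 2L,
            cfg$n_subjects >= 1L)
  if (cfg$n_intervention_runs != cfg$n_test_runs - 1L) {
    stop("n_intervention_runs must equal n_test_runs - 1 ",
         "(alternating test/intervention structure)", call. = FALSE)
  }
  if (cfg$cue_validity < 0 || cfg$cue_validity > 1 ||
      cfg$corrupted_fraction < 0 || cfg$corrupted_fraction > 1) {
    stop("cue_validity and corrupted_fraction must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$trials_per_test_run %% 2L != 0L ||
      cfg$trials_per_intervention_run %% 2L != 0L) {
    stop("per-run trial counts must be even", call. = FALSE)
  }
  invisible(cfg)
}

#' Pre-train the sensory classifier
#'
#' Updates the "absent" belief with `pretrain_trials` correctly labelled
#' evidence batches from N(mean_absent, variance) and the "present" belief
#' likewise from N(mean_present, variance), starting from the configured
#' prior.  With `pretrain_trials = 0` the classifier equals the prior.
#'
#' @param config A [sim_config()].
#' @return A [sensory_classifier()].
#' @export
pretrain <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  prior <- ng_from_list(config$prior)
  d0 <- d1 <- prior
  sdv <- sqrt(config$variance)
  n <- config$pretrain_samples_per_trial
  for (i in seq_len(config$pretrain_trials)) {
    d0 <- update_belief(d0, stats::rnorm(n, config$mean_absent, sdv))
    d1 <- update_belief(d1, stats::rnorm(n, config$mean_present, sdv))
  }
  sensory_classifier(d0, d1)
}

# balanced stimulus schedule of length nt (even), shuffled
balanced_stimuli <- function(nt) {
  sample(rep(c(0L, 1L), each = nt %/% 2L))
}

# exact cue/stimulus contingency: for each stimulus type, round(validity *
# nt/2) trials get the congruent cue; order shuffled jointly with stimuli
cue_schedule <- function(nt, validity) {
  half <- nt %/% 2L
  ncc <- round(validity * half)
  stim <- rep(c(0L, 1L), each = half)
  congruent <- rep(rep(c(TRUE, FALSE), c(ncc, half - ncc)), 2L)
  ord <- sample(nt)
  stim <- stim[ord]
  congruent <- congruent[ord]
  cue <- ifelse(congruent, stim, 1L - stim)
  list(stimulus = stim, cue = as.integer(cue), congruent = congruent)
}

# feedback-label schedule: flip `fraction` of each stimulus type exactly
corruption_schedule <- function(stimulus, fraction) {
  label <- stimulus
  if (fraction > 0) {
    for (s in c(0L, 1L)) {
      idx <- which(stimulus == s)
      nflip <- round(fraction * length(idx))
      flip <- if (nflip > 0L) sample(idx, nflip) else integer(0)
      label[flip] <- 1L - s
    }
  }
  label
}

# draw an evidence matrix (samples_per_trial x n_trials) given per-trial
# class means
draw_batches <- function(stimulus, config) {
  mu <- ifelse(stimulus == 1L, config$mean_present, config$mean_absent)
  m <- config$samples_per_trial
  matrix(stats::rnorm(m * length(stimulus), mean = rep(mu, each = m),
                      sd = sqrt(config$variance)), nrow = m)
}

empty_trial_log <- function(n) {
  data.frame(
    subject_id = integer(n), session_feedback = character(n),
    run_index = integer(n), run_type = character(n),
    cue = integer(n), true_stimulus = integer(n),
    feedback_label = integer(n), sensvote = numeric(n),
    cuevote = integer(n), prediction = numeric(n), decision = integer(n),
    correct = integer(n), cue_congruent = integer(n),
    stringsAsFactors = FALSE
  )
}

#' Simulate one intervention run
#'
#' Uncued run delivering (possibly corrupted) feedback.  Per trial the
#' observer draws an evidence batch from the true stimulus distribution,
#' records the sensory vote and a cue-free decision (`sensvote >= 0`), and
#' then updates the belief named by the feedback label with that batch.  In
#' corrupted mode the label schedule mislabels exactly
#' `corrupted_fraction` of the trials of each stimulus type, in
#' pseudo-random order.
#'
#' @param classifier A [sensory_classifier()].
#' @param config A [sim_config()].
#' @param corrupted Logical: corrupted or uncorrupted feedback.
#' @return List with `classifier` (updated) and `trials` (data frame, one
#'   row per trial with the standard trial-log columns).
#' @export
run_intervention <- function(classifier, config, corrupted) {
  stopifnot(inherits(classifier, "sensory_classifier"),
            inherits(config, "sim_config"))
  nt <- config$trials_per_intervention_run
  stim <- balanced_stimuli(nt)
  label <- corruption_schedule(stim,
                               if (corrupted) config$corrupted_fraction else 0)
  batches <- draw_batches(stim, config)
  sv <- numeric(nt)
  d0 <- classifier$absent
  d1 <- classifier$present
  for (t in seq_len(nt)) {
    x <- batches[, t]
    sv[t] <- sum(ng_predictive_logpdf(d1, x)) -
      sum(ng_predictive_logpdf(d0, x))
    if (label[t] == 1L) d1 <- update_belief(d1, x) else
      d0 <- update_belief(d0, x)
  }
  decision <- as.integer(sv >= 0)
  trials <- empty_trial_log(nt)
  trials$run_type <- "intervention"
  trials$cue <- NA_integer_
  trials$cuevote <- NA_integer_
  trials$prediction <- NA_real_
  trials$cue_congruent <- NA_integer_
  trials$true_stimulus <- stim
  trials$feedback_label <- label
  trials$sensvote <- sv
  trials$decision <- decision
  trials$correct <- as.integer(decision == stim)
  list(classifier = sensory_classifier(d0, d1), trials = trials)
}

#' Simulate one test run
#'
#' Cued run with uncorrupted feedback and no belief updating.  The stimulus
#' schedule realises the cue validity exactly; sensory votes are computed
#' under the (frozen) classifier; logistic decision weights are fitted on
#' this run's (sensvote, cuevote, true label) triples and applied to every
#' trial.
#'
#' @inheritParams run_intervention
#' @param prior_trials Optional data frame of earlier test-run trials used
#'   when `config$cumulative_fit` is `TRUE`.
#' @return Data frame of trial records; the classifier is not modified.
#' @export
run_test <- function(classifier, config, prior_trials = NULL) {
  stopifnot(inherits(classifier, "sensory_classifier"),
            inherits(config, "sim_config"))
  nt <- config$trials_per_test_run
  sched <- cue_schedule(nt, config$cue_validity)
  batches <- draw_batches(sched$stimulus, config)
  sv <- sensory_vote_matrix(classifier, batches)
  fit_sv <- sv
  fit_cue <- sched$cue
  fit_lab <- sched$stimulus
  if (isTRUE(config$cumulative_fit) && !is.null(prior_trials) &&
      nrow(prior_trials) > 0L) {
    fit_sv <- c(prior_trials$sensvote, fit_sv)
    fit_cue <- c(prior_trials$cuevote, fit_cue)
    fit_lab <- c(prior_trials$true_stimulus, fit_lab)
  }
  w <- fit_decision_weights(fit_sv, fit_cue, fit_lab)
  d <- decide(w, sv, sched$cue)
  trials <- empty_trial_log(nt)
  trials$run_type <- "test"
  trials$cue <- sched$cue
  trials$true_stimulus <- sched$stimulus
  trials$feedback_label <- sched$stimulus   # uncorrupted feedback in tests
  trials$sensvote <- sv
  trials$cuevote <- sched$cue
  trials$prediction <- d$prediction
  trials$decision <- d$decision
  trials$correct <- as.integer(d$decision == sched$stimulus)
  trials$cue_congruent <- as.integer(d$decision == sched$cue)
  trials
}

#' Simulate one artificial subject's session
#'
#' Runs pre-training followed by the alternating sequence T1, I1, T2, I2,
#' T3, I3, T4 (for the default four test runs), with the given feedback
#' mode in all intervention runs.
#'
#' @param config A [sim_config()].
#' @param feedback `"corrupted"` or `"uncorrupted"`.
#' @param seed Integer seed for this subject-session's random stream.
#' @param subject_id Identifier stored in the trial log.
#' @return Data frame of trial records tagged by run index and type.
#' @export
simulate_subject <- function(config, feedback = c("corrupted", "uncorrupted"),
                             seed = NULL, subject_id = 1L) {
  feedback <- match.arg(feedback)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  classifier <- pretrain(config)
  corrupted <- feedback == "corrupted"
  logs <- vector("list", config$n_test_runs + config$n_intervention_runs)
  test_hist <- NULL
  run_index <- 0L
  for (r in seq_len(config$n_test_runs)) {
    run_index <- run_index + 1L
    tt <- run_test(classifier, config, prior_trials = test_hist)
    tt$run_index <- run_index
    logs[[run_index]] <- tt
    if (isTRUE(config$cumulative_fit)) {
      test_hist <- if (is.null(test_hist)) tt else rbind(test_hist, tt)
    }
    if (r < config$n_test_runs) {
      run_index <- run_index + 1L
      iv <- run_intervention(classifier, config, corrupted)
      classifier <- iv$classifier
      iv$trials$run_index <- run_index
      logs[[run_index]] <- iv$trials
    }
  }
  out <- do.call(rbind, logs)
  out$subject_id <- subject_id
  out$session_feedback <- feedback
  rownames(out) <- NULL
  out
}

#' Simulate a paired cohort
#'
#' Simulates each subject under both feedback conditions (the within-subject
#' design), with deterministic per-subject, per-condition random substreams
#' derived from the master seed.
#'
#' @param config A [sim_config()].
#' @param seed Master integer seed.
#' @param progress Logical; print a dot every 50 subjects.
#' @return Data frame of trial records for all subjects and both sessions.
#' @export
simulate_cohort <- function(config, seed = 1L, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"), config$n_subjects >= 1L)
  n <- config$n_subjects
  set.seed(seed)
  substreams <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n),
                       nrow = n, ncol = 2L)
  logs <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    for (j in 1:2) {
      fb <- c("corrupted", "uncorrupted")[j]
      k <- k + 1L
      logs[[k]] <- simulate_subject(config, fb, seed = substreams[i, j],
                                    subject_id = i)
    }
    if (progress && i %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  out <- do.call(rbind, logs)
  rownames(out) <- NULL
  out
}
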