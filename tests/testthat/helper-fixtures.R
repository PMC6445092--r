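# shared fixtures, built in code

# a single test run with exact 75/25 contingency where responses are fully
# determined by `respond`: "cue" (always follow the cue's predicted
# stimulus) or "stimulus" (always respond correctly)
toy_test_run <- function(respond = c("cue", "stimulus"), nt = 64,
                         validity = 0.75, seed = 42) {
  respond <- match.arg(respond)
  set.seed(seed)
  half <- nt %/% 2
  ncc <- round(validity * half)
  stim <- rep(c(0L, 1L), each = half)
  congruent <- rep(rep(c(TRUE, FALSE), c(ncc, half - ncc)), 2)
  ord <- sample(nt)
  stim <- stim[ord]; congruent <- congruent[ord]
  cue <- ifelse(congruent, stim, 1L - stim)
  decision <- if (respond == "cue") cue else stim
  data.frame(subject_id = 1L, session_feedback = "uncorrupted",
             run_index = 1L, run_type = "test",
             cue = as.integer(cue), true_stimulus = stim,
             feedback_label = stim, sensvote = 0,
             cuevote = as.integer(cue), prediction = 0.5,
             decision = as.integer(decision),
             correct = as.integer(decision == stim),
             cue_congruent = as.integer(decision == cue))
}

# metric table for a paired cohort built directly at the metric level:
# per-session mean trajectories plus i.i.d. Gaussian run noise
metric_cohort <- function(n, base = 80, slope_corr = 0, slope_unc = 0,
                          noise_sd = 2, n_runs = 4, cci_base = 10) {
  rows <- expand.grid(time = seq_len(n_runs),
                      session_feedback = c("corrupted", "uncorrupted"),
                      subject_id = seq_len(n), stringsAsFactors = FALSE)
  slope <- ifelse(rows$session_feedback == "corrupted", slope_corr,
                  slope_unc)
  rows$run_index <- rows$time * 2L - 1L
  rows$run_type <- "test"
  rows$performance <- base + slope * (rows$time - 1) +
    stats::rnorm(nrow(rows), 0, noise_sd)
  rows$cci <- cci_base + stats::rnorm(nrow(rows), 0, noise_sd)
  rows$cr_cc <- NA_real_
  rows$cr_ci <- NA_real_
  rows$mean_confidence <- NA_real_
  rows$n_trials <- 64L
  rows[, c("subject_id", "session_feedback", "run_index", "time",
           "run_type", "performance", "cci", "cr_cc", "cr_ci",
           "mean_confidence", "n_trials")]
}

# tiny simulation config for fast protocol tests
small_sim_config <- function(...) {
  sim_config(n_subjects = 2L, trials_per_test_run = 16L,
             trials_per_intervention_run = 16L, pretrain_trials = 5L, ...)
}
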