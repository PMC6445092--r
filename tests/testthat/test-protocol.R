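test_that("pretraining is deterministic and yields above-chance accuracy", {
  cfg <- sim_config(n_subjects = 1L)
  set.seed(1); c1 <- pretrain(cfg)
  set.seed(1); c2 <- pretrain(cfg)
  expect_identical(c1, c2)

  # no pretraining: classifier equals the prior
  cfg0 <- sim_config(pretrain_trials = 0L)
  cls0 <- pretrain(cfg0)
  expect_equal(unclass(cls0$absent), unclass(ng_from_list(cfg0$prior)))

  # sign-of-sensvote accuracy on fresh batches: imperfect but clearly
  # above chance (design point ~78.5%)
  set.seed(2)
  cls <- pretrain(cfg)
  nb <- 500
  acc <- 0
  for (i in seq_len(nb)) {
    stim <- i %% 2L
    mu <- if (stim == 1L) cfg$mean_present else cfg$mean_absent
    sv <- sensory_vote(cls, rnorm(cfg$samples_per_trial, mu, 2))
    acc <- acc + as.integer((sv >= 0) == (stim == 1L))
  }
  expect_gt(acc / nb, 0.6)
  expect_lt(acc / nb, 0.9)
})

test_that("intervention runs balance stimuli and mislabel exactly half", {
  cfg <- sim_config()
  set.seed(3)
  cls <- pretrain(cfg)
  iv <- run_intervention(cls, cfg, corrupted = TRUE)
  tr <- iv$trials
  expect_equal(nrow(tr), cfg$trials_per_intervention_run)
  expect_equal(sum(tr$true_stimulus == 0), sum(tr$true_stimulus == 1))
  for (s in 0:1) {
    idx <- tr$true_stimulus == s
    expect_equal(sum(tr$feedback_label[idx] != s), sum(idx) / 2)
  }
  expect_true(all(is.na(tr$cue)))
  # cue-free decisions are the sign of the sensory vote
  expect_equal(tr$decision, as.integer(tr$sensvote >= 0))

  # uncorrupted: labels match the stimulus everywhere
  iu <- run_intervention(cls, cfg, corrupted = FALSE)
  expect_true(all(iu$trials$feedback_label == iu$trials$true_stimulus))

  # corrupted_fraction = 0 makes the corrupted schedule an identity
  cfg0 <- sim_config(corrupted_fraction = 0)
  i0 <- run_intervention(cls, cfg0, corrupted = TRUE)
  expect_true(all(i0$trials$feedback_label == i0$trials$true_stimulus))

  expect_error(sim_config(trials_per_intervention_run = 127L), "even")
})

test_that("test runs schedule the cue validity exactly and leak no state", {
  cfg <- sim_config()
  set.seed(4)
  cls <- pretrain(cfg)
  before <- ng_to_list(cls$absent)
  before1 <- ng_to_list(cls$present)
  tr <- run_test(cls, cfg)
  expect_identical(ng_to_list(cls$absent), before)
  expect_identical(ng_to_list(cls$present), before1)

  expect_equal(mean(tr$cue == tr$true_stimulus), cfg$cue_validity)
  expect_equal(sum(tr$true_stimulus == 0), sum(tr$true_stimulus == 1))
  expect_true(all(tr$prediction > 0 & tr$prediction < 1))
  expect_equal(tr$decision, as.integer(tr$prediction >= 0.5))
  expect_equal(tr$cue_congruent, as.integer(tr$decision == tr$cue))
})

test_that("an uninformative cue gets near-zero weight and centred CCI", {
  cfg <- sim_config(cue_validity = 0.5, trials_per_test_run = 64L)
  set.seed(6)
  cls <- pretrain(cfg)
  ccis <- vapply(1:40, function(i) run_metrics(run_test(cls, cfg))$cci,
                 numeric(1))
  expect_lt(abs(mean(ccis)), 10)
})

test_that("a fully corrupted classifier follows the cue", {
  # identical beliefs: sensvote is exactly 0; the fitted weights recover
  # the cue contingency and every decision follows the cue
  cfg <- sim_config()
  b <- ng_belief(0.25, 3000, 1500, 6000)
  cls <- sensory_classifier(b, b)
  set.seed(8)
  tr <- run_test(cls, cfg)
  m <- run_metrics(tr)
  expect_true(all(tr$sensvote == 0))
  expect_gte(mean(tr$decision == tr$cue), 0.99)
  expect_gte(m$cci, 99)
})

test_that("a subject session has the alternating run structure, reproducibly", {
  cfg <- small_sim_config()
  log1 <- simulate_subject(cfg, "corrupted", seed = 99, subject_id = 7L)
  log2 <- simulate_subject(cfg, "corrupted", seed = 99, subject_id = 7L)
  expect_identical(log1, log2)

  seq_types <- vapply(split(log1$run_type, log1$run_index),
                      function(z) z[[1]], character(1))
  expect_equal(unname(seq_types),
               c("test", "intervention", "test", "intervention", "test",
                 "intervention", "test"))
  expect_equal(sum(seq_types == "test"), cfg$n_test_runs)
  expect_equal(sum(seq_types == "intervention"), cfg$n_intervention_runs)
  expect_true(all(log1$subject_id == 7L))
  expect_true(all(log1$session_feedback == "corrupted"))
})

test_that("corrupted interventions pull the class beliefs together", {
  cfg <- sim_config()
  gaps <- vapply(1:25, function(i) {
    set.seed(1000 + i)
    cls <- pretrain(cfg)
    gap0 <- abs(predictive_moments(cls$present)$mean -
                  predictive_moments(cls$absent)$mean)
    for (r in 1:3) cls <- run_intervention(cls, cfg, corrupted = TRUE)$classifier
    gap1 <- abs(predictive_moments(cls$present)$mean -
                  predictive_moments(cls$absent)$mean)
    gap1 / gap0
  }, numeric(1))
  expect_lt(mean(gaps), 0.5)
})

test_that("a paired cohort covers both sessions per subject", {
  cfg <- small_sim_config()
  tr <- simulate_cohort(cfg, seed = 5)
  expect_setequal(unique(tr$subject_id), 1:2)
  expect_setequal(unique(tr$session_feedback),
                  c("corrupted", "uncorrupted"))
  counts <- table(tr$subject_id, tr$session_feedback)
  expect_true(all(counts == 4 * 16 + 3 * 16))

  # reproducible end to end
  tr2 <- simulate_cohort(cfg, seed = 5)
  expect_identical(tr, tr2)
})

test_that("cumulative decision-weight fitting is available and distinct", {
  cfg_run <- small_sim_config(cumulative_fit = TRUE)
  cfg_per <- small_sim_config()
  lc <- simulate_subject(cfg_run, "uncorrupted", seed = 31)
  lp <- simulate_subject(cfg_per, "uncorrupted", seed = 31)
  expect_equal(nrow(lc), nrow(lp))
  # same random stream: identical trials, but different fitted predictions
  # from run 2 onward
  t1 <- lc$run_index == 1
  expect_identical(lc$sensvote[t1], lp$sensvote[t1])
  later <- lc$run_type == "test" & lc$run_index > 1
  expect_false(identical(lc$prediction[later], lp$prediction[later]))
})
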