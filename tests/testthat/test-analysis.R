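test_that("run metrics implement the CCI definition exactly", {
  # hand-enumerated toy run: 8 congruent trials with 6 correct, 8
  # incongruent with 4 correct
  tr <- data.frame(
    cue = rep(c(1, 0), each = 8),
    true_stimulus = c(rep(1, 8), rep(1, 8)),
    correct = c(rep(1, 6), 0, 0, rep(1, 4), rep(0, 4))
  )
  m <- run_metrics(tr)
  expect_equal(m$performance, 62.5)
  expect_equal(m$cr_cc, 75)
  expect_equal(m$cr_ci, 50)
  expect_equal(m$cci, 25)
  expect_equal(m$n_cue_congruent_trials, 8)
  expect_equal(m$n_cue_incongruent_trials, 8)
  # identity CCI = CR_CC - CR_CI holds exactly
  expect_identical(m$cci, m$cr_cc - m$cr_ci)
})

test_that("CCI anchors: pure cue-following gives 100, pure accuracy gives 0", {
  m_cue <- run_metrics(toy_test_run("cue"))
  expect_identical(m_cue$cci, 100)
  expect_identical(m_cue$cr_cc, 100)
  expect_identical(m_cue$cr_ci, 0)

  m_acc <- run_metrics(toy_test_run("stimulus"))
  expect_identical(m_acc$cci, 0)
  expect_identical(m_acc$performance, 100)
})

test_that("CCI is undefined without both cue classes, and is shift-invariant", {
  tr <- toy_test_run("cue")
  expect_error(run_metrics(tr[tr$cue == tr$true_stimulus, ]),
               "incongruent")
  expect_error(run_metrics(tr[tr$cue != tr$true_stimulus, ]),
               "congruent")

  # adding equal numbers of correct responses to both cue classes leaves
  # CCI unchanged while shifting raw performance
  base <- data.frame(cue = rep(c(1, 0), c(12, 4)),
                     true_stimulus = rep(1, 16),
                     correct = c(rep(1, 6), rep(0, 6), rep(1, 1), rep(0, 3)))
  extra <- data.frame(cue = c(1, 0), true_stimulus = c(1, 1),
                      correct = c(1, 1))
  m0 <- run_metrics(base)
  m1 <- run_metrics(rbind(base, extra, extra))
  delta_cc <- m1$cr_cc - m0$cr_cc
  delta_ci <- m1$cr_ci - m0$cr_ci
  expect_gt(m1$performance, m0$performance)
  expect_equal(m1$cci, m1$cr_cc - m1$cr_ci)
  # raw cue-congruent-choice rate moves with performance; the CR-based
  # index only moves via the differential term
  expect_equal(m1$cci - m0$cci, delta_cc - delta_ci)
})

test_that("session slopes are ordinary least squares across runs", {
  expect_equal(ols_slope(c(80, 80, 80, 80)), 0)
  expect_equal(ols_slope(c(86, 84, 82, 80)), -2)
  expect_equal(ols_slope(c(0, 5, 10, 15)), 5)
  expect_error(ols_slope(c(80, NA, 80, 80)), "non-missing")

  m <- metric_cohort(1, base = 86, slope_corr = -2, slope_unc = 0,
                     noise_sd = 0)
  s <- session_slopes(m[m$session_feedback == "corrupted", ])
  expect_equal(s$performance_slope, -2)
  expect_error(session_slopes(m[1:3, ]), "expected exactly")
})

test_that("slope t-test matches hand computation", {
  r <- slope_t_test(c(-1, -2, -3))
  expect_equal(r$mean_slope, -2)
  expect_equal(r$standard_error, 0.5774, tolerance = 1e-4)
  expect_equal(r$t, -3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2)

  r0 <- slope_t_test(c(0, 0, 0, 0))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_error(slope_t_test(1), "at least 2")
})

test_that("the linear interaction test is exact on degenerate input", {
  set.seed(14)
  m <- metric_cohort(10, slope_corr = -1, slope_unc = -1, noise_sd = 0)
  # identical trajectories in both sessions: zero contrast difference
  r <- linear_interaction_test(m, "performance")
  expect_equal(r$F, 0)
  expect_equal(r$partial_eta_sq, 0)
  expect_equal(r$df1, 1L)
  expect_equal(r$df2, 9L)
})

test_that("interaction F equals an independent repeated-measures decomposition", {
  set.seed(15)
  m <- metric_cohort(5, slope_corr = -1.5, slope_unc = 0.2, noise_sd = 3)
  ours <- linear_interaction_test(m, "performance")

  # independent route: per-cell linear contrast scores, then R's own
  # within-subject ANOVA decomposition of the fbtype effect on the scores
  w <- c(-3, -1, 1, 3)
  m <- m[order(m$subject_id, m$session_feedback, m$time), ]
  scores <- aggregate(performance ~ subject_id + session_feedback, m,
                      function(y) sum(w * y))
  fit <- stats::aov(performance ~ session_feedback +
                      Error(factor(subject_id) / session_feedback),
                    data = scores)
  tab <- summary(fit)[["Error: factor(subject_id):session_feedback"]][[1]]
  F_aov <- tab["session_feedback", "F value"]
  expect_equal(ours$F, F_aov, tolerance = 1e-8)
  expect_equal(ours$p, tab["session_feedback", "Pr(>F)"], tolerance = 1e-8)
  # partial eta squared consistency with its defining identity
  expect_equal(ours$partial_eta_sq,
               ours$F / (ours$F + ours$df2), tolerance = 1e-12)
  expect_equal(ours$F, ours$t^2, tolerance = 1e-10)
})

test_that("contrast weights are scale-invariant", {
  set.seed(16)
  m <- metric_cohort(20, slope_corr = -1, slope_unc = 0, noise_sd = 2)
  r1 <- linear_interaction_test(m, "performance", weights = c(-3, -1, 1, 3))
  r2 <- linear_interaction_test(m, "performance",
                                weights = 0.25 * c(-3, -1, 1, 3))
  expect_equal(r1$F, r2$F, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
  expect_equal(r1$partial_eta_sq, r2$partial_eta_sq, tolerance = 1e-10)
})

test_that("the interaction test detects a planted fbtype-by-time effect", {
  set.seed(17)
  hits <- vapply(1:200, function(i) {
    m <- metric_cohort(200, slope_corr = -1, slope_unc = 0, noise_sd = 2)
    linear_interaction_test(m, "performance")$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("unpaired or incomplete tables are rejected", {
  set.seed(18)
  m <- metric_cohort(6)
  expect_error(linear_interaction_test(m[-1, ], "performance"),
               "both sessions")
})

test_that("confidence analysis recovers the intervention drop", {
  cfgc <- behavior_config(n_subjects = 32L, response_mode = "continuous")
  tr <- generate_behavior_cohort(cfgc, seed = 19)
  m <- cohort_metrics(tr, include_intervention = TRUE)
  corr <- confidence_intervention_test(m, "corrupted")
  expect_lt(abs(corr$mean_slope - (0.35 - 0.51)), 0.03)
  expect_lt(corr$p, 0.001)

  # no drop configured: difference near zero
  cfg0 <- behavior_config(n_subjects = 32L, response_mode = "continuous",
                          confidence_mean_intervention = 0.51,
                          confidence_uncorrupted_drop = 0)
  tr0 <- generate_behavior_cohort(cfg0, seed = 20)
  m0 <- cohort_metrics(tr0, include_intervention = TRUE)
  r0 <- confidence_intervention_test(m0, "corrupted")
  expect_lt(abs(r0$mean_slope), 0.02)

  # binary data has no confidence
  trb <- generate_behavior_cohort(behavior_config(n_subjects = 4L),
                                  seed = 21)
  mb <- cohort_metrics(trb, include_intervention = TRUE)
  expect_error(confidence_intervention_test(mb, "corrupted"),
               "binary")
})
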