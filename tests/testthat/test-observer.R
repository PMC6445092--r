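test_that("sensory vote is a log-likelihood ratio with its symmetries", {
  b <- ng_belief(0.2, 2, 3, 4)
  same <- sensory_classifier(b, b)
  set.seed(5)
  for (i in 1:5) {
    expect_equal(sensory_vote(same, rnorm(40)), 0)
  }
  d0 <- ng_belief(0, 5, 4, 9)
  d1 <- ng_belief(0.5, 5, 4, 9)
  cls <- sensory_classifier(d0, d1)
  swapped <- sensory_classifier(d1, d0)
  x <- rnorm(40, 0.5, 2)
  expect_equal(sensory_vote(cls, x), -sensory_vote(swapped, x))
})

test_that("a well-trained classifier votes for the generating class", {
  set.seed(21)
  d0 <- update_belief(ng_belief(0.25, 0.1, 1, 1), rnorm(10000, 0, 2))
  d1 <- update_belief(ng_belief(0.25, 0.1, 1, 1), rnorm(10000, 0.5, 2))
  cls <- sensory_classifier(d0, d1)
  votes <- vapply(1:1000, function(i)
    sensory_vote(cls, rnorm(40, 0.5, 2)), numeric(1))
  expect_gte(mean(votes > 0), 0.75)
})

test_that("mislabelled training drives the class beliefs together", {
  # equal mixture of both classes into each belief: predictive means
  # approach each other in expectation, shrinking |sensvote|
  set.seed(77)
  one_path <- function() {
    prior <- ng_belief(0.25, 0.1, 1, 1)
    d0 <- update_belief(prior, rnorm(800, 0, 2))
    d1 <- update_belief(prior, rnorm(800, 0.5, 2))
    gaps <- abs(predictive_moments(d1)$mean - predictive_moments(d0)$mean)
    for (block in 1:4) {
      d0 <- update_belief(d0, c(rnorm(400, 0, 2), rnorm(400, 0.5, 2)))
      d1 <- update_belief(d1, c(rnorm(400, 0, 2), rnorm(400, 0.5, 2)))
      gaps <- c(gaps, abs(predictive_moments(d1)$mean -
                            predictive_moments(d0)$mean))
    }
    gaps
  }
  mean_gaps <- rowMeans(replicate(20, one_path()))
  expect_true(all(diff(mean_gaps) < 0))
  expect_lt(mean_gaps[length(mean_gaps)], 0.3 * mean_gaps[1])
})

test_that("decision-weight fitting recovers generating coefficients", {
  set.seed(9)
  n <- 10000
  sv <- rnorm(n, 0, 2)
  cue <- rbinom(n, 1, 0.5)
  p <- plogis(0 + 1 * sv + 2 * cue)
  y <- rbinom(n, 1, p)
  w <- fit_decision_weights(sv, cue, y)
  expect_lt(abs(w$beta_s - 1) / 1, 0.1)
  expect_lt(abs(w$beta_c - 2) / 2, 0.1)
  expect_lt(abs(w$intercept_c), 0.15)

  # agrees with the unpenalised ML fit on non-separable data
  g <- glm(y ~ sv + cue, family = binomial())
  expect_equal(w$intercept_c, unname(coef(g)[1]), tolerance = 1e-3)
  expect_equal(w$beta_s, unname(coef(g)[2]), tolerance = 1e-3)
  expect_equal(w$beta_c, unname(coef(g)[3]), tolerance = 1e-3)

  # flipping the labels negates every coefficient
  wf <- fit_decision_weights(sv, cue, 1 - y)
  expect_equal(wf$intercept_c, -w$intercept_c, tolerance = 1e-6)
  expect_equal(wf$beta_s, -w$beta_s, tolerance = 1e-6)
  expect_equal(wf$beta_c, -w$beta_c, tolerance = 1e-6)
})

test_that("an uninformative cue receives (near) zero weight", {
  set.seed(13)
  n <- 4000
  y <- rbinom(n, 1, 0.5)
  sv <- ifelse(y == 1, 1, -1) + rnorm(n, 0, 0.1)  # strongly informative
  cue <- rbinom(n, 1, 0.5)                        # independent of label
  w <- fit_decision_weights(sv, cue, y)
  expect_lt(abs(w$beta_c), abs(w$beta_s) / 10)
})

test_that("separable designs yield finite capped coefficients", {
  sv <- c(-2, -1, -0.5, 0.5, 1, 2)
  y <- c(0, 0, 0, 1, 1, 1)
  cue <- c(0, 1, 0, 1, 0, 1)
  w <- fit_decision_weights(sv, cue, y)
  expect_true(all(is.finite(c(w$intercept_c, w$beta_s, w$beta_c))))
})

test_that("degenerate designs are rejected with clear errors", {
  expect_error(fit_decision_weights(1:5, rep(0, 5), rep(1, 5)),
               "degenerate")
  expect_error(fit_decision_weights(1:4, rep(0, 3), c(0, 1, 0)),
               "equal length")
  expect_error(fit_decision_weights(1, 0, 1), "at least 3")
})

test_that("the decision rule thresholds the logistic prediction at 0.5", {
  w <- structure(list(intercept_c = 0, beta_s = 1, beta_c = -1),
                 class = "decision_weights")
  # zero linear predictor: prediction exactly 0.5, assigned to category 1
  d <- decide(w, 1, 1)
  expect_equal(d$prediction, 0.5)
  expect_identical(d$decision, 1L)

  # strictly increasing in sensvote for beta_s > 0
  sv <- seq(-3, 3, length.out = 25)
  preds <- decide(w, sv, 0)$prediction
  expect_true(all(diff(preds) > 0))
  expect_true(all(preds > 0 & preds < 1))

  # point symmetry of the logistic around 0.5
  expect_equal(decide(w, 1.3, 0)$prediction +
                 decide(w, -1.3, 0)$prediction, 1)
})
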