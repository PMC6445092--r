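#' Sensory classifier: paired class beliefs
#'
#' The observer's sensory classifier holds two independent normal-gamma
#' beliefs, one for the "target absent" class (D0) and one for the "target
#' present" class (D1).  The two beliefs share no state and are updated
#' independently.
#'
#' @param belief_absent,belief_present [ng_belief()] objects for classes 0
#'   and 1.
#' @return An object of class `sensory_classifier`.
#' @export
sensory_classifier <- function(belief_absent, belief_present) {
  stopifnot(inherits(belief_absent, "ng_belief"),
            inherits(belief_present, "ng_belief"))
  structure(list(absent = belief_absent, present = belief_present),
            class = "sensory_classifier")
}

#' @export
print.sensory_classifier <- function(x, ...) {
  cat("<sensory_classifier>\n  D0 (absent):  ")
  print(x$absent)
  cat("  D1 (present): ")
  print(x$present)
  invisible(x)
}

#' Sensory vote: predictive log-likelihood ratio
#'
#' `sensvote = ln p(X | D1) - ln p(X | D0)`: how much more likely the trial's
#' evidence batch is under the "target present" belief than under the
#' "target absent" belief, in nats.  Antisymmetric under swapping the two
#' beliefs.
#'
#' @param classifier A [sensory_classifier()].
#' @param samples Numeric vector, one trial's evidence batch.
#' @return Scalar log-likelihood ratio in nats.
#' @export
sensory_vote <- function(classifier, samples) {
  stopifnot(inherits(classifier, "sensory_classifier"))
  predictive_log_likelihood(classifier$present, samples) -
    predictive_log_likelihood(classifier$absent, samples)
}

# vectorised sensvote for a matrix of batches (samples in rows, trials in
# columns) under fixed beliefs; used by the protocol simulator.
sensory_vote_matrix <- function(classifier, batches) {
  lp1 <- ng_predictive_logpdf(classifier$present, batches)
  lp0 <- ng_predictive_logpdf(classifier$absent, batches)
  .colSums(lp1 - lp0, nrow(batches), ncol(batches))
}

#' Fit logistic decision weights
#'
#' Maximum-likelihood logistic regression of the true stimulus category on
#' the sensory vote and the cue vote, with intercept.  A small L2 (ridge)
#' penalty on the two slopes (`lambda`, default 1e-4) keeps the coefficients
#' finite when the design is separable, which can happen on short runs; at
#' this penalty the fit is indistinguishable from plain maximum likelihood
#' on non-separable data.
#'
#' @param sensvotes Numeric vector of sensory votes.
#' @param cuevotes Vector of cue votes in `{0, 1}`.
#' @param true_labels Vector of true stimulus categories in `{0, 1}`; both
#'   values must be present.
#' @param lambda Ridge penalty on the slope coefficients.
#' @return An object of class `decision_weights` with fields `intercept_c`,
#'   `beta_s`, `beta_c`.
#' @export
fit_decision_weights <- function(sensvotes, cuevotes, true_labels,
                                 lambda = 1e-4) {
  n <- length(true_labels)
  if (length(sensvotes) != n || length(cuevotes) != n) {
    stop("sensvotes, cuevotes and true_labels must have equal length",
         call. = FALSE)
  }
  if (n < 3L) stop("need at least 3 trials to fit decision weights",
                   call. = FALSE)
  if (!all(true_labels %in% c(0, 1)) || !all(cuevotes %in% c(0, 1))) {
    stop("cuevotes and true_labels must be coded 0/1", call. = FALSE)
  }
  if (length(unique(true_labels)) < 2L) {
    stop("degenerate design: only one label value present", call. = FALSE)
  }
  X <- cbind(1, sensvotes, cuevotes)
  beta <- ridge_logistic(X, as.numeric(true_labels),
                         penalty = c(0, lambda, lambda))
  structure(list(intercept_c = beta[[1L]], beta_s = beta[[2L]],
                 beta_c = beta[[3L]]),
            class = "decision_weights")
}

# Newton-Raphson for the L2-penalised logistic log likelihood; `penalty` is
# a per-coefficient vector (0 leaves the intercept unpenalised).
ridge_logistic <- function(X, y, penalty, tol = 1e-10, maxit = 100L) {
  p <- ncol(X)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(X, y - mu)) - penalty * beta
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X * w, X) + diag(penalty, p)
    step <- solve(H, g)
    # halve the step if it overshoots (rare, near-separable designs)
    f0 <- penalized_logit_nll(X, y, beta, penalty)
    for (h in 0:20) {
      cand <- beta + step / 2^h
      if (penalized_logit_nll(X, y, cand, penalty) <= f0 + 1e-12) break
    }
    beta <- cand
    if (max(abs(step / 2^h)) < tol) break
  }
  beta
}

penalized_logit_nll <- function(X, y, beta, penalty) {
  eta <- drop(X %*% beta)
  # log(1 + exp(eta)) computed stably
  lse <- pmax(eta, 0) + log1p(exp(-abs(eta)))
  -sum(y * eta - lse) + sum(penalty * beta^2) / 2
}

#' @export
print.decision_weights <- function(x, ...) {
  cat(sprintf("<decision_weights> c=%.4g beta_s=%.4g beta_c=%.4g\n",
              x$intercept_c, x$beta_s, x$beta_c))
  invisible(x)
}

#' Decision rule of the decision classifier
#'
#' Computes `prediction = plogis(c + beta_s*sensvote + beta_c*cuevote)` and
#' thresholds it at 0.5; the boundary value 0.5 is assigned to category 1
#' ("target present").
#'
#' @param weights A [fit_decision_weights()] result.
#' @param sensvote Numeric vector of sensory votes.
#' @param cuevote Vector in `{0, 1}` (recycled if scalar).
#' @return List with `prediction` (probabilities in (0, 1)) and `decision`
#'   (integer 0/1).
#' @export
decide <- function(weights, sensvote, cuevote) {
  stopifnot(inherits(weights, "decision_weights"))
  if (!all(is.finite(sensvote))) stop("non-finite sensvote", call. = FALSE)
  pred <- stats::plogis(weights$intercept_c + weights$beta_s * sensvote +
                          weights$beta_c * cuevote)
  list(prediction = pred, decision = as.integer(pred >= 0.5))
}
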