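#' Normal-gamma belief over a stimulus class
#'
#' A normal-gamma distribution is the conjugate prior for a normal
#' distribution with unknown mean and precision.  The observer maintains one
#' such belief per stimulus class; updating it with observed evidence samples
#' yields the conjugate posterior, and the marginal (posterior-predictive)
#' distribution of a new sample is a Student-t.
#'
#' @param mu Location hyperparameter, in stimulus-evidence units.
#' @param kappa Pseudo-count weighting the location; must be > 0.
#' @param alpha Shape hyperparameter; must be > 0.
#' @param beta Rate hyperparameter (squared-evidence units); must be > 0.
#'
#' @return An object of class `ng_belief`: a list with fields `mu`, `kappa`,
#'   `alpha`, `beta`.
#' @examples
#' b <- ng_belief(0, 1, 1, 1)
#' update_belief(b, c(0.2, 0.7))
#' @export
ng_belief <- function(mu = 0, kappa = 1, alpha = 1, beta = 1) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (!(kappa > 0 && alpha > 0 && beta > 0)) {
    stop("kappa, alpha and beta must be strictly positive", call. = FALSE)
  }
  structure(list(mu = mu, kappa = kappa, alpha = alpha, beta = beta),
            class = "ng_belief")
}

#' @export
print.ng_belief <- function(x, ...) {
  m <- predictive_moments(x)
  cat(sprintf(
    "<ng_belief> mu=%.4g kappa=%.4g alpha=%.4g beta=%.4g | predictive mean=%.4g var=%.4g\n",
    x$mu, x$kappa, x$alpha, x$beta, m$mean, m$variance))
  invisible(x)
}

#' Conjugate update of a normal-gamma belief
#'
#' Returns the posterior belief after observing a batch of evidence samples,
#' using the standard batch update: `kappa' = kappa + n`,
#' `alpha' = alpha + n/2`, `mu' = (kappa*mu + n*xbar)/(kappa + n)`,
#' `beta' = beta + SS/2 + kappa*n*(xbar - mu)^2 / (2*(kappa + n))`, where
#' `xbar` is the batch mean and `SS` the within-batch sum of squared
#' deviations.  The update is exchangeable: one batch of n samples is
#' equivalent to n sequential single-sample updates.
#'
#' @param belief An [ng_belief()].
#' @param samples Numeric vector of evidence samples; must be non-empty.
#' @return The posterior `ng_belief`; the input is unchanged.
#' @export
update_belief <- function(belief, samples) {
  stopifnot(inherits(belief, "ng_belief"))
  if (length(samples) == 0L) stop("empty sample batch", call. = FALSE)
  if (!is.numeric(samples) || anyNA(samples)) {
    stop("samples must be numeric and non-missing", call. = FALSE)
  }
  n <- length(samples)
  xbar <- mean(samples)
  ss <- sum((samples - xbar)^2)
  kn <- belief$kappa + n
  ng_belief(
    mu    = (belief$kappa * belief$mu + n * xbar) / kn,
    kappa = kn,
    alpha = belief$alpha + n / 2,
    beta  = belief$beta + ss / 2 +
      belief$kappa * n * (xbar - belief$mu)^2 / (2 * kn)
  )
}

#' Moments of the posterior-predictive Student-t
#'
#' The posterior predictive of a normal-gamma belief is a Student-t with
#' location `mu`, squared scale `beta*(kappa+1)/(alpha*kappa)` and
#' `2*alpha` degrees of freedom.  The variance is finite for `alpha > 1`.
#'
#' @param belief An [ng_belief()].
#' @return List with `mean`, `scale` (Student-t scale), `df`, and `variance`
#'   (`NA` if `alpha <= 1`).
#' @export
predictive_moments <- function(belief) {
  stopifnot(inherits(belief, "ng_belief"))
  s2 <- belief$beta * (belief$kappa + 1) / (belief$alpha * belief$kappa)
  df <- 2 * belief$alpha
  v <- if (df > 2) s2 * df / (df - 2) else NA_real_
  list(mean = belief$mu, scale = sqrt(s2), df = df, variance = v)
}

# log density of the belief's posterior-predictive Student-t at x (vectorised)
ng_predictive_logpdf <- function(belief, x) {
  df <- 2 * belief$alpha
  s <- sqrt(belief$beta * (belief$kappa + 1) / (belief$alpha * belief$kappa))
  stats::dt((x - belief$mu) / s, df = df, log = TRUE) - log(s)
}

#' Predictive log likelihood of a sample batch
#'
#' Sum over the batch of the log density of each sample under the belief's
#' posterior-predictive Student-t (samples are evaluated i.i.d. under the
#' predictive; the belief is not updated between samples).  This is
#' `ln p(X | D)` for a trial's evidence `X` under class belief `D`.
#'
#' @inheritParams update_belief
#' @return Scalar log likelihood in nats.
#' @export
predictive_log_likelihood <- function(belief, samples) {
  stopifnot(inherits(belief, "ng_belief"))
  if (length(samples) == 0L) stop("empty sample batch", call. = FALSE)
  sum(ng_predictive_logpdf(belief, samples))
}

#' Serialise / restore a belief
#'
#' Beliefs serialise to a plain named list (and hence to JSON) of the four
#' hyperparameters, for checkpointing.
#'
#' @param belief An [ng_belief()].
#' @return `ng_to_list()`: a named list; `ng_from_list()`: an `ng_belief`.
#' @export
ng_to_list <- function(belief) {
  stopifnot(inherits(belief, "ng_belief"))
  list(mu = belief$mu, kappa = belief$kappa,
       alpha = belief$alpha, beta = belief$beta)
}

#' @rdname ng_to_list
#' @param x Named list with fields `mu`, `kappa`, `alpha`, `beta`.
#' @export
ng_from_list <- function(x) {
  ng_belief(mu = x$mu, kappa = x$kappa, alpha = x$alpha, beta = x$beta)
}
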