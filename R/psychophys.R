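#' Signal weight from signal threshold
#'
#' `w_s = w_n * s / (100 - s)`: converts a signal level `s` (percent) into
#' the grating weight, given the fixed noise weight.  Monotone increasing in
#' `s`; `s = 50` gives `w_s = w_n`, `s = 0` a pure-noise image.
#'
#' @param s Signal level in percent, `0 <= s < 100`.
#' @param w_n Noise weight, > 0 (default 0.25).
#' @return Signal weight `w_s`.
#' @export
signal_weight <- function(s, w_n = 0.25) {
  if (any(s < 0) || any(s >= 100)) {
    stop("signal percent must satisfy 0 <= s < 100", call. = FALSE)
  }
  if (w_n <= 0) stop("w_n must be positive", call. = FALSE)
  w_n * s / (100 - s)
}

#' Stimulus specification
#'
#' Geometry and weights of the annular grating-in-noise stimulus.  The
#' grating and smoothed-noise images are each scaled to `[-0.5, 0.5]` and
#' combined as `I = 0.5 * (1 + w_s*G + w_n*N)`; pixels outside the annulus
#' sit at the 0.5 background.
#'
#' @param orientation Grating orientation in degrees (+45 = clockwise tilt,
#'   -45 counter-clockwise).
#' @param spatial_frequency Cycles per degree.
#' @param inner_diameter,outer_diameter Annulus diameters in degrees of
#'   visual angle.
#' @param noise_weight Noise weight `w_n`.
#' @param signal_percent Signal level `s` feeding [signal_weight()].
#' @param image_size Image side length in pixels; the outer diameter spans
#'   the image.
#' @param noise_smoothing_sd SD of the Gaussian smoothing kernel applied to
#'   the noise field, in degrees.
#' @param grating_phase Phase of the sinusoid in radians.  The default
#'   (cosine phase) makes the +45 and -45 deg gratings exact mirror images.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(orientation = 45, spatial_frequency = 0.87,
                          inner_diameter = 9.94, outer_diameter = 20.93,
                          noise_weight = 0.25, signal_percent = 12,
                          image_size = 128L, noise_smoothing_sd = 0.4,
                          grating_phase = pi / 2) {
  if (!(inner_diameter > 0 && inner_diameter < outer_diameter)) {
    stop("need 0 < inner_diameter < outer_diameter", call. = FALSE)
  }
  structure(list(
    orientation = orientation, spatial_frequency = spatial_frequency,
    inner_diameter = inner_diameter, outer_diameter = outer_diameter,
    noise_weight = noise_weight, signal_percent = signal_percent,
    image_size = as.integer(image_size),
    noise_smoothing_sd = noise_smoothing_sd,
    grating_phase = grating_phase
  ), class = "stimulus_spec")
}

# separable Gaussian blur via banded convolution matrices (reflecting edges
# are unnecessary: the field is masked to the annulus afterwards)
gaussian_blur <- function(m, sd_px) {
  if (sd_px <= 0) return(m)
  half <- max(1L, ceiling(3 * sd_px))
  k <- stats::dnorm(-half:half, sd = sd_px)
  k <- k / sum(k)
  n <- nrow(m)
  K <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - half - 1L
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1L & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + k[j]
  }
  K <- K / rowSums(K)
  K %*% m %*% t(K)
}

#' Compose an annular grating-in-noise stimulus
#'
#' Builds the composite image `I = 0.5 * (1 + w_s*G + w_n*N)`: `G` an
#' annular sinusoidal grating and `N` a spatially smoothed annular noise
#' field, each rescaled to `[-0.5, 0.5]`, zero outside the annulus (hard
#' edge).  All pixel values lie in
#' `[0.5*(1 - w_s - w_n), 0.5*(1 + w_s + w_n)]`.
#'
#' @param spec A [stimulus_spec()].
#' @param seed Optional seed for the noise field (deterministic image when
#'   given).
#' @return Numeric matrix of size `image_size` x `image_size` in `[0, 1]`.
#' @export
compose_stimulus <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$image_size
  deg_per_px <- spec$outer_diameter / n
  cc <- (seq_len(n) - (n + 1) / 2) * deg_per_px   # centred coordinates, deg
  x <- matrix(cc, n, n, byrow = TRUE)
  y <- matrix(cc, n, n)
  r <- sqrt(x^2 + y^2)
  annulus <- r >= spec$inner_diameter / 2 & r <= spec$outer_diameter / 2
  th <- spec$orientation * pi / 180
  u <- x * cos(th) + y * sin(th)
  G <- 0.5 * sin(2 * pi * spec$spatial_frequency * u + spec$grating_phase)
  G[!annulus] <- 0
  N <- matrix(stats::rnorm(n * n), n, n)
  N <- gaussian_blur(N, spec$noise_smoothing_sd / deg_per_px)
  N <- N / max(abs(N[annulus])) / 2
  N[!annulus] <- 0
  w_s <- signal_weight(spec$signal_percent, spec$noise_weight)
  0.5 * (1 + w_s * G + spec$noise_weight * N)
}

#' Write a stimulus image as PNG
#'
#' @param image Matrix in `[0, 1]` from [compose_stimulus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), target = path)
  invisible(path)
}

#' Two-phase 2-down-1-up staircase
#'
#' Adaptive threshold-estimation procedure: the signal level decreases after
#' two consecutive correct responses and increases after every error, with a
#' step-size-down / step-size-up ratio of 0.5548 in both phases (phase 1:
#' 1% up / 0.5548% down; phase 2: 0.5% up / 0.2774% down).  With this
#' ratio the procedure converges to the signal level where
#' `p_correct^2 = 1/(1 + 0.5548)`, i.e. about 80.2% correct.  A reversal is
#' recorded whenever the direction of change flips; the threshold estimate
#' is the mean signal at the last `threshold_reversals` reversals of
#' phase 2.
#'
#' @param start_signal Initial signal level, percent.
#' @param phase 1 or 2.
#' @param step_up Step size upward (percent); defaults to 1 (phase 1) or
#'   0.5 (phase 2).
#' @param step_ratio Down/up step-size ratio.
#' @param max_trials Trial cap for the phase.
#' @param max_reversals Reversal cap for the phase (8 for phase 1; phase-2
#'   default 6, as in the refined procedure; use 10 for the original one).
#' @param floor_signal Lowest admissible signal level; steps below it are
#'   clipped with a warning.
#' @return An object of class `staircase` (environment-free list state).
#' @export
staircase_init <- function(start_signal = 12, phase = 1L,
                           step_up = if (phase == 1L) 1 else 0.5,
                           step_ratio = 0.5548,
                           max_trials = 80L,
                           max_reversals = if (phase == 1L) 8L else 6L,
                           floor_signal = 0.1) {
  stopifnot(start_signal > 0, phase %in% c(1L, 2L))
  structure(list(
    phase = as.integer(phase), signal = start_signal,
    step_up = step_up, step_down = step_up * step_ratio,
    consecutive_correct = 0L, reversal_signals = numeric(0),
    trial_count = 0L, last_direction = 0L,
    max_trials = as.integer(max_trials),
    max_reversals = as.integer(max_reversals),
    floor_signal = floor_signal,
    trace = data.frame(trial = integer(0), signal = numeric(0),
                       correct = integer(0), reversal = logical(0))
  ), class = "staircase")
}

#' @rdname staircase_init
#' @param state A `staircase` state.
#' @param correct Logical: was the response on the current trial correct?
#' @export
staircase_step <- function(state, correct) {
  stopifnot(inherits(state, "staircase"))
  state$trial_count <- state$trial_count + 1L
  move <- 0
  if (isTRUE(correct)) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= 2L) {
      move <- -state$step_down
      state$consecutive_correct <- 0L
    }
  } else {
    move <- state$step_up
    state$consecutive_correct <- 0L
  }
  reversal <- FALSE
  if (move != 0) {
    direction <- sign(move)
    if (state$last_direction != 0L && direction != state$last_direction) {
      reversal <- TRUE
      state$reversal_signals <- c(state$reversal_signals, state$signal)
    }
    state$last_direction <- direction
    new_signal <- state$signal + move
    if (new_signal < state$floor_signal) {
      warning("signal step clipped at floor", call. = FALSE)
      new_signal <- state$floor_signal
    }
    state$signal <- new_signal
  }
  state$trace <- rbind(state$trace, data.frame(
    trial = state$trial_count, signal = state$signal,
    correct = as.integer(isTRUE(correct)), reversal = reversal))
  state
}

#' @rdname staircase_init
#' @export
staircase_done <- function(state) {
  state$trial_count >= state$max_trials ||
    length(state$reversal_signals) >= state$max_reversals
}

#' Threshold estimate from a finished phase-2 staircase
#'
#' Mean signal at the last `threshold_reversals` recorded reversals.
#'
#' @param state A finished `staircase` state.
#' @param threshold_reversals How many trailing reversals to average.
#' @return Scalar threshold estimate (percent signal).
#' @export
staircase_threshold <- function(state, threshold_reversals = 4L) {
  rs <- state$reversal_signals
  if (length(rs) < threshold_reversals) {
    stop("fewer than ", threshold_reversals, " reversals recorded",
         call. = FALSE)
  }
  mean(utils::tail(rs, threshold_reversals))
}

#' Logistic psychometric function
#'
#' Probability of a correct response at signal level `s` for a simulated
#' observer: chance (0.5) at zero signal rising to 1, with midpoint-of-range
#' `threshold` and spread `width`:
#' `p(s) = 0.5 + 0.5 * plogis((s - threshold) / width)`.
#'
#' @param s Signal level, percent.
#' @param threshold Signal at which p = 0.75.
#' @param width Spread (percent) of the logistic.
#' @return Probability of a correct response.
#' @export
logistic_psychometric <- function(s, threshold = 8, width = 2) {
  0.5 + 0.5 * stats::plogis((s - threshold) / width)
}

#' Run the full two-phase staircase against a simulated observer
#'
#' Phase 1 (coarse steps) runs to 8 reversals or 80 trials; phase 2 starts
#' at phase 1's estimate with halved steps and runs to `phase2_reversals`
#' reversals or 80 trials.  The final threshold is the mean signal at the
#' last 4 reversals of phase 2.
#'
#' @param psychometric Function mapping signal percent to p(correct).
#' @param start_signal Phase-1 starting signal.
#' @param phase2_reversals Reversal cap for phase 2 (6 by default; 10 in
#'   the original procedure).
#' @param seed Optional seed.
#' @return List with `threshold`, `phase1`, `phase2` (final states), and
#'   `p_correct_observed` (fraction correct over phase-2 trials).
#' @export
run_staircase <- function(psychometric = logistic_psychometric,
                          start_signal = 12, phase2_reversals = 6L,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s1 <- staircase_init(start_signal, phase = 1L)
  while (!staircase_done(s1)) {
    correct <- stats::runif(1) < psychometric(s1$signal)
    s1 <- staircase_step(s1, correct)
  }
  start2 <- if (length(s1$reversal_signals) >= 4L) {
    staircase_threshold(s1, 4L)
  } else {
    s1$signal
  }
  s2 <- staircase_init(start2, phase = 2L, max_reversals = phase2_reversals)
  while (!staircase_done(s2)) {
    correct <- stats::runif(1) < psychometric(s2$signal)
    s2 <- staircase_step(s2, correct)
  }
  list(threshold = staircase_threshold(s2, 4L),
       phase1 = s1, phase2 = s2,
       p_correct_observed = mean(s2$trace$correct))
}

#' Equilibrium accuracy of the weighted 2-down-1-up rule
#'
#' The signal level drifts to where two consecutive correct responses are
#' as likely (weighted by step size) as one error:
#' `p^2 * step_down = (1 - p^2) * step_up`; with down/up ratio `r` the
#' stationary point satisfies `p = sqrt(1 / (1 + r))`.
#'
#' @param step_ratio Down/up step-size ratio.
#' @return Targeted probability correct.
#' @export
staircase_target_p <- function(step_ratio = 0.5548) {
  sqrt(1 / (1 + step_ratio))
}
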