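trial_log_columns <- c(
  "subject_id", "session_feedback", "run_index", "run_type", "cue",
  "true_stimulus", "feedback_label", "sensvote", "cuevote", "prediction",
  "decision", "correct", "cue_congruent"
)

#' Read / write trial logs
#'
#' Trial logs are comma-separated UTF-8 CSV files with a header row, one row
#' per trial, and the standard column set (plus `response_value` for
#' continuous-response data).  Reading validates the schema and names any
#' missing columns.
#'
#' @param trials Trial-log data frame.
#' @param path File path.
#' @return `write_trial_log()`: `path`, invisibly.  `read_trial_log()`: the
#'   validated data frame.
#' @export
write_trial_log <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(trial_log_columns, names(trials))
  if (length(miss)) {
    stop("trial log ", path, " is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  trials
}

#' Read / write configuration files
#'
#' Configurations round-trip through YAML (`.yml`/`.yaml`) or JSON
#' (`.json`), chosen by file extension.  The `type` field selects the
#' constructor (`"simulation"` -> [sim_config()], `"behavior"` ->
#' [behavior_config()]); remaining fields are passed through as arguments,
#' and unknown keys raise an error naming them.
#'
#' @param config A `sim_config` or `behavior_config`.
#' @param path File path ending in `.yml`, `.yaml` or `.json`.
#' @return `write_config()`: `path`, invisibly; `read_config()`: the
#'   reconstructed config object.
#' @export
write_config <- function(config, path) {
  type <- if (inherits(config, "sim_config")) "simulation" else
    if (inherits(config, "behavior_config")) "behavior" else
      stop("unsupported config object", call. = FALSE)
  payload <- c(list(type = type), unclass(config))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  payload <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  type <- payload$type %||% "simulation"
  payload$type <- NULL
  ctor <- switch(type,
                 simulation = sim_config,
                 behavior = behavior_config,
                 stop("unknown config type: ", type, call. = FALSE))
  known <- names(formals(ctor))
  unknown <- setdiff(names(payload), known)
  if (length(unknown)) {
    stop("config ", path, " has unknown keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(payload$prior)) payload$prior <- as.list(payload$prior)
  do.call(ctor, payload)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a pipeline stage and write a manifest
#'
#' Executes one named stage -- `simulate` (observer cohort), `synth`
#' (behavioural generator), `analyze` (metrics + tests on a trial-log CSV),
#' `stimulus` (PNG of a composed stimulus) or `staircase-sim` (staircase
#' Monte-Carlo trace) -- writing its outputs and a JSON manifest (config
#' snapshot, master seed, package version, timestamp, output inventory with
#' MD5 checksums) into `out_dir`.  Output CSV/JSON files are reproduced
#' byte-identically when re-run with the same config and seed.
#'
#' @param command Stage name.
#' @param config A config object ([sim_config()], [behavior_config()] or
#'   [stimulus_spec()]), or a path to a config file for the simulate/synth
#'   stages.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for the stage.
#' @param input Input trial-log CSV path (`analyze` stage only).
#' @param n_staircase_runs Number of staircase repetitions
#'   (`staircase-sim`).
#' @return The manifest, invisibly (list).
#' @export
run_pipeline <- function(command = c("simulate", "synth", "analyze",
                                     "stimulus", "staircase-sim"),
                         config = NULL, out_dir = ".", seed = 1L,
                         input = NULL, n_staircase_runs = 100L) {
  command <- match.arg(command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(config)) config <- read_config(config)
  outputs <- character(0)
  results_summary <- NULL

  if (command == "simulate") {
    if (!inherits(config, "sim_config")) {
      stop("simulate needs a sim_config", call. = FALSE)
    }
    trials <- simulate_cohort(config, seed = seed)
    f <- file.path(out_dir, "trials.csv")
    write_trial_log(trials, f)
    outputs <- f
  } else if (command == "synth") {
    if (!inherits(config, "behavior_config")) {
      stop("synth needs a behavior_config", call. = FALSE)
    }
    trials <- generate_behavior_cohort(config, seed = seed)
    f <- file.path(out_dir, "trials.csv")
    write_trial_log(trials, f)
    outputs <- f
  } else if (command == "analyze") {
    if (is.null(input)) stop("analyze needs an input trial-log CSV",
                             call. = FALSE)
    trials <- read_trial_log(input)
    res <- analyze_cohort(trials)
    fj <- file.path(out_dir, "results.json")
    jsonlite::write_json(results_to_list(res), fj, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    fc <- file.path(out_dir, "cohort_stats.csv")
    utils::write.csv(res$run_means, fc, row.names = FALSE, quote = FALSE)
    fm <- file.path(out_dir, "run_metrics.csv")
    utils::write.csv(res$metrics, fm, row.names = FALSE, quote = FALSE)
    outputs <- c(fj, fc, fm)
    results_summary <- results_to_list(res)$interactions
  } else if (command == "stimulus") {
    if (!inherits(config, "stimulus_spec")) config <- stimulus_spec()
    img <- compose_stimulus(config, seed = seed)
    f <- file.path(out_dir, "stimulus.png")
    write_stimulus_png(img, f)
    outputs <- f
  } else if (command == "staircase-sim") {
    set.seed(seed)
    thr <- replicate(n_staircase_runs, run_staircase()$threshold)
    f <- file.path(out_dir, "staircase_thresholds.csv")
    utils::write.csv(data.frame(run = seq_along(thr), threshold = thr), f,
                     row.names = FALSE, quote = FALSE)
    outputs <- f
  }

  manifest <- list(
    command = command,
    seed = seed,
    package_version = as.character(utils::packageVersion("percfb")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = if (!is.null(config)) unclass(config) else NULL,
    outputs = lapply(outputs, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    }),
    results = results_summary
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# flatten analyze_cohort() output to JSON-friendly lists
results_to_list <- function(res) {
  list(
    slope_tests = lapply(res$slope_tests, function(v)
      lapply(v, unclass)),
    interactions = lapply(res$interactions, unclass),
    run_means = res$run_means
  )
}

#' Cohort trajectory figure
#'
#' Mean performance and CCI across test runs by feedback type, with
#' standard-error bars.
#'
#' @param metrics A [cohort_metrics()] table.
#' @param variable `"performance"` or `"cci"`.
#' @return A ggplot object.
#' @export
plot_cohort_trajectories <- function(metrics,
                                     variable = c("performance", "cci")) {
  variable <- match.arg(variable)
  tm <- metrics[metrics$run_type == "test", , drop = FALSE]
  agg <- stats::aggregate(tm[[variable]],
                          by = list(session_feedback = tm$session_feedback,
                                    time = tm$time),
                          FUN = function(z)
                            c(mean = mean(z),
                              se = stats::sd(z) / sqrt(length(z))))
  df <- data.frame(session_feedback = agg$session_feedback,
                   time = agg$time,
                   mean = agg$x[, "mean"], se = agg$x[, "se"])
  ylab <- if (variable == "performance") "Percent correct" else
    "Cue congruence index"
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time, y = .data$mean,
    colour = .data$session_feedback, group = .data$session_feedback)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.1) +
    ggplot2::labs(x = "Test run", y = ylab, colour = "Feedback") +
    ggplot2::theme_minimal()
}
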