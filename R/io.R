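#' Write / read a simulation configuration as YAML
#'
#' The YAML file round-trips exactly: `read_config(write_config(cfg, f))`
#' reconstructs an identical configuration.
#'
#' @param config a `simulation_config`.
#' @param path output file path.
#' @export
write_config <- function(config, path) {
  as_plain <- function(x)
    if (is.list(x)) lapply(unclass(x), as_plain) else x
  yaml::write_yaml(as_plain(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML reads whole numbers as integers; the configuration is double
  raw <- rapply(raw, function(x)
    if (is.integer(x)) as.numeric(x) else x, how = "replace")
  sig <- do.call(signal_params, raw$model$signal)
  raw$model$signal <- NULL
  model <- do.call(model_params, c(raw$model, list(signal = sig)))
  mech <- do.call(mechanics_params, raw$mechanics)
  stim <- do.call(stimulus_spec, raw$stimulus)
  rest <- raw[setdiff(names(raw), c("model", "mechanics", "stimulus"))]
  do.call(simulation_config,
          c(list(model = model, mechanics = mech, stimulus = stim), rest))
}

#' Write a run's analysis products to a directory
#'
#' Writes `trajectory.csv`, `tracks.csv`, `events.csv` (with alpha / gamma
#' / clockwise per bifurcation), `aggregate_activator.csv`, the kymograph
#' matrix as `kymograph.csv`, the resolved configuration as `config.yaml`
#' and a `run.json` summary (seed, frame count, abort status, package
#' version).
#'
#' @param output a `simulation_output`.
#' @param dir output directory (created if missing).
#' @param gradient_direction gradient direction (degrees) used for the
#'   event angles.
#' @param ... passed to [analyze_run()].
#' @return invisibly, the tracking result.
#' @export
write_run <- function(output, dir, gradient_direction = 0, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(output$trajectory, file.path(dir, "trajectory.csv"),
                   row.names = FALSE)
  tracking <- analyze_run(output, ...)
  utils::write.csv(tracking$tracks, file.path(dir, "tracks.csv"),
                   row.names = FALSE)
  stats <- split_angle_statistics(tracking,
                                  gradient_direction = gradient_direction)
  ev <- if (nrow(stats$table) > 0) stats$table else
    data.frame(frame = integer(), parent_id = integer(),
               dominant_id = integer(), alpha = numeric(), gamma = numeric(),
               clockwise = logical())
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(aggregate_activator_timeseries(output),
                   file.path(dir, "aggregate_activator.csv"),
                   row.names = FALSE)
  km <- suppressMessages(kymograph(output$frames))
  utils::write.csv(as.data.frame(km), file.path(dir, "kymograph.csv"),
                   row.names = FALSE)
  write_config(output$config, file.path(dir, "config.yaml"))
  summary <- list(seed = output$config$seed,
                  frames = nrow(output$trajectory) - 1,
                  aborted = output$aborted,
                  package_version = as.character(utils::packageVersion("pseudotax")),
                  log = output$log)
  writeLines(yaml::as.yaml(summary), file.path(dir, "run.yaml"))
  invisible(tracking)
}
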