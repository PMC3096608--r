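#' Preset experiment configurations
#'
#' Ready-made protocols for the model's standard in silico experiments:
#' \describe{
#'   \item{random_migration}{no attractant; polarization, persistent
#'     migration and pseudopod bifurcation emerge from noise alone.}
#'   \item{gradient_panel}{four linear gradients reading 5.3 nM at the
#'     cell's rear edge and 5.5, 5.7, 6.1 or 6.6 nM at its front edge
#'     (across one cell diameter); returns a list of four configs.}
#'   \item{steep_gradient}{linear gradient spanning receptor occupancy 0 to
#'     20% across the cell diameter (0 to Kd/4 nM).}
#'   \item{cringe}{uniform concentration step to essentially full receptor
#'     occupancy with exponential receptor adaptation.}
#'   \item{circling}{5.3 to 7.0 nM gradient re-pointed to +90 degrees from
#'     the cell's current heading every 200 frames, making the cell circle.}
#' }
#'
#' @param name preset name.
#' @param overrides named list of `simulation_config` fields to replace
#'   after the preset is built (e.g. `list(frames = 300, seed = 7)`).
#' @param smoke if TRUE, use the reduced smoke profile (fewer frames,
#'   120 perimeter nodes, 64 x 64 grid) instead of the full defaults.
#' @return a `simulation_config`, or a list of four for "gradient_panel".
#' @export
preset <- function(name = c("random_migration", "gradient_panel",
                            "steep_gradient", "cringe", "circling"),
                   overrides = list(), smoke = FALSE) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown preset; valid presets: random_migration, gradient_panel, ",
         "steep_gradient, cringe, circling"))
  base <- simulation_config()
  if (smoke) {
    base$frames <- 500
    base$n_nodes <- 120
    base$grid_n <- 64
  }
  Kd <- base$model$signal$occupancy_Kd
  diam <- 2 * base$init_radius
  build <- function(cfg, stim) {
    cfg$stimulus <- stim
    for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
    cfg
  }
  linear_across <- function(rear, front) {
    # rear edge of the initial cell reads `rear`, front edge `front`;
    # gradient points along +x, reference at the initial centroid
    stimulus_spec("linear",
                  reference_concentration = (rear + front) / 2,
                  gradient_vector = c((front - rear) / diam, 0),
                  reference_point = c(0, 0))
  }
  switch(name,
    random_migration = build(base, stimulus_spec("none")),
    gradient_panel = lapply(c(5.5, 5.7, 6.1, 6.6), function(front)
      build(base, linear_across(5.3, front))),
    steep_gradient = build(base, linear_across(0, Kd * 0.2 / 0.8)),
    cringe = {
      cfg <- build(base, stimulus_spec("uniform_step",
                                       reference_concentration = 200 * Kd,
                                       onset_time = 500,
                                       adaptation_timescale = 300))
      cfg
    },
    circling = {
      stim <- stimulus_spec("scheduled",
                            reference_concentration = (5.3 + 7.0) / 2,
                            gradient_vector = c((7.0 - 5.3) / diam, 0),
                            reference_point = c(0, 0),
                            reorientation_interval = 200,
                            reorientation_offset = 90)
      build(base, stim)
    })
}

#' Parameter robustness scan
#'
#' Re-runs a base configuration with each scalar model parameter halved and
#' doubled, classifying every run as "migrates", "stalled", "repetitious"
#' or "aborted" from net displacement and the periodicity of the perimeter
#' activator pattern.
#'
#' @param base_config a `simulation_config`.
#' @param parameters names of `model_params` entries to scan.
#' @param factors multiplicative factors (default 0.5 and 2).
#' @param n_rep replicate seeds per condition.
#' @param displacement_threshold net displacement (in cell diameters) below
#'   which a run counts as stalled.
#' @param repetition_threshold lag-autocorrelation of the kymograph above
#'   which a run counts as repetitious.
#' @return data.frame: parameter, factor, seed, outcome, displacement.
#' @export
robustness_scan <- function(base_config,
                            parameters = c("D_a", "D_c", "r_a", "r_b",
                                           "b_c", "r_c"),
                            factors = c(0.5, 2),
                            n_rep = 1,
                            displacement_threshold = 0.5,
                            repetition_threshold = 0.9) {
  diam <- 2 * base_config$init_radius
  rows <- list()
  for (par in parameters) for (f in factors) for (r in seq_len(n_rep)) {
    cfg <- base_config
    cfg$model[[par]] <- cfg$model[[par]] * f
    cfg$model <- do.call(model_params, cfg$model[setdiff(names(cfg$model), NULL)])
    cfg$seed <- base_config$seed + r - 1L
    out <- tryCatch(run_simulation(cfg), error = function(e) e)
    rows[[length(rows) + 1]] <- classify_run(out, par, f, cfg$seed, diam,
                                             displacement_threshold,
                                             repetition_threshold)
  }
  do.call(rbind, rows)
}

classify_run <- function(out, par, f, seed, diam,
                         displacement_threshold, repetition_threshold) {
  if (inherits(out, "error"))
    return(data.frame(parameter = par, factor = f, seed = seed,
                      outcome = "aborted", displacement = NA_real_))
  tr <- out$trajectory
  disp <- sqrt((utils::tail(tr$x, 1) - tr$x[1])^2 +
                 (utils::tail(tr$y, 1) - tr$y[1])^2) / diam
  outcome <- if (out$aborted) "aborted"
  else if (disp < displacement_threshold) "stalled"
  else if (kymograph_periodicity(out) > repetition_threshold) "repetitious"
  else "migrates"
  data.frame(parameter = par, factor = f, seed = seed, outcome = outcome,
             displacement = disp)
}

# max autocorrelation of the flattened kymograph over time lags >= 5 frames:
# near 1 means the activator pattern repeats itself
kymograph_periodicity <- function(output, n_bins = 36, max_lag = NULL) {
  skip <- min(length(output$frames) - 2, 50)
  frames <- output$frames[-seq_len(skip)]
  if (length(frames) < 20) return(0)
  km <- suppressMessages(kymograph(frames, n_bins))
  km <- sweep(km, 2, colMeans(km))
  max_lag <- max_lag %||% min(nrow(km) - 5, 200)
  lags <- 5:max_lag
  if (length(lags) < 1) return(0)
  denom <- sum(km^2)
  if (denom == 0) return(1)
  best <- max(vapply(lags, function(L) {
    x <- km[seq_len(nrow(km) - L), , drop = FALSE]
    y <- km[(L + 1):nrow(km), , drop = FALSE]
    sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  }, numeric(1)))
  best
}

#' Chemotaxis-index matrix over gradient steepness and noise level
#'
#' @param gradients front-edge concentrations (nM, rear fixed at 5.3 nM;
#'   use 5.3 for a zero gradient).
#' @param noises noise amplitudes applied to both signal noise components.
#' @param n_seeds seeds per cell of the matrix.
#' @param base_config configuration template.
#' @return matrix (length(gradients) x length(noises)) of mean chemotaxis
#'   indices, with dimnames.
#' @export
noise_scan <- function(gradients, noises, n_seeds = 3,
                       base_config = preset("random_migration", smoke = TRUE)) {
  out <- matrix(NA_real_, length(gradients), length(noises),
                dimnames = list(paste0("front_", gradients),
                                paste0("noise_", noises)))
  diam <- 2 * base_config$init_radius
  for (i in seq_along(gradients)) for (j in seq_along(noises)) {
    ci <- numeric(n_seeds)
    for (r in seq_len(n_seeds)) {
      cfg <- base_config
      cfg$stimulus <- stimulus_spec("linear",
        reference_concentration = (5.3 + gradients[i]) / 2,
        gradient_vector = c((gradients[i] - 5.3) / diam, 0))
      cfg$model$signal$autocatalysis_noise_amplitude <- noises[j]
      cfg$model$signal$receptor_noise_amplitude <- noises[j]
      cfg$seed <- base_config$seed + r - 1L
      res <- tryCatch(run_simulation(cfg), error = function(e) NULL)
      ci[r] <- if (is.null(res) || nrow(res$trajectory) < 2) NA_real_
      else chemotaxis_index(res$trajectory, 0)
    }
    out[i, j] <- mean(ci, na.rm = TRUE)
  }
  out
}
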