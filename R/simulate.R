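#' Full simulation configuration
#'
#' Bundles model, mechanics, signal and stimulus parameters with the
#' numerical settings of a run. The cell diameter is normalized to 10
#' length units; "across the cell" in gradient protocols means across this
#' diameter.
#'
#' @param model a [model_params()].
#' @param mechanics a [mechanics_params()].
#' @param stimulus a [stimulus_spec()].
#' @param n_nodes perimeter nodes after each remesh.
#' @param frames number of output frames.
#' @param steps_per_frame reaction-diffusion sub-steps per frame; the
#'   boundary moves once per frame over `steps_per_frame * dt` model time.
#' @param grid_n level-set grid points per axis.
#' @param grid_h level-set grid spacing; default cell diameter / 32.
#' @param seed RNG seed (integer).
#' @param init_radius initial cell radius.
#' @param init_noise relative amplitude of the random perturbation applied
#'   to the initial activator field.
#' @param heading_window frames over which the centroid displacement
#'   defines the cell heading (used by scheduled stimuli).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(model = model_params(),
                              mechanics = mechanics_params(),
                              stimulus = stimulus_spec("none"),
                              n_nodes = 200, frames = 500,
                              steps_per_frame = 5,
                              grid_n = 128, grid_h = 10 / 32,
                              seed = 1L, init_radius = 5,
                              init_noise = 0.02,
                              heading_window = 20) {
  structure(list(model = model, mechanics = mechanics, stimulus = stimulus,
                 n_nodes = n_nodes, frames = frames,
                 steps_per_frame = steps_per_frame,
                 grid_n = grid_n, grid_h = grid_h, seed = as.integer(seed),
                 init_radius = init_radius, init_noise = init_noise,
                 heading_window = heading_window),
            class = "simulation_config")
}

# self-consistent unstimulated uniform state: s depends on a through the
# autocatalytic coupling, so iterate the fixed point a* = uss(s(a*))
init_uniform_state <- function(params) {
  sg <- params$signal
  a <- uniform_steady_state(params, sg$baseline)$a
  for (i in 1:50) {
    s <- sg$baseline + sg$autocatalysis_coupling * a
    a_new <- uniform_steady_state(params, s)$a
    if (abs(a_new - a) < 1e-12) break
    a <- a_new
  }
  list(a = a, b = a, c = params$b_c / params$r_c * a)
}

#' Run a pseudopod-centred chemotaxis simulation
#'
#' Main loop, once per frame: evaluate the stimulus at the perimeter nodes,
#' map it to receptor occupancy, advance the reaction-diffusion fields by
#' `steps_per_frame` semi-implicit sub-steps (fresh signal noise each
#' sub-step), compute the normal velocity from activator/curvature/area,
#' advance and reinitialize the level set, extract and resample the new
#' perimeter, and transfer the fields conservatively (geometric dilution).
#' Identical seeds give identical outputs.
#'
#' @param config a [simulation_config()].
#' @param progress print a progress message every `progress` frames
#'   (0 = silent).
#' @return object of class `simulation_output`: list with `frames` (list of
#'   per-frame snapshots: `mesh`, `a`, `c`, `b`, `time`), `trajectory`
#'   (data.frame: frame, time, x, y, area, heading), `config`, `log`
#'   (character), `aborted` (logical).
#' @export
run_simulation <- function(config, progress = 0) {
  set.seed(config$seed)
  p <- config$model
  mech <- config$mechanics
  stim <- config$stimulus
  dt_frame <- config$steps_per_frame * p$dt
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  mesh <- ring_mesh(config$init_radius, config$n_nodes)
  st <- init_uniform_state(p)
  a <- st$a * (1 + config$init_noise * stats::runif(config$n_nodes, -1, 1))
  fields <- surface_fields(a, rep(st$c, config$n_nodes), st$b)

  half <- config$grid_h * (config$grid_n - 1) / 2
  grid <- levelset_grid(origin = -c(half, half), h = config$grid_h,
                        nx = config$grid_n, ny = config$grid_n)
  grid <- signed_distance(grid, mesh)

  snapshots <- vector("list", config$frames + 1)
  traj <- data.frame(frame = integer(), time = numeric(), x = numeric(),
                     y = numeric(), area = numeric(), heading = numeric(),
                     stim_dir = numeric())
  stim_direction <- function(stim) {
    if (stim$kind %in% c("linear", "scheduled") &&
        sum(stim$gradient_vector^2) > 0)
      vec_angle(stim$gradient_vector)
    else NA_real_
  }
  record <- function(frame, time, mesh, fields, heading) {
    ac <- polygon_area_centroid(mesh)
    snapshots[[frame + 1]] <<- list(mesh = mesh, a = fields$a, c = fields$c,
                                    b = fields$b, time = time)
    traj <<- rbind(traj, data.frame(frame = frame, time = time,
                                    x = ac$centroid[1], y = ac$centroid[2],
                                    area = ac$area, heading = heading,
                                    stim_dir = stim_direction(stim)))
  }
  heading <- 0
  record(0, 0, mesh, fields, heading)
  aborted <- FALSE

  for (frame in seq_len(config$frames)) {
    time <- (frame - 1) * dt_frame
    # scheduled reorientation relative to the current heading
    if (identical(stim$kind, "scheduled") &&
        frame > 1 && (frame - 1) %% stim$reorientation_interval == 0) {
      ctr_now <- as.numeric(utils::tail(traj, 1)[c("x", "y")])
      # keep the cell-local concentration band fixed while re-pointing
      stim$reference_point <- ctr_now
      stim <- reorient_gradient(stim, heading, about = ctr_now)
      note("frame %d: stimulus reoriented to %.1f deg (heading %.1f)",
           frame, wrap_angle(heading + stim$reorientation_offset), heading)
    }
    conc <- concentration_at(mesh$nodes, time, stim)
    occ <- receptor_occupancy(conc, p$signal$occupancy_Kd)
    if (identical(stim$kind, "uniform_step") &&
        !is.null(stim$adaptation_timescale))
      occ <- adapted_occupancy(occ, time, stim$onset_time,
                               stim$adaptation_timescale)
    ops <- prepare_stepper(mesh, p)
    for (k in seq_len(config$steps_per_frame)) {
      s <- signal_field(occ, fields$a, p$signal)
      fields <- step_fields(fields, mesh, s, p, ops = ops)
    }
    ac <- polygon_area_centroid(mesh)
    kap <- smooth_periodic(curvature(mesh), passes = 3)
    v <- normal_velocity(fields$a, kap, ac$area, mech)
    # geometric sanity: one frame may not move the interface by more than
    # a third of the narrow band
    v_cap <- grid$band / (3 * dt_frame)
    if (any(abs(v) > v_cap)) {
      note("frame %d: %d node speeds clipped to %.3g", frame,
           sum(abs(v) > v_cap), v_cap)
      v <- pmin(pmax(v, -v_cap), v_cap)
    }
    Fx <- extend_velocity(mesh, v, grid)
    grid <- tryCatch(advance_levelset(grid, Fx, dt_frame), error = function(e) e)
    if (inherits(grid, "error")) {
      note("frame %d: aborted (%s)", frame, conditionMessage(grid))
      aborted <- TRUE
      break
    }
    grid <- tryCatch(reinitialize(grid), error = function(e) e)
    if (inherits(grid, "error")) {
      note("frame %d: aborted (%s)", frame, conditionMessage(grid))
      aborted <- TRUE
      break
    }
    new_mesh <- tryCatch(extract_perimeter(grid, config$n_nodes),
                         error = function(e) e)
    if (inherits(new_mesh, "error") || !polygon_is_simple(new_mesh$nodes)) {
      note("frame %d: aborted (%s)", frame,
           if (inherits(new_mesh, "error")) conditionMessage(new_mesh)
           else "self-intersecting perimeter")
      aborted <- TRUE
      break
    }
    fields <- transfer_fields(mesh, new_mesh, fields)
    mesh <- new_mesh
    # recentre the grid when the cell approaches the border
    ctr <- polygon_area_centroid(mesh)$centroid
    margin <- 1.3 * config$init_radius + grid$band + 2 * grid$h
    gx <- grid$origin[1] + c(0, grid$h * (grid$nx - 1))
    gy <- grid$origin[2] + c(0, grid$h * (grid$ny - 1))
    if (ctr[1] - margin < gx[1] || ctr[1] + margin > gx[2] ||
        ctr[2] - margin < gy[1] || ctr[2] + margin > gy[2]) {
      grid <- recenter_grid(grid, ctr)
      grid <- signed_distance(grid, mesh)
      note("frame %d: grid recentred", frame)
    }
    # heading from centroid displacement over the last heading_window frames
    k0 <- max(1, nrow(traj) - config$heading_window + 1)
    disp <- c(ctr[1] - traj$x[k0], ctr[2] - traj$y[k0])
    if (sqrt(sum(disp^2)) > 1e-6) heading <- vec_angle(disp)
    record(frame, frame * dt_frame, mesh, fields, heading)
    if (progress > 0 && frame %% progress == 0)
      message(sprintf("frame %d / %d", frame, config$frames))
  }
  structure(list(frames = snapshots[!vapply(snapshots, is.null, logical(1))],
                 trajectory = traj, config = config, log = log,
                 aborted = aborted),
            class = "simulation_output")
}

#' @export
print.simulation_output <- function(x, ...) {
  cat(sprintf("simulation_output: %d frames%s, final centroid (%.2f, %.2f)\n",
              nrow(x$trajectory) - 1, if (x$aborted) " (aborted)" else "",
              utils::tail(x$trajectory$x, 1), utils::tail(x$trajectory$y, 1)))
  invisible(x)
}

#' Line integral of the activator over the perimeter, per frame
#'
#' @param output a `simulation_output`.
#' @return data.frame with `frame`, `time`, `total_activator`.
#' @export
aggregate_activator_timeseries <- function(output) {
  do.call(rbind, lapply(seq_along(output$frames), function(i) {
    fr <- output$frames[[i]]
    data.frame(frame = i - 1, time = fr$time,
               total_activator = sum(fr$a * node_weights(fr$mesh)))
  }))
}

#' Detect and track pseudopods over a whole run
#'
#' Applies [detect_pseudopods()] to every frame with thresholds relative to
#' the run maximum of the activator, then [track_pseudopods()].
#'
#' @param output a `simulation_output`.
#' @param min_height_frac,min_prominence_frac thresholds as fractions of
#'   the run-maximum activator.
#' @param min_separation_frac minimum peak separation as a fraction of the
#'   perimeter.
#' @param matching_radius_frac frame-to-frame matching radius (fraction of
#'   perimeter).
#' @param bifurcation_radius_frac radius for attributing an appearing peak
#'   to a parent track as a bifurcation daughter.
#' @param min_lifetime minimum track lifetime in frames.
#' @return as [track_pseudopods()], plus element `peaks` (per-frame lists).
#' @export
analyze_run <- function(output, min_height_frac = 0.2,
                        min_prominence_frac = 0.1,
                        min_separation_frac = 0.1,
                        matching_radius_frac = 0.1,
                        bifurcation_radius_frac = 0.2,
                        min_lifetime = 5) {
  a_max <- max(vapply(output$frames, function(fr) max(fr$a), numeric(1)))
  peaks <- lapply(output$frames, function(fr) {
    detect_pseudopods(fr$a, fr$mesh,
                      min_height = min_height_frac * a_max,
                      min_prominence = min_prominence_frac * a_max,
                      min_separation = min_separation_frac * fr$mesh$perimeter)
  })
  res <- track_pseudopods(peaks, matching_radius = matching_radius_frac,
                          bifurcation_radius = bifurcation_radius_frac,
                          min_lifetime = min_lifetime)
  res$peaks <- peaks
  res
}

#' Fraction of pseudopods born by bifurcation
#'
#' New pseudopods either arise as bifurcation daughters (non-NA parent) or
#' de novo. Tracks present in the first frame are excluded (their origin is
#' unobserved).
#'
#' @param tracking result of [analyze_run()] / [track_pseudopods()].
#' @export
bifurcation_fraction <- function(tracking) {
  tr <- tracking$tracks
  born <- tr[tr$birth_frame > 1, , drop = FALSE]
  if (nrow(born) == 0) return(NA_real_)
  mean(!is.na(born$parent_id))
}
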