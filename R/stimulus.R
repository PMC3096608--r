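#' Chemoattractant stimulus specification
#'
#' Declarative description of the attractant protocol. Kinds:
#' \describe{
#'   \item{none}{no attractant anywhere.}
#'   \item{linear}{static linear gradient: concentration =
#'     `reference_concentration + gradient_vector . (position - reference_point)`,
#'     clipped at zero.}
#'   \item{point_source}{radial 1/r profile:
#'     `reference_concentration / max(r / source_scale, 1)` with `r` the
#'     distance to `source_position`, i.e. the concentration plateaus at the
#'     reference value within one `source_scale` of the source.}
#'   \item{uniform_step}{spatially uniform jump from 0 to
#'     `reference_concentration` at `onset_time`; receptor adaptation with
#'     timescale `adaptation_timescale` is applied downstream of occupancy.}
#'   \item{scheduled}{a linear gradient that the simulation driver
#'     re-points to `reorientation_offset` degrees from the cell's current
#'     heading every `reorientation_interval` frames.}
#' }
#'
#' All concentrations are in nM, lengths in model units (cell diameter =
#' 10), angles in degrees CCW from +x.
#'
#' @param kind one of "none", "linear", "point_source", "uniform_step",
#'   "scheduled".
#' @param reference_concentration concentration (nM) at the reference point
#'   (linear/scheduled), at the source plateau (point_source), or after the
#'   step (uniform_step).
#' @param gradient_vector length-2 gradient (nM per length unit).
#' @param reference_point point where the linear field equals the reference
#'   concentration.
#' @param source_position point-source location.
#' @param source_scale plateau radius of the point source.
#' @param onset_time stimulus onset (model time); concentration is 0 before.
#' @param adaptation_timescale receptor-adaptation decay time (uniform_step;
#'   NULL disables adaptation).
#' @param reorientation_interval frames between scheduled reorientations.
#' @param reorientation_offset offset (degrees) from the current heading at
#'   each scheduled reorientation.
#' @return object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("none", "linear", "point_source",
                                   "uniform_step", "scheduled"),
                          reference_concentration = 0,
                          gradient_vector = c(0, 0),
                          reference_point = c(0, 0),
                          source_position = c(0, 0),
                          source_scale = 5,
                          onset_time = 0,
                          adaptation_timescale = NULL,
                          reorientation_interval = NULL,
                          reorientation_offset = 90) {
  kind <- match.arg(kind)
  if (reference_concentration < 0) stop("reference_concentration must be >= 0")
  if (kind == "scheduled") {
    if (is.null(reorientation_interval) || reorientation_interval <= 0)
      stop("scheduled stimulus needs a strictly positive reorientation_interval")
  }
  if (!is.null(adaptation_timescale) && adaptation_timescale <= 0)
    stop("adaptation_timescale must be > 0")
  structure(list(kind = kind,
                 reference_concentration = reference_concentration,
                 gradient_vector = as.numeric(gradient_vector),
                 reference_point = as.numeric(reference_point),
                 source_position = as.numeric(source_position),
                 source_scale = source_scale,
                 onset_time = onset_time,
                 adaptation_timescale = adaptation_timescale,
                 reorientation_interval = reorientation_interval,
                 reorientation_offset = reorientation_offset),
            class = "stimulus_spec")
}

#' Chemoattractant concentration at a point
#'
#' @param position length-2 point or n x 2 matrix of points.
#' @param time model time (>= 0).
#' @param spec a [stimulus_spec()].
#' @return nonnegative concentration(s) in nM; 0 before `onset_time`.
#' @export
concentration_at <- function(position, time, spec) {
  if (time < 0) stop("time must be >= 0")
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 2)
  n <- nrow(pos)
  if (spec$kind == "none" || time < spec$onset_time) return(rep(0, n))
  conc <- switch(spec$kind,
    linear = ,
    scheduled = {
      dx <- pos[, 1] - spec$reference_point[1]
      dy <- pos[, 2] - spec$reference_point[2]
      spec$reference_concentration +
        spec$gradient_vector[1] * dx + spec$gradient_vector[2] * dy
    },
    point_source = {
      r <- sqrt((pos[, 1] - spec$source_position[1])^2 +
                  (pos[, 2] - spec$source_position[2])^2)
      spec$reference_concentration / pmax(r / spec$source_scale, 1)
    },
    uniform_step = rep(spec$reference_concentration, n),
    stop("unknown stimulus kind: ", spec$kind)
  )
  pmax(conc, 0)
}

#' Fractional receptor occupancy
#'
#' Hyperbolic (single-site) binding: Y = C / (C + Kd).
#'
#' @param concentration concentration(s) in nM, >= 0.
#' @param Kd dissociation constant in nM, > 0.
#' @return occupancy fraction(s) in [0, 1].
#' @export
receptor_occupancy <- function(concentration, Kd) {
  if (any(concentration < 0)) stop("concentration must be >= 0")
  if (Kd <= 0) stop("Kd must be > 0")
  concentration / (concentration + Kd)
}

#' Receptor occupancy with exponential adaptation
#'
#' Multiplies the occupancy by exp(-(t - onset)/tau), emulating receptor
#' adaptation to a sustained uniform stimulus. Before onset the
#' pre-stimulus value 0 is returned.
#'
#' @param occupancy occupancy fraction(s).
#' @param time current model time.
#' @param onset_time stimulus onset.
#' @param tau adaptation timescale (> 0).
#' @export
adapted_occupancy <- function(occupancy, time, onset_time, tau) {
  if (tau <= 0) stop("tau must be > 0")
  if (time < onset_time) return(0 * occupancy)
  occupancy * exp(-(time - onset_time) / tau)
}

#' Re-point a gradient stimulus relative to the cell's heading
#'
#' Rotates the gradient direction (linear/scheduled) or the source position
#' about `about` (point_source) so the stimulus points at
#' `cell_heading + offset` degrees; the gradient magnitude (or source
#' distance) is unchanged.
#'
#' @param spec a [stimulus_spec()].
#' @param cell_heading current heading in degrees.
#' @param offset offset in degrees relative to the heading (defaults to the
#'   spec's `reorientation_offset`).
#' @param about pivot for point sources (default: gradient reference point).
#' @export
reorient_gradient <- function(spec, cell_heading, offset = NULL,
                              about = spec$reference_point) {
  offset <- offset %||% spec$reorientation_offset
  if (spec$kind %in% c("none", "uniform_step")) {
    warning("reorient_gradient is a no-op for kind '", spec$kind, "'")
    return(spec)
  }
  target <- wrap_angle(cell_heading + offset)
  if (spec$kind %in% c("linear", "scheduled")) {
    g <- sqrt(sum(spec$gradient_vector^2))
    spec$gradient_vector <- g * unit_vector(target)
  } else {
    r <- sqrt(sum((spec$source_position - about)^2))
    spec$source_position <- about + r * unit_vector(target)
  }
  spec
}

#' Signal coupling and noise parameters
#'
#' Parameters of the per-node signal law
#' \deqn{s = (s_0 + w_a a)(1 + \eta_a \xi_1) + w_y Y (1 + \eta_y \xi_2),}
#' with `a` the local activator, `Y` the local receptor occupancy and
#' `xi_1, xi_2` independent zero-mean unit-amplitude noises drawn per node
#' per step (uniform on [-1, 1] by default, standard normal with
#' `noise_kind = "gaussian"`). The first component represents noisy
#' autocatalysis, the second noisy receptor signalling; `s` is clipped at 0.
#'
#' @param baseline s_0, the constitutive signal level (dimensionless).
#' @param autocatalysis_coupling w_a.
#' @param occupancy_coupling w_y.
#' @param autocatalysis_noise_amplitude eta_a (>= 0).
#' @param receptor_noise_amplitude eta_y (>= 0).
#' @param occupancy_Kd receptor dissociation constant (nM, > 0) used when a
#'   concentration field is mapped to occupancy.
#' @param noise_kind "uniform" or "gaussian".
#' @export
signal_params <- function(baseline = 1,
                          autocatalysis_coupling = 0.002,
                          occupancy_coupling = 2,
                          autocatalysis_noise_amplitude = 0.15,
                          receptor_noise_amplitude = 0.15,
                          occupancy_Kd = 30,
                          noise_kind = c("uniform", "gaussian")) {
  if (autocatalysis_noise_amplitude < 0 || receptor_noise_amplitude < 0)
    stop("noise amplitudes must be >= 0")
  if (occupancy_Kd <= 0) stop("occupancy_Kd must be > 0")
  structure(list(baseline = baseline,
                 autocatalysis_coupling = autocatalysis_coupling,
                 occupancy_coupling = occupancy_coupling,
                 autocatalysis_noise_amplitude = autocatalysis_noise_amplitude,
                 receptor_noise_amplitude = receptor_noise_amplitude,
                 occupancy_Kd = occupancy_Kd,
                 noise_kind = match.arg(noise_kind)),
            class = "signal_params")
}

#' Per-node signal driving activator production
#'
#' Combines the autocatalytic and occupancy components with their
#' multiplicative noises (see [signal_params()]). Noise is drawn from the
#' R session RNG: two draws per node, consumed in node order
#' (xi_1 then xi_2 for node 1, then node 2, ...). With both noise
#' amplitudes zero the function is deterministic and consumes no random
#' numbers.
#'
#' @param occupancy per-node receptor occupancy in [0, 1].
#' @param activator per-node activator concentration.
#' @param params a [signal_params()].
#' @return per-node nonnegative signal vector.
#' @export
signal_field <- function(occupancy, activator, params) {
  n <- length(activator)
  if (length(occupancy) == 1) occupancy <- rep(occupancy, n)
  if (length(occupancy) != n)
    stop("occupancy and activator must be defined on the same node set")
  ea <- params$autocatalysis_noise_amplitude
  ey <- params$receptor_noise_amplitude
  if (ea > 0 || ey > 0) {
    draws <- if (params$noise_kind == "uniform")
      stats::runif(2 * n, -1, 1) else stats::rnorm(2 * n)
    xi1 <- draws[seq(1, 2 * n, by = 2)]
    xi2 <- draws[seq(2, 2 * n, by = 2)]
  } else {
    xi1 <- xi2 <- numeric(n)
  }
  s <- (params$baseline + params$autocatalysis_coupling * activator) *
    (1 + ea * xi1) +
    params$occupancy_coupling * occupancy * (1 + ey * xi2)
  pmax(s, 0)
}
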