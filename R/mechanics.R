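#' Membrane mechanics parameters
#'
#' The perimeter moves along its outward normal with speed
#' \deqn{v = \lambda_p a - \lambda_\sigma \kappa
#'       \left(1 + k_A \frac{A - A_0}{A_0}\right),}
#' an activator-proportional protrusion opposed by a curvature-based
#' retraction (cortical tension). The tension term is scaled up when the
#' cell exceeds its target area and down when it is below it, which keeps
#' the area roughly constant over a run.
#'
#' @param lambda_p protrusion coefficient (length / (time * activator)).
#' @param lambda_sigma tension coefficient (length^2 / time).
#' @param k_A dimensionless area-control gain (>= 0).
#' @param A0 target area (length^2); default: a circle of diameter 10.
#' @export
mechanics_params <- function(lambda_p = 0.01, lambda_sigma = 0.20,
                             k_A = 15, A0 = pi * 25) {
  if (lambda_p <= 0 || lambda_sigma <= 0 || A0 <= 0)
    stop("lambda_p, lambda_sigma and A0 must be > 0")
  if (k_A < 0) stop("k_A must be >= 0")
  structure(list(lambda_p = lambda_p, lambda_sigma = lambda_sigma,
                 k_A = k_A, A0 = A0), class = "mechanics_params")
}

#' Outward-normal boundary speed
#'
#' @param a per-node activator.
#' @param kappa per-node signed curvature from [curvature()].
#' @param area current cell area.
#' @param params a [mechanics_params()].
#' @return per-node outward-normal speed (positive = protrusion).
#' @export
normal_velocity <- function(a, kappa, area, params) {
  if (length(a) != length(kappa)) stop("a and kappa must be aligned")
  gain <- 1 + params$k_A * (area - params$A0) / params$A0
  # bounded: a negative gain pushes the boundary outward when the cell is
  # far below its target area
  gain <- pmin(pmax(gain, -2), 4)
  params$lambda_p * a - params$lambda_sigma * kappa * gain
}

#' Circular moving-average smoothing of a per-node quantity
#'
#' Repeated 1-2-1 kernel passes on a periodic signal; used to filter
#' node-scale discretization noise out of the curvature before it enters
#' the retraction term.
#'
#' @param x periodic per-node values.
#' @param passes number of smoothing passes.
#' @export
smooth_periodic <- function(x, passes = 2) {
  n <- length(x)
  for (k in seq_len(passes)) x <- (x[c(n, 1:(n - 1))] + 2 * x + x[c(2:n, 1)]) / 4
  x
}

# outward unit normals of a CCW polygon (rotate tangent by -90 degrees)
outward_normals <- function(mesh) {
  tang <- node_shift(mesh$nodes, 1) - node_shift(mesh$nodes, -1)
  len <- sqrt(rowSums(tang^2))
  cbind(tang[, 2], -tang[, 1]) / len
}
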