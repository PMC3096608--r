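#' Model parameters for the activator / two-inhibitor system
#'
#' Rate and diffusion constants of the Meinhardt-type system driving
#' pseudopod dynamics. The activator a obeys
#' \deqn{\partial_t a = D_a \Delta_\Gamma a +
#'   \frac{s\,(a^2/b + b_a)}{(s_c + c)(1 + s_a a^2)} - r_a a,}
#' the global inhibitor is a single scalar relaxing toward the
#' length-weighted perimeter mean of a, \eqn{db/dt = r_b(\langle a\rangle - b)},
#' and the local inhibitor obeys
#' \eqn{\partial_t c = D_c \Delta_\Gamma c + b_c a - r_c c}.
#'
#' Defaults are in the classical Meinhardt regime, rescaled to a cell of
#' diameter 10 length units, and were fixed once so that the unstimulated
#' default cell is motile and area-stable.
#'
#' @param D_a activator diffusivity (length^2 / time).
#' @param D_c local-inhibitor diffusivity (length^2 / time).
#' @param r_a activator decay rate (1 / time).
#' @param r_b global-inhibitor turnover rate (1 / time).
#' @param b_c local-inhibitor production rate (1 / time).
#' @param r_c local-inhibitor decay rate (1 / time).
#' @param basal_production basal (signal-coupled) activator production,
#'   Meinhardt's b_a (dimensionless).
#' @param activator_saturation saturation constant of autocatalysis,
#'   Meinhardt's s_a.
#' @param inhibitor_offset offset of the local inhibitor in the production
#'   denominator, Meinhardt's s_c.
#' @param dt reaction-diffusion time step (model time).
#' @param signal a [signal_params()] object.
#' @return object of class `model_params`.
#' @export
model_params <- function(D_a = 0.08, D_c = 0.35,
                         r_a = 0.02, r_b = 0.03,
                         b_c = 0.13, r_c = 0.013,
                         basal_production = 0.1,
                         activator_saturation = 0.005,
                         inhibitor_offset = 0.2,
                         dt = 1, signal = signal_params()) {
  p <- list(D_a = D_a, D_c = D_c, r_a = r_a, r_b = r_b, b_c = b_c,
            r_c = r_c, basal_production = basal_production,
            activator_saturation = activator_saturation,
            inhibitor_offset = inhibitor_offset, dt = dt, signal = signal)
  rates <- p[c("D_a", "D_c", "r_a", "r_b", "b_c", "r_c", "dt")]
  if (any(unlist(rates) <= 0))
    stop("all diffusivities, rates and dt must be > 0")
  structure(p, class = "model_params")
}

#' Surface fields on the perimeter
#'
#' @param a per-node activator concentration (>= 0).
#' @param c per-node local-inhibitor concentration (>= 0).
#' @param b scalar global-inhibitor level (>= 0).
#' @export
surface_fields <- function(a, c, b) {
  if (length(a) != length(c)) stop("a and c must share the node set")
  if (length(b) != 1) stop("b is a single global scalar")
  if (any(!is.finite(a)) || any(!is.finite(c)) || !is.finite(b))
    stop("non-finite field values")
  if (any(a < 0) || any(c < 0) || b < 0) stop("fields must be nonnegative")
  structure(list(a = as.numeric(a), c = as.numeric(c), b = as.numeric(b)),
            class = "surface_fields")
}

B_FLOOR <- 1e-12  # guard for divisions by the global inhibitor

#' Mass and stiffness matrices on a closed polygonal curve
#'
#' Piecewise-linear (P1) surface finite elements on the closed 1-D curve:
#' the consistent mass matrix encodes element lengths and the stiffness
#' matrix is the discrete Laplace-Beltrami operator (annihilates
#' constants).
#'
#' @param mesh a [perimeter_mesh()].
#' @return list with sparse symmetric `M` (mass) and `K` (stiffness).
#' @export
assemble_operators <- function(mesh) {
  n <- nrow(mesh$nodes)
  if (n < 8) stop("mesh needs at least 8 nodes")
  h <- mesh$lengths
  if (any(h <= .Machine$double.eps)) stop("degenerate element")
  i2 <- c(seq_len(n)[-1], 1)          # element e joins node e and i2[e]
  ii <- c(seq_len(n), i2, seq_len(n), i2)
  jj <- c(seq_len(n), i2, i2, seq_len(n))
  M <- Matrix::sparseMatrix(i = ii, j = jj,
                            x = c(h / 3, h / 3, h / 6, h / 6),
                            dims = c(n, n))
  K <- Matrix::sparseMatrix(i = ii, j = jj,
                            x = c(1 / h, 1 / h, -1 / h, -1 / h),
                            dims = c(n, n))
  list(M = Matrix::forceSymmetric(M), K = Matrix::forceSymmetric(K))
}

#' Non-diffusive reaction terms of the three-species system
#'
#' @param a,c per-node fields; `b` scalar global inhibitor.
#' @param s per-node signal.
#' @param params a [model_params()].
#' @param weights optional per-node quadrature weights used for the
#'   perimeter mean of `a` (defaults to equal weights).
#' @return list with `da` (per node), `db` (scalar), `dc` (per node).
#' @export
reaction_terms <- function(a, b, c, s, params, weights = NULL) {
  if (length(a) != length(c) || length(a) != length(s))
    stop("a, c and s must be aligned")
  bb <- max(b, B_FLOOR)
  prod <- s * (a^2 / bb + params$basal_production) /
    ((params$inhibitor_offset + c) * (1 + params$activator_saturation * a^2))
  da <- prod - params$r_a * a
  w <- if (is.null(weights)) rep(1 / length(a), length(a)) else weights / sum(weights)
  db <- params$r_b * (sum(w * a) - b)
  dc <- params$b_c * a - params$r_c * c
  list(da = da, db = db, dc = dc)
}

#' Advance the surface fields by one semi-implicit step
#'
#' First-order IMEX scheme: reaction terms explicit, diffusion implicit
#' (unconditionally stable); the global inhibitor advances as a scalar ODE.
#' Negative round-off values are clipped to zero.
#'
#' @param fields a [surface_fields()].
#' @param mesh the current [perimeter_mesh()].
#' @param s per-node signal vector.
#' @param params a [model_params()].
#' @param dt time step; defaults to `params$dt`.
#' @param ops optional precomputed result of [assemble_operators()] plus
#'   factorizations (see [prepare_stepper()]); assembled on the fly if
#'   missing.
#' @return updated `surface_fields`.
#' @export
step_fields <- function(fields, mesh, s, params, dt = params$dt, ops = NULL) {
  if (is.null(ops)) ops <- prepare_stepper(mesh, params, dt)
  w <- mesh$lengths_node %||% node_weights(mesh)
  rt <- reaction_terms(fields$a, fields$b, fields$c, s, params, weights = w)
  rhs_a <- ops$M %*% (fields$a + dt * rt$da)
  rhs_c <- ops$M %*% (fields$c + dt * rt$dc)
  a_new <- as.numeric(Matrix::solve(ops$A_a, rhs_a))
  c_new <- as.numeric(Matrix::solve(ops$A_c, rhs_c))
  if (any(!is.finite(a_new)) || any(!is.finite(c_new)))
    stop("linear solve produced non-finite values (diffusion step)")
  b_new <- fields$b + dt * rt$db
  surface_fields(pmax(a_new, 0), pmax(c_new, 0), max(b_new, 0))
}

#' Precompute operators and factorizations for repeated stepping
#'
#' @inheritParams step_fields
#' @export
prepare_stepper <- function(mesh, params, dt = params$dt) {
  ops <- assemble_operators(mesh)
  ops$A_a <- Matrix::Cholesky(Matrix::forceSymmetric(
    ops$M + dt * params$D_a * ops$K), LDL = FALSE)
  ops$A_c <- Matrix::Cholesky(Matrix::forceSymmetric(
    ops$M + dt * params$D_c * ops$K), LDL = FALSE)
  ops
}

# trapezoidal per-node weights (half the two adjacent element lengths)
node_weights <- function(mesh) {
  (mesh$lengths + c(mesh$lengths[length(mesh$lengths)],
                    mesh$lengths[-length(mesh$lengths)])) / 2
}

#' Transfer fields between meshes with geometric dilution
#'
#' Each new node is projected to its closest point on the old perimeter and
#' the fields are interpolated there; the interpolated value is then divided
#' by the local stretch factor J (ratio of new to old node spacing), so the
#' line integral of each field is conserved. Stretching of an expanding
#' leading edge therefore dilutes the activator - the geometric inhibition
#' mechanism of the moving-boundary model.
#'
#' @param old_mesh,new_mesh `perimeter_mesh` objects.
#' @param fields `surface_fields` on `old_mesh`.
#' @param max_distance reject the transfer when any new node is farther than
#'   this from the old perimeter (default: 20% of the old perimeter /
#'   number of nodes * 10, i.e. a loose geometric-similarity guard).
#' @param dilute if FALSE, plain interpolation without the conservative
#'   1/J factor.
#' @return `surface_fields` on `new_mesh`.
#' @export
transfer_fields <- function(old_mesh, new_mesh, fields,
                            max_distance = NULL, dilute = TRUE) {
  if (length(fields$a) != nrow(old_mesh$nodes))
    stop("fields are not defined on old_mesh")
  cp <- polygon_closest_point(new_mesh$nodes[, 1], new_mesh$nodes[, 2],
                              old_mesh$nodes)
  max_distance <- max_distance %||% (0.1 * old_mesh$perimeter)
  if (max(cp$dist) > max_distance)
    stop(sprintf("meshes too dissimilar for transfer (max distance %.3g > %.3g)",
                 max(cp$dist), max_distance))
  # arc position of each new node on the old perimeter
  t_old <- (old_mesh$arc[cp$element] + cp$t * old_mesh$lengths[cp$element]) %%
    old_mesh$perimeter
  a_i <- interp_periodic(old_mesh$arc, fields$a, old_mesh$perimeter, t_old)
  c_i <- interp_periodic(old_mesh$arc, fields$c, old_mesh$perimeter, t_old)
  if (dilute) {
    n <- length(t_old)
    circ_gap <- function(x, L) {
      d <- (x %% L + L) %% L
      d
    }
    nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
    # old-arc span and new-arc span covered by each node's dual cell
    dt_old <- circ_gap(t_old[nxt] - t_old[prv], old_mesh$perimeter) / 2
    ds_new <- circ_gap(new_mesh$arc[nxt] - new_mesh$arc[prv],
                       new_mesh$perimeter) / 2
    # guard against degenerate correspondences; per-frame stretch beyond
    # 2x is a geometry artifact, not physical dilution
    J <- ds_new / pmax(dt_old, 1e-10)
    J <- pmin(pmax(J, 0.5), 2)
    a_i <- a_i / J
    c_i <- c_i / J
  }
  surface_fields(pmax(a_i, 0), pmax(c_i, 0), fields$b)
}

#' Spatially uniform steady state of the reaction system
#'
#' Root of the uniform (diffusion-free) system at fixed uniform signal
#' `s0`: the global inhibitor equals the activator (b* = a*), the local
#' inhibitor is (b_c / r_c) a*, and a* solves
#' \deqn{s_0 (a + b_a) = r_a a (s_c + (b_c/r_c) a)(1 + s_a a^2).}
#'
#' @param params a [model_params()].
#' @param s0 uniform signal level (>= 0).
#' @return list with `a`, `b`, `c` at the steady state.
#' @export
uniform_steady_state <- function(params, s0) {
  if (s0 < 0) stop("s0 must be >= 0")
  k <- params$b_c / params$r_c
  f <- function(a) {
    s0 * (a + params$basal_production) -
      params$r_a * a * (params$inhibitor_offset + k * a) *
        (1 + params$activator_saturation * a^2)
  }
  if (s0 == 0) return(list(a = 0, b = 0, c = 0))
  upper <- 1
  while (f(upper) > 0 && upper < 1e8) upper <- upper * 2
  if (f(upper) > 0) stop("no positive uniform steady state found")
  a_star <- stats::uniroot(f, c(0, upper), tol = 1e-14)$root
  list(a = a_star, b = a_star, c = k * a_star)
}
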