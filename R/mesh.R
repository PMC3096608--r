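#' Closed polygonal perimeter mesh
#'
#' The cell boundary is represented as a simple closed polygon whose nodes
#' carry the surface fields (activator, local inhibitor). Nodes are stored
#' counterclockwise without repeating the first node; element i joins node i
#' to node i + 1 (cyclically).
#'
#' @param nodes numeric matrix (n x 2) of vertex coordinates.
#' @param check if TRUE (default) verify simplicity and enforce CCW order.
#' @return an object of class `perimeter_mesh`: list with `nodes`, element
#'   lengths `lengths`, cumulative arc positions `arc` (arc length of each
#'   node from node 1) and total `perimeter`.
#' @export
perimeter_mesh <- function(nodes, check = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 2 || nrow(nodes) < 3)
    stop("mesh needs an n x 2 matrix with n >= 3")
  # drop a repeated closing vertex if present
  n <- nrow(nodes)
  if (isTRUE(all.equal(nodes[1, ], nodes[n, ], tolerance = 1e-12)))
    nodes <- nodes[-n, , drop = FALSE]
  if (check && signed_area(nodes) < 0)
    nodes <- nodes[rev(seq_len(nrow(nodes))), , drop = FALSE]
  ed <- node_shift(nodes, 1) - nodes
  len <- sqrt(rowSums(ed^2))
  if (any(len <= .Machine$double.eps))
    stop("degenerate (zero-length) element in perimeter mesh")
  if (check && !polygon_is_simple(nodes))
    stop("perimeter mesh is self-intersecting")
  structure(list(
    nodes = nodes,
    lengths = len,
    arc = c(0, cumsum(len))[seq_len(nrow(nodes))],
    perimeter = sum(len)
  ), class = "perimeter_mesh")
}

#' @export
print.perimeter_mesh <- function(x, ...) {
  ac <- polygon_area_centroid(x)
  cat(sprintf("perimeter_mesh: %d nodes, length %.4g, area %.4g\n",
              nrow(x$nodes), x$perimeter, ac$area))
  invisible(x)
}

node_shift <- function(m, k) {
  n <- nrow(m)
  m[((seq_len(n) - 1 + k) %% n) + 1, , drop = FALSE]
}

signed_area <- function(nodes) {
  x <- nodes[, 1]; y <- nodes[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area and centroid
#'
#' Shoelace area (positive for counterclockwise orientation) and the
#' area-weighted centroid of a simple closed polygon.
#'
#' @param mesh a `perimeter_mesh` (or bare n x 2 matrix).
#' @return list with `area` and `centroid` (length-2 vector).
#' @export
polygon_area_centroid <- function(mesh) {
  nodes <- if (inherits(mesh, "perimeter_mesh")) mesh$nodes else as.matrix(mesh)
  x <- nodes[, 1]; y <- nodes[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) stop("polygon has (near) zero area")
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  list(area = a, centroid = c(cx, cy))
}

#' Discrete signed curvature of a closed polygon
#'
#' Finite difference of the tangent angle over arc length: at node i the
#' turning angle between the incoming and outgoing edge is divided by the
#' mean of the adjacent element lengths. Convention: a counterclockwise
#' circle has positive curvature 1/R everywhere.
#'
#' @param mesh a `perimeter_mesh`.
#' @return numeric vector of per-node curvature (1/length units).
#' @export
curvature <- function(mesh) {
  nodes <- mesh$nodes
  if (anyDuplicated(nodes)) stop("duplicate nodes in mesh")
  prev <- node_shift(nodes, -1)
  nxt <- node_shift(nodes, 1)
  e_in <- nodes - prev
  e_out <- nxt - nodes
  turn <- atan2(e_in[, 1] * e_out[, 2] - e_in[, 2] * e_out[, 1],
                rowSums(e_in * e_out))
  len_in <- sqrt(rowSums(e_in^2))
  len_out <- sqrt(rowSums(e_out^2))
  turn / ((len_in + len_out) / 2)
}

#' Uniform circular mesh
#'
#' @param radius circle radius.
#' @param n number of nodes.
#' @param center length-2 centre.
#' @export
ring_mesh <- function(radius, n = 200, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  perimeter_mesh(cbind(center[1] + radius * cos(th),
                       center[2] + radius * sin(th)), check = FALSE)
}

#' Resample a closed polygon to equal arc-length spacing
#'
#' @param mesh a `perimeter_mesh`.
#' @param n_nodes number of output nodes; node 1 stays at the original
#'   node-1 arc position.
#' @export
resample_mesh <- function(mesh, n_nodes) {
  s <- c(mesh$arc, mesh$perimeter)
  px <- c(mesh$nodes[, 1], mesh$nodes[1, 1])
  py <- c(mesh$nodes[, 2], mesh$nodes[1, 2])
  si <- mesh$perimeter * (seq_len(n_nodes) - 1) / n_nodes
  perimeter_mesh(cbind(stats::approx(s, px, xout = si)$y,
                       stats::approx(s, py, xout = si)$y), check = FALSE)
}

# Interpolate a periodic per-node field at arbitrary arc positions.
interp_periodic <- function(arc, values, perimeter, at) {
  s <- c(arc, perimeter)
  v <- c(values, values[1])
  stats::approx(s, v, xout = at %% perimeter, rule = 2)$y
}

# simplicity, point-membership and closest-point primitives are compiled
# (see src/geometry.cpp); these wrappers keep the call sites readable
polygon_is_simple <- function(nodes) {
  cpp_polygon_is_simple(nodes)
}

#' Points-in-polygon test (crossing number)
#'
#' @param px,py coordinates of query points.
#' @param nodes polygon vertex matrix.
#' @return logical vector, TRUE for points inside.
#' @keywords internal
points_in_polygon <- function(px, py, nodes) {
  cpp_point_in_polygon(px, py, nodes)
}

# Closest point on a polygon boundary for a set of query points.
# Returns distance, the element index (1-based) and the within-element
# parameter in [0, 1].
polygon_closest_point <- function(px, py, nodes) {
  cpp_closest_point(px, py, nodes)
}
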