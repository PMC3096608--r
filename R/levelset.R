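#' Cartesian level-set grid
#'
#' The cell interior is the region where `phi < 0`; the zero contour of
#' `phi` is the cell perimeter. `phi` approximates the signed distance in a
#' narrow band of half-width `band` around the interface and is clamped to
#' `+/- band` outside it.
#'
#' @param origin length-2 coordinates of grid point (1, 1).
#' @param h grid spacing (same in x and y).
#' @param nx,ny number of grid points per axis.
#' @param band narrow-band half-width (length units); default 6 h.
#' @return object of class `levelset_grid` with `x`, `y` coordinate vectors
#'   and `phi` (nx x ny matrix, x indexing rows).
#' @export
levelset_grid <- function(origin, h, nx, ny, band = 6 * h) {
  structure(list(
    origin = origin, h = h, nx = nx, ny = ny, band = band,
    x = origin[1] + h * (seq_len(nx) - 1),
    y = origin[2] + h * (seq_len(ny) - 1),
    phi = matrix(band, nx, ny)
  ), class = "levelset_grid")
}

#' Initialize (or reset) a grid as signed distance to a polygon
#'
#' Exact point-to-polygon distance, negative inside, clamped to the band.
#'
#' @param grid a [levelset_grid()].
#' @param mesh a [perimeter_mesh()].
#' @export
signed_distance <- function(grid, mesh) {
  # exact distances are only needed inside the polygon's bounding box
  # inflated by the band; everything farther out clamps to +band
  xr <- range(mesh$nodes[, 1]) + c(-1, 1) * (grid$band + grid$h)
  yr <- range(mesh$nodes[, 2]) + c(-1, 1) * (grid$band + grid$h)
  ix <- which(grid$x >= xr[1] & grid$x <= xr[2])
  iy <- which(grid$y >= yr[1] & grid$y <= yr[2])
  if (length(ix) == 0 || length(iy) == 0)
    stop("perimeter lies outside the level-set grid")
  xs <- rep(grid$x[ix], times = length(iy))
  ys <- rep(grid$y[iy], each = length(ix))
  cp <- polygon_closest_point(xs, ys, mesh$nodes)
  inside <- points_in_polygon(xs, ys, mesh$nodes)
  d <- cp$dist
  d[inside] <- -d[inside]
  phi <- matrix(grid$band, grid$nx, grid$ny)
  phi[ix, iy] <- matrix(d, length(ix), length(iy))
  grid$phi <- matrix(pmin(pmax(phi, -grid$band), grid$band),
                     grid$nx, grid$ny)
  grid
}

band_indices <- function(grid, width = grid$band) {
  which(abs(grid$phi) < width)
}

#' Closest-point extension of a perimeter speed to the grid band
#'
#' Each narrow-band grid point takes the (linearly interpolated) speed of
#' its closest point on the perimeter, making the extended field constant
#' along normals up to discretization error. Outside the band the field
#' is zero.
#'
#' @param mesh a [perimeter_mesh()].
#' @param v per-node outward-normal speed.
#' @param grid a [levelset_grid()].
#' @return matrix of speeds with the grid's dimensions.
#' @export
extend_velocity <- function(mesh, v, grid) {
  if (length(v) != nrow(mesh$nodes)) stop("v not aligned with mesh nodes")
  xr <- range(mesh$nodes[, 1]); yr <- range(mesh$nodes[, 2])
  if (xr[1] < grid$x[1] || xr[2] > grid$x[grid$nx] ||
      yr[1] < grid$y[1] || yr[2] > grid$y[grid$ny])
    stop("perimeter lies outside the level-set grid")
  F <- matrix(0, grid$nx, grid$ny)
  idx <- band_indices(grid)
  if (length(idx) == 0) return(F)
  ix <- ((idx - 1) %% grid$nx) + 1
  iy <- ((idx - 1) %/% grid$nx) + 1
  cp <- polygon_closest_point(grid$x[ix], grid$y[iy], mesh$nodes)
  n <- nrow(mesh$nodes)
  v_next <- v[c(2:n, 1)]
  F[idx] <- (1 - cp$t) * v[cp$element] + cp$t * v_next[cp$element]
  F
}

#' Advance the level-set function by a normal-speed field
#'
#' First-order Godunov upwind scheme for `phi_t + F |grad phi| = 0` with
#' `F` the outward-normal interface speed (positive = expansion). The CFL
#' condition `max|F| dt <= 0.5 h` is enforced by internal sub-stepping.
#'
#' @param grid a [levelset_grid()].
#' @param speed matrix of extended speeds (grid dimensions).
#' @param dt time increment.
#' @export
advance_levelset <- function(grid, speed, dt) {
  h <- grid$h
  fmax <- max(abs(speed))
  if (fmax == 0 || dt == 0) return(grid)
  nsub <- max(1L, ceiling(fmax * dt / (0.5 * h)))
  dts <- dt / nsub
  phi <- grid$phi
  nx <- grid$nx; ny <- grid$ny
  for (k in seq_len(nsub)) {
    # one-sided differences with replicated borders
    Dxm <- (phi - phi[c(1, 1:(nx - 1)), , drop = FALSE]) / h
    Dxp <- (phi[c(2:nx, nx), , drop = FALSE] - phi) / h
    Dym <- (phi - phi[, c(1, 1:(ny - 1)), drop = FALSE]) / h
    Dyp <- (phi[, c(2:ny, ny), drop = FALSE] - phi) / h
    gp <- sqrt(pmax(Dxm, 0)^2 + pmin(Dxp, 0)^2 +
                 pmax(Dym, 0)^2 + pmin(Dyp, 0)^2)
    gm <- sqrt(pmin(Dxm, 0)^2 + pmax(Dxp, 0)^2 +
                 pmin(Dym, 0)^2 + pmax(Dyp, 0)^2)
    phi <- phi - dts * (pmax(speed, 0) * gp + pmin(speed, 0) * gm)
  }
  if (all(phi > 0) || all(phi < 0))
    stop("zero contour lost during level-set advance (cell collapse)")
  grid$phi <- matrix(pmin(pmax(phi, -grid$band), grid$band), nx, ny)
  grid
}

#' Reinitialize the level-set function to signed distance
#'
#' Extracts the current zero contour and rebuilds `phi` as the exact signed
#' distance to it (clamped to the band). The zero contour itself moves by
#' less than a fraction of a cell.
#'
#' @param grid a [levelset_grid()].
#' @return updated grid.
#' @export
reinitialize <- function(grid) {
  contour <- extract_contour(grid)
  signed_distance(grid, contour)
}

# Largest closed zero contour of phi as a raw (unresampled) mesh.
extract_contour <- function(grid) {
  phi <- grid$phi
  # grid points landing (almost) exactly on the interface make marching
  # squares emit split/open contours; nudge them to the inside
  eps <- 1e-9 * grid$h
  phi[abs(phi) < eps] <- -eps
  cl <- grDevices::contourLines(grid$x, grid$y, phi, levels = 0)
  if (length(cl) == 0) stop("no zero contour: cell collapsed")
  is_closed <- function(cc) {
    length(cc$x) >= 4 &&
      abs(cc$x[1] - cc$x[length(cc$x)]) < 1e-9 &&
      abs(cc$y[1] - cc$y[length(cc$y)]) < 1e-9
  }
  closed <- Filter(is_closed, cl)
  if (length(closed) == 0 && length(cl) > 1) {
    stitched <- stitch_segments(cl, tol = 1e-6 * grid$h)
    if (!is.null(stitched)) closed <- list(stitched)
  }
  if (length(closed) == 0) stop("zero contour is not closed (cell touching grid border?)")
  if (length(closed) > 1)
    message("multiple zero contours; keeping the largest by area")
  areas <- vapply(closed, function(cc)
    abs(signed_area(cbind(cc$x[-1], cc$y[-1]))), numeric(1))
  cc <- closed[[which.max(areas)]]
  nodes <- cbind(cc$x[-1], cc$y[-1])
  if (signed_area(nodes) < 0) nodes <- nodes[rev(seq_len(nrow(nodes))), ]
  perimeter_mesh(nodes, check = FALSE)
}

# join open marching-squares segments sharing endpoints into one loop
stitch_segments <- function(cl, tol) {
  seg <- lapply(cl, function(cc) cbind(cc$x, cc$y))
  cur <- seg[[1]]
  seg <- seg[-1]
  while (length(seg) > 0) {
    tail_pt <- cur[nrow(cur), ]
    hit <- NULL
    for (k in seq_along(seg)) {
      s <- seg[[k]]
      if (sum(abs(s[1, ] - tail_pt)) < tol) { hit <- s[-1, , drop = FALSE] }
      else if (sum(abs(s[nrow(s), ] - tail_pt)) < tol) {
        hit <- s[rev(seq_len(nrow(s) - 1)), , drop = FALSE]
      }
      if (!is.null(hit)) { seg <- seg[-k]; break }
    }
    if (is.null(hit)) return(NULL)
    cur <- rbind(cur, hit)
  }
  if (sum(abs(cur[1, ] - cur[nrow(cur), ])) > tol) return(NULL)
  list(x = cur[, 1], y = cur[, 2])
}

#' Extract the cell perimeter from the level set
#'
#' Marching-squares zero contour, ordered counterclockwise and resampled to
#' `n_nodes` equal arc-length nodes.
#'
#' @param grid a [levelset_grid()].
#' @param n_nodes number of perimeter nodes.
#' @return a [perimeter_mesh()].
#' @export
extract_perimeter <- function(grid, n_nodes, smooth_passes = 2) {
  raw <- extract_contour(grid)
  nodes <- raw$nodes
  # damp marching-squares stair-steps (sub-grid noise) before resampling;
  # a 1-2-1 kernel pass removes the node-scale zigzag while moving the
  # contour by far less than the grid error
  for (k in seq_len(smooth_passes)) {
    n <- nrow(nodes)
    nodes <- (nodes[c(n, 1:(n - 1)), ] + 2 * nodes + nodes[c(2:n, 1), ]) / 4
  }
  resample_mesh(perimeter_mesh(nodes, check = FALSE), n_nodes)
}

# Translate the grid so its centre tracks `center`, snapping the shift to
# whole grid cells; phi must be reinitialized from geometry afterwards.
recenter_grid <- function(grid, center) {
  cx <- grid$origin[1] + grid$h * (grid$nx - 1) / 2
  cy <- grid$origin[2] + grid$h * (grid$ny - 1) / 2
  shift <- round((center - c(cx, cy)) / grid$h) * grid$h
  if (all(shift == 0)) return(grid)
  grid$origin <- grid$origin + shift
  grid$x <- grid$x + shift[1]
  grid$y <- grid$y + shift[2]
  grid
}
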