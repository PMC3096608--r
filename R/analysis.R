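#' Detect pseudopods as activator peaks on the perimeter
#'
#' Local maxima of the periodic per-node activator profile that pass height
#' and prominence thresholds; peaks closer than `min_separation` (arc
#' length) are greedily suppressed, keeping the highest (ties broken in
#' favour of the lower arc position).
#'
#' @param a per-node activator.
#' @param mesh the [perimeter_mesh()] carrying `a`.
#' @param min_height absolute height threshold.
#' @param min_prominence absolute prominence threshold (height above the
#'   highest saddle connecting the peak to higher terrain).
#' @param min_separation minimum arc-length separation between reported
#'   peaks.
#' @return data.frame with columns `node`, `arc_pos`, `pos` (arc position
#'   normalized to [0, 1)), `height`, `direction` (degrees, centroid to
#'   peak). Zero rows when nothing qualifies.
#' @export
detect_pseudopods <- function(a, mesh, min_height = 0,
                              min_prominence = 0, min_separation = 0) {
  n <- length(a)
  if (n != nrow(mesh$nodes)) stop("a not aligned with mesh nodes")
  empty <- data.frame(node = integer(), arc_pos = numeric(),
                      pos = numeric(), height = numeric(),
                      direction = numeric())
  prev <- a[c(n, 1:(n - 1))]
  nxt <- a[c(2:n, 1)]
  cand <- which(a > prev & a >= nxt & a >= min_height)
  if (length(cand) == 0) return(empty)
  prom <- vapply(cand, function(i) peak_prominence(a, i), numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]
  if (length(cand) == 0) return(empty)
  # greedy suppression: highest first, lower arc position wins ties
  ord <- order(-a[cand], mesh$arc[cand])
  cand <- cand[ord]
  sel <- integer(0)
  for (i in cand) {
    d <- abs(mesh$arc[i] - mesh$arc[sel])
    d <- pmin(d, mesh$perimeter - d)
    if (length(sel) == 0 || all(d >= min_separation)) sel <- c(sel, i)
  }
  sel <- sort(sel)
  ctr <- polygon_area_centroid(mesh)$centroid
  dirs <- rad2deg(atan2(mesh$nodes[sel, 2] - ctr[2],
                        mesh$nodes[sel, 1] - ctr[1]))
  data.frame(node = sel, arc_pos = mesh$arc[sel],
             pos = mesh$arc[sel] / mesh$perimeter,
             height = a[sel], direction = dirs)
}

# prominence of peak i on a periodic signal: height above the higher of
# the two saddles separating it from higher terrain
peak_prominence <- function(a, i) {
  n <- length(a)
  if (a[i] >= max(a)) return(a[i] - min(a))
  walk <- function(step) {
    lo <- a[i]
    j <- i
    for (k in seq_len(n - 1)) {
      j <- ((j - 1 + step) %% n) + 1
      if (a[j] > a[i]) return(lo)
      lo <- min(lo, a[j])
    }
    lo
  }
  a[i] - max(walk(1L), walk(-1L))
}

circ_dist01 <- function(x, y) {
  d <- abs(x - y) %% 1
  pmin(d, 1 - d)
}

#' Track pseudopods across frames and detect bifurcations
#'
#' Nearest-neighbour matching of peaks between consecutive frames (circular
#' arc distance on the normalized perimeter). A new peak appearing within
#' `matching_radius` of a track that also has a matched continuation is a
#' bifurcation: the parent ends with fate "split" and two daughter tracks
#' begin. Tracks that fail to match end with fate "retracted" ("censored"
#' when still alive at the last frame). Tracks shorter than `min_lifetime`
#' frames are pruned as detection noise; when a pruned track was a
#' bifurcation daughter the sibling is merged back into the parent and the
#' event discarded.
#'
#' @param peak_frames list (one entry per frame, in time order) of
#'   data.frames as returned by [detect_pseudopods()].
#' @param matching_radius maximum frame-to-frame movement, as a fraction of
#'   the perimeter.
#' @param bifurcation_radius maximum distance (fraction of perimeter) from
#'   a continued track at which an appearing peak counts as its bifurcation
#'   daughter rather than a de novo pseudopod; default twice the matching
#'   radius (a split angle of ~55 degrees places the new daughter ~0.15 of
#'   the perimeter from the parent).
#' @param min_lifetime minimum track length in frames.
#' @return list with `tracks` (id, birth_frame, death_frame, parent_id,
#'   fate, birth_direction, birth_pos, max_height), `events` (frame,
#'   parent_id, daughter1, daughter2) and `positions` (long data.frame:
#'   track_id, frame, pos, direction, height).
#' @export
track_pseudopods <- function(peak_frames, matching_radius = 0.1,
                             bifurcation_radius = 2 * matching_radius,
                             min_lifetime = 5) {
  tr <- list()     # each: list(id, birth, death, parent, fate, frames, pos, dir, height)
  events <- list()
  next_id <- 1L
  active <- integer(0)
  new_track <- function(frame, row, parent = NA_integer_) {
    id <- next_id
    next_id <<- next_id + 1L
    tr[[id]] <<- list(id = id, birth = frame, death = frame, parent = parent,
                      fate = "censored", frames = frame, pos = row$pos,
                      dir = row$direction, height = row$height)
    id
  }
  n_frames <- length(peak_frames)
  for (t in seq_len(n_frames)) {
    pk <- peak_frames[[t]]
    np <- if (is.null(pk)) 0L else nrow(pk)
    if (t == 1 || length(active) == 0) {
      active <- if (np > 0) vapply(seq_len(np), function(j)
        new_track(t, pk[j, ]), integer(1)) else integer(0)
      next
    }
    prev_pos <- vapply(active, function(id) {
      k <- length(tr[[id]]$pos); tr[[id]]$pos[k]
    }, numeric(1))
    match_track <- rep(NA_integer_, np)   # peak j -> index into active
    if (np > 0) {
      D <- outer(prev_pos, pk$pos, circ_dist01)
      D[D > matching_radius] <- NA
      while (any(is.finite(D))) {
        ij <- arrayInd(which.min(D), dim(D))
        match_track[ij[2]] <- ij[1]
        D[ij[1], ] <- NA
        D[, ij[2]] <- NA
      }
    }
    matched_active <- stats::na.omit(match_track)
    new_active <- integer(0)
    # continuations
    cont_of <- rep(NA_integer_, length(active))  # peak index continuing track
    for (j in seq_len(np)) {
      if (!is.na(match_track[j])) cont_of[match_track[j]] <- j
    }
    # bifurcations: unmatched peak near a continued track
    bif_extra <- rep(NA_integer_, length(active))
    for (j in seq_len(np)) {
      if (!is.na(match_track[j])) next
      d <- circ_dist01(prev_pos, pk$pos[j])
      d[!is.finite(d)] <- Inf
      cand <- which(d <= bifurcation_radius & !is.na(cont_of) & is.na(bif_extra))
      if (length(cand) > 0) {
        bif_extra[cand[which.min(d[cand])]] <- j
      }
    }
    for (ai in seq_along(active)) {
      id <- active[ai]
      j_cont <- cont_of[ai]
      j_new <- bif_extra[ai]
      if (!is.na(j_cont) && !is.na(j_new)) {
        # split: parent ends at t-1, two daughters born at t
        tr[[id]]$fate <- "split"
        d1 <- new_track(t, pk[j_cont, ], parent = id)
        d2 <- new_track(t, pk[j_new, ], parent = id)
        events[[length(events) + 1]] <- list(frame = t, parent_id = id,
                                             daughter1 = d1, daughter2 = d2)
        new_active <- c(new_active, d1, d2)
      } else if (!is.na(j_cont)) {
        tr[[id]]$death <- t
        tr[[id]]$frames <- c(tr[[id]]$frames, t)
        tr[[id]]$pos <- c(tr[[id]]$pos, pk$pos[j_cont])
        tr[[id]]$dir <- c(tr[[id]]$dir, pk$direction[j_cont])
        tr[[id]]$height <- c(tr[[id]]$height, pk$height[j_cont])
        new_active <- c(new_active, id)
      } else {
        tr[[id]]$fate <- "retracted"
      }
    }
    # unmatched peaks not absorbed by a bifurcation: de novo tracks
    used <- c(stats::na.omit(bif_extra))
    for (j in seq_len(np)) {
      if (is.na(match_track[j]) && !(j %in% used))
        new_active <- c(new_active, new_track(t, pk[j, ]))
    }
    active <- new_active
  }
  for (id in active) tr[[id]]$fate <- "censored"
  prune_and_collect(tr, events, min_lifetime)
}

prune_and_collect <- function(tr, events, min_lifetime) {
  lifetime <- vapply(tr, function(x) x$death - x$birth + 1L, integer(1))
  is_parent <- vapply(tr, function(x) identical(x$fate, "split"), logical(1))
  short <- lifetime < min_lifetime & !is_parent
  # resolve events whose daughters were pruned: merge sibling into parent
  repeat {
    changed <- FALSE
    keep_events <- list()
    for (ev in events) {
      p1 <- short[ev$daughter1]; p2 <- short[ev$daughter2]
      if (!p1 && !p2) { keep_events[[length(keep_events) + 1]] <- ev; next }
      changed <- TRUE
      parent <- ev$parent_id
      if (p1 && p2) {
        tr[[parent]]$fate <- "retracted"
      } else {
        kept <- if (p1) ev$daughter2 else ev$daughter1
        k <- tr[[kept]]
        tr[[parent]]$death <- k$death
        tr[[parent]]$fate <- k$fate
        tr[[parent]]$frames <- c(tr[[parent]]$frames, k$frames)
        tr[[parent]]$pos <- c(tr[[parent]]$pos, k$pos)
        tr[[parent]]$dir <- c(tr[[parent]]$dir, k$dir)
        tr[[parent]]$height <- c(tr[[parent]]$height, k$height)
        # re-point grandchildren at the parent
        for (gi in seq_along(events)) {
          if (identical(events[[gi]]$parent_id, kept))
            events[[gi]]$parent_id <- parent
        }
        for (ti in seq_along(tr)) {
          if (identical(tr[[ti]]$parent, kept)) tr[[ti]]$parent <- parent
        }
        short[kept] <- TRUE  # mark merged daughter as removed
      }
    }
    events <- keep_events
    is_parent <- vapply(tr, function(x) identical(x$fate, "split"), logical(1))
    parents_now <- unique(vapply(events, function(e) e$parent_id, integer(1)))
    for (ti in seq_along(tr)) {
      if (is_parent[ti] && !(tr[[ti]]$id %in% parents_now))
        tr[[ti]]$fate <- "retracted"
    }
    if (!changed) break
  }
  lifetime <- vapply(tr, function(x) x$death - x$birth + 1L, integer(1))
  is_parent <- vapply(tr, function(x) identical(x$fate, "split"), logical(1))
  drop <- (lifetime < min_lifetime & !is_parent) | short
  kept <- Filter(function(x) !drop[x$id], tr)
  tracks <- do.call(rbind, lapply(kept, function(x) data.frame(
    id = x$id, birth_frame = x$birth, death_frame = x$death,
    parent_id = if (!is.na(x$parent) && drop[x$parent]) NA_integer_ else x$parent,
    fate = x$fate, birth_direction = x$dir[1], birth_pos = x$pos[1],
    max_height = max(x$height))))
  positions <- do.call(rbind, lapply(kept, function(x) data.frame(
    track_id = x$id, frame = x$frames, pos = x$pos, direction = x$dir,
    height = x$height)))
  events_df <- if (length(events) == 0)
    data.frame(frame = integer(), parent_id = integer(),
               daughter1 = integer(), daughter2 = integer())
  else do.call(rbind, lapply(events, as.data.frame))
  if (is.null(tracks))
    tracks <- data.frame(id = integer(), birth_frame = integer(),
                         death_frame = integer(), parent_id = integer(),
                         fate = character(), birth_direction = numeric(),
                         birth_pos = numeric(), max_height = numeric())
  list(tracks = tracks, events = events_df,
       positions = positions %||% data.frame(track_id = integer(),
                                             frame = integer(), pos = numeric(),
                                             direction = numeric(),
                                             height = numeric()))
}

#' Direction of a perimeter point seen from the centroid
#'
#' @param arc_pos arc position(s) on the perimeter.
#' @param mesh a [perimeter_mesh()].
#' @param centroid optional centroid (computed from the mesh if missing).
#' @return angle(s) in degrees CCW from +x.
#' @export
pseudopod_direction <- function(arc_pos, mesh, centroid = NULL) {
  centroid <- centroid %||% polygon_area_centroid(mesh)$centroid
  px <- interp_periodic(mesh$arc, mesh$nodes[, 1], mesh$perimeter, arc_pos)
  py <- interp_periodic(mesh$arc, mesh$nodes[, 2], mesh$perimeter, arc_pos)
  dx <- px - centroid[1]; dy <- py - centroid[2]
  if (any(sqrt(dx^2 + dy^2) < 1e-9))
    stop("peak coincides with the centroid; direction undefined")
  rad2deg(atan2(dy, dx))
}

#' Split-angle statistics of bifurcation events
#'
#' For every bifurcation, alpha is the attractant direction relative to the
#' parent pseudopod (at its last frame) and gamma the direction of the
#' dominant daughter (at birth) relative to the parent. The dominant
#' daughter is the one that survives (fate "split", or the longer-lived /
#' higher-peaked one when both are censored). Events are also expressed in
#' the reflected convention in which the attractant always lies
#' counterclockwise from the parent (alpha >= 0): for events with alpha < 0
#' both angles change sign. Two linear fits are returned: signed
#' `gamma_r ~ alpha_r` in the reflected convention, and `|gamma| ~ |alpha|`.
#'
#' @param events,tracks output of [track_pseudopods()].
#' @param gradient_direction attractant direction in degrees.
#' @param baseline_gamma optional unstimulated mean |split angle| used to
#'   locate the zero-bias crossing (the alpha at which the fitted split
#'   angle equals the unstimulated one).
#' @param bin_width width (degrees) of the alpha bins for binned means.
#' @return list with `table` (alpha, gamma, clockwise, alpha_r, gamma_r),
#'   `fit_signed`, `fit_abs` (intercept/slope vectors), `binned`
#'   data.frame, `zero_bias_crossing` (NA unless `baseline_gamma` given),
#'   `mean_abs_gamma`.
#' @export
split_angle_statistics <- function(events, tracks = NULL,
                                   gradient_direction = 0,
                                   baseline_gamma = NULL, bin_width = 20) {
  if (is.list(events) && !is.data.frame(events) && !is.null(events$events)) {
    tracking <- events
    events <- tracking$events
    tracks <- tracking$tracks
    attr(tracks, "positions") <- tracking$positions
  }
  if (nrow(events) == 0)
    return(list(table = data.frame(), fit_signed = NULL, fit_abs = NULL,
                binned = data.frame(), zero_bias_crossing = NA_real_,
                mean_abs_gamma = NA_real_))
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    d1 <- tracks[tracks$id == ev$daughter1, ]
    d2 <- tracks[tracks$id == ev$daughter2, ]
    if (nrow(d1) == 0 || nrow(d2) == 0) return(NULL)
    dom <- dominant_daughter(d1, d2)
    parent_dir <- parent_direction(ev$parent_id, tracks, events)
    if (is.na(parent_dir)) return(NULL)
    gamma <- angle_diff(dom$birth_direction, parent_dir)
    alpha <- angle_diff(gradient_direction, parent_dir)
    data.frame(frame = ev$frame, parent_id = ev$parent_id,
               dominant_id = dom$id, alpha = alpha, gamma = gamma,
               clockwise = gamma < 0)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0)
    return(list(table = data.frame(), fit_signed = NULL, fit_abs = NULL,
                binned = data.frame(), zero_bias_crossing = NA_real_,
                mean_abs_gamma = NA_real_))
  refl <- tab$alpha < 0
  tab$alpha_r <- ifelse(refl, -tab$alpha, tab$alpha)
  tab$gamma_r <- ifelse(refl, -tab$gamma, tab$gamma)
  fit_s <- stats::coef(stats::lm(gamma_r ~ alpha_r, data = tab))
  fit_a <- stats::coef(stats::lm(abs(gamma) ~ abs(alpha), data = tab))
  brk <- seq(0, 180 + bin_width, by = bin_width)
  bin <- cut(tab$alpha_r, brk, right = FALSE)
  binned <- do.call(rbind, lapply(split(tab, bin), function(d) {
    if (nrow(d) == 0) return(NULL)
    data.frame(alpha_mid = mean(d$alpha_r), n = nrow(d),
               mean_gamma = circular_mean_sd(d$gamma_r)$mean,
               mean_abs_gamma = mean(abs(d$gamma)))
  }))
  zbc <- NA_real_
  if (!is.null(baseline_gamma) && abs(fit_s[2]) > 1e-12)
    zbc <- (baseline_gamma - fit_s[1]) / fit_s[2]
  list(table = tab, fit_signed = fit_s, fit_abs = fit_a,
       binned = binned %||% data.frame(),
       zero_bias_crossing = unname(zbc),
       mean_abs_gamma = mean(abs(tab$gamma)))
}

dominant_daughter <- function(d1, d2) {
  s1 <- d1$fate == "split"; s2 <- d2$fate == "split"
  if (s1 != s2) return(if (s1) d1 else d2)
  r1 <- d1$fate == "retracted"; r2 <- d2$fate == "retracted"
  if (r1 != r2) return(if (r2) d1 else d2)   # survivor dominates
  l1 <- d1$death_frame - d1$birth_frame
  l2 <- d2$death_frame - d2$birth_frame
  if (l1 != l2) return(if (l1 > l2) d1 else d2)
  if (d1$max_height >= d2$max_height) d1 else d2
}

# direction of the parent pseudopod at its last frame before the split
parent_direction <- function(parent_id, tracks, events, positions = NULL) {
  p <- tracks[tracks$id == parent_id, ]
  if (nrow(p) == 0) return(NA_real_)
  pos <- attr(tracks, "positions")
  if (!is.null(pos)) {
    pp <- pos[pos$track_id == parent_id, ]
    if (nrow(pp) > 0) return(pp$direction[which.max(pp$frame)])
  }
  p$last_direction %||% p$birth_direction
}

#' Chemotaxis index of a centroid trajectory
#'
#' Net displacement projected on the gradient direction divided by total
#' path length; 1 for a straight path up-gradient, -1 straight
#' down-gradient.
#'
#' @param trajectory data.frame with columns `x`, `y` (frame order).
#' @param gradient_direction gradient direction in degrees.
#' @export
chemotaxis_index <- function(trajectory, gradient_direction) {
  if (nrow(trajectory) < 2) stop("trajectory needs at least 2 frames")
  dx <- diff(trajectory$x); dy <- diff(trajectory$y)
  path <- sum(sqrt(dx^2 + dy^2))
  if (path == 0) {
    warning("zero path length; chemotaxis index undefined")
    return(NA_real_)
  }
  u <- unit_vector(gradient_direction)
  net <- c(trajectory$x[nrow(trajectory)] - trajectory$x[1],
           trajectory$y[nrow(trajectory)] - trajectory$y[1])
  sum(net * u) / path
}

#' Kymograph of perimeter activator
#'
#' Unwraps each frame's perimeter from polar to Cartesian: the activator is
#' averaged over `n_bins` equal angular sectors around the centroid,
#' anchored at the fixed laboratory angle -180 degrees. Perimeters that are
#' not star-shaped with respect to their centroid fall back to arc-length
#' binning (flagged in the `fallback` attribute).
#'
#' @param frames list of lists with elements `mesh` and `a`.
#' @param n_bins number of angular bins.
#' @return n_frames x n_bins matrix.
#' @export
kymograph <- function(frames, n_bins = 72) {
  edges <- seq(-180, 180, length.out = n_bins + 1)
  out <- matrix(NA_real_, length(frames), n_bins)
  fallback <- logical(length(frames))
  for (t in seq_along(frames)) {
    mesh <- frames[[t]]$mesh
    a <- frames[[t]]$a
    ctr <- polygon_area_centroid(mesh)$centroid
    rel <- sweep(mesh$nodes, 2, ctr)
    star <- all((rel[, 1] * c(rel[-1, 2], rel[1, 2]) -
                   rel[, 2] * c(rel[-1, 1], rel[1, 1])) > 0)
    if (star) {
      th <- rad2deg(atan2(rel[, 2], rel[, 1]))
      bin <- findInterval(th, edges, rightmost.closed = TRUE)
      v <- tapply(a, factor(bin, levels = seq_len(n_bins)), mean)
      out[t, ] <- fill_gaps_circular(as.numeric(v))
    } else {
      fallback[t] <- TRUE
      # anchor arc position 0 at the node closest to lab angle -180
      th <- rad2deg(atan2(rel[, 2], rel[, 1]))
      anchor <- which.min(abs(wrap_angle(th - 180)))
      s0 <- mesh$arc[anchor]
      pos <- ((mesh$arc - s0) %% mesh$perimeter) / mesh$perimeter
      bin <- pmin(floor(pos * n_bins) + 1, n_bins)
      v <- tapply(a, factor(bin, levels = seq_len(n_bins)), mean)
      out[t, ] <- fill_gaps_circular(as.numeric(v))
    }
  }
  if (any(fallback))
    message(sum(fallback), " frame(s) not star-shaped; arc-length unwrap used")
  attr(out, "fallback") <- fallback
  out
}

fill_gaps_circular <- function(v) {
  if (!anyNA(v)) return(v)
  n <- length(v)
  idx <- which(!is.na(v))
  if (length(idx) == 0) return(rep(0, n))
  x <- c(idx - n, idx, idx + n)
  y <- rep(v[idx], 3)
  stats::approx(x, y, xout = seq_len(n))$y
}

#' Circular mean, standard deviation and resultant length
#'
#' @param angles angles in degrees.
#' @return list with `mean` (degrees), `sd` (degrees,
#'   `sqrt(-2 log R)` convention), `resultant` (mean resultant length R in
#'   [0, 1]) and `reliable` (FALSE when R < 0.05).
#' @export
circular_mean_sd <- function(angles) {
  if (length(angles) < 1) stop("need at least one angle")
  th <- deg2rad(angles)
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  m <- rad2deg(atan2(S, C))
  sdv <- if (R > 0) rad2deg(sqrt(-2 * log(R))) else Inf
  list(mean = m, sd = sdv, resultant = R, reliable = R >= 0.05)
}

#' Pseudopod fate histogram by birth direction
#'
#' Histogram of pseudopod birth directions relative to the gradient,
#' partitioned by fate (split vs retracted); censored tracks are excluded.
#'
#' @param tracks track table from [track_pseudopods()].
#' @param gradient_direction gradient direction in degrees.
#' @param bin_width bin width in degrees (must divide 360).
#' @return data.frame with `bin_mid`, `total`, `split`, `retracted`.
#' @export
fate_by_direction_histogram <- function(tracks, gradient_direction = 0,
                                        bin_width = 30) {
  edges <- seq(-180, 180, by = bin_width)
  mids <- edges[-1] - bin_width / 2
  out <- data.frame(bin_mid = mids, total = 0L, split = 0L, retracted = 0L)
  use <- tracks[tracks$fate %in% c("split", "retracted"), , drop = FALSE]
  if (nrow(use) > 0) {
    rel <- angle_diff(use$birth_direction, gradient_direction)
    bin <- findInterval(rel, edges, rightmost.closed = TRUE)
    for (i in seq_len(nrow(use))) {
      b <- bin[i]
      out$total[b] <- out$total[b] + 1L
      if (use$fate[i] == "split") out$split[b] <- out$split[b] + 1L
      else out$retracted[b] <- out$retracted[b] + 1L
    }
  }
  out
}
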