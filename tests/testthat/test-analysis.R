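test_that("peak detection finds isolated bumps and ignores flat profiles", {
  mesh <- ring_mesh(5, 200)
  bump <- gaussian_profile(mesh, 0.25, height = 2, base = 0.1)
  pk <- detect_pseudopods(bump, mesh, min_height = 0.5,
                          min_prominence = 0.2,
                          min_separation = 0.1 * mesh$perimeter)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$pos, 0.25, tolerance = 0.01)
  expect_equal(pk$direction, 90, tolerance = 2)  # bump at the top of the circle

  expect_equal(nrow(detect_pseudopods(rep(1, 200), mesh)), 0)

  two <- gaussian_profile(mesh, 0.2, 2) + gaussian_profile(mesh, 0.6, 2)
  pk2 <- detect_pseudopods(two, mesh, 0.5, 0.2, 0.1 * mesh$perimeter)
  expect_equal(nrow(pk2), 2)
})

test_that("close peaks are suppressed keeping the highest", {
  mesh <- ring_mesh(5, 200)
  a <- gaussian_profile(mesh, 0.50, 2, width_frac = 0.02) +
    gaussian_profile(mesh, 0.54, 1.2, width_frac = 0.02)
  pk <- detect_pseudopods(a, mesh, 0.5, 0.1, 0.1 * mesh$perimeter)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$pos, 0.50, tolerance = 0.01)
})

test_that("a drifting peak yields a single track and no events", {
  frames <- lapply(0:49, function(t) peak_frame(0.2 + 0.005 * t))
  res <- track_pseudopods(frames, matching_radius = 0.05)
  expect_equal(nrow(res$tracks), 1)
  expect_equal(nrow(res$events), 0)
  expect_equal(res$tracks$birth_frame, 1)
  expect_equal(res$tracks$death_frame, 50)
  expect_equal(res$tracks$fate, "censored")
})

test_that("a one-to-two transition is recorded as a bifurcation", {
  frames <- c(
    lapply(1:49, function(t) peak_frame(0.5)),
    lapply(1:30, function(t) peak_frame(c(0.5 - 0.002 * t, 0.5 + 0.004 * t)))
  )
  res <- track_pseudopods(frames, matching_radius = 0.05)
  expect_equal(nrow(res$events), 1)
  expect_equal(res$events$frame, 50)
  parent <- res$tracks[res$tracks$id == res$events$parent_id, ]
  expect_equal(parent$fate, "split")
  expect_equal(parent$birth_frame, 1)
  daughters <- res$tracks[!is.na(res$tracks$parent_id), ]
  expect_equal(nrow(daughters), 2)
  expect_true(all(daughters$parent_id == parent$id))
  expect_true(all(daughters$birth_frame == 50))
})

test_that("a vanishing peak ends its track with fate retracted", {
  frames <- c(lapply(1:30, function(t) peak_frame(0.4)),
              lapply(1:20, function(t) empty_peaks()))
  res <- track_pseudopods(frames, matching_radius = 0.05)
  expect_equal(nrow(res$tracks), 1)
  expect_equal(res$tracks$death_frame, 30)
  expect_equal(res$tracks$fate, "retracted")
})

test_that("sub-minimum-lifetime tracks are pruned as noise", {
  frames <- c(lapply(1:30, function(t) peak_frame(0.4)),
              list(peak_frame(c(0.4, 0.8))),   # 1-frame flicker far away
              lapply(1:10, function(t) peak_frame(0.4)))
  res <- track_pseudopods(frames, matching_radius = 0.05, min_lifetime = 5)
  expect_equal(nrow(res$tracks), 1)
  expect_equal(res$tracks$death_frame, 41)
})

test_that("tracking is deterministic", {
  set.seed(3)
  frames <- lapply(1:60, function(t)
    peak_frame(sort(stats::runif(sample(0:3, 1)))))
  r1 <- track_pseudopods(frames, 0.08)
  r2 <- track_pseudopods(frames, 0.08)
  expect_identical(r1, r2)
})

test_that("pseudopod direction is the centroid-to-peak angle", {
  mesh <- ring_mesh(5, 256)
  expect_equal(pseudopod_direction(0, mesh), 0, tolerance = 0.5)
  expect_equal(pseudopod_direction(mesh$perimeter / 4, mesh), 90,
               tolerance = 0.5)
  # rotating the geometry rotates the answer
  th <- pi / 5
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- perimeter_mesh(mesh$nodes %*% t(Rm), check = FALSE)
  d0 <- pseudopod_direction(2.3, mesh)
  d1 <- pseudopod_direction(2.3, rot)
  expect_equal(wrap_angle(d1 - d0), 36, tolerance = 0.5)
})

test_that("split-angle table reproduces constructed event geometry", {
  # one parent heading 0, dominant daughter at +40: gamma = 40
  tracks <- data.frame(
    id = 1:3, birth_frame = c(1, 50, 50), death_frame = c(49, 120, 70),
    parent_id = c(NA, 1, 1), fate = c("split", "censored", "retracted"),
    birth_direction = c(0, 40, -25), birth_pos = c(0.5, 0.55, 0.45),
    max_height = c(2, 2, 1))
  positions <- data.frame(track_id = 1, frame = 49, pos = 0.5,
                          direction = 0, height = 2)
  events <- data.frame(frame = 50, parent_id = 1, daughter1 = 2,
                       daughter2 = 3)
  attr(tracks, "positions") <- positions
  st <- split_angle_statistics(events, tracks, gradient_direction = 90)
  expect_equal(st$table$gamma, 40)
  expect_equal(st$table$alpha, 90)
  expect_false(st$table$clockwise)
  # gradient on the other side: alpha flips sign, mirrored convention
  st2 <- split_angle_statistics(events, tracks, gradient_direction = -90)
  expect_equal(st2$table$alpha, -90)
  expect_equal(st2$table$alpha_r, 90)
  expect_equal(st2$table$gamma_r, -40)
})

test_that("split-angle fit recovers a planted alpha-gamma relation", {
  set.seed(21)
  n <- 400
  alpha <- stats::runif(n, -180, 180)
  gamma <- sign(alpha) * (30 + abs(alpha) / 3) + stats::rnorm(n, 0, 8)
  tracks_list <- list()
  events <- data.frame(frame = integer(), parent_id = integer(),
                       daughter1 = integer(), daughter2 = integer())
  positions <- data.frame(track_id = integer(), frame = integer(),
                          pos = numeric(), direction = numeric(),
                          height = numeric())
  id <- 0
  for (i in seq_len(n)) {
    parent_dir <- stats::runif(1, -180, 180)
    p <- id + 1; d1 <- id + 2; d2 <- id + 3; id <- id + 3
    tracks_list[[i]] <- data.frame(
      id = c(p, d1, d2), birth_frame = c(1, 50, 50),
      death_frame = c(49, 200, 60), parent_id = c(NA, p, p),
      fate = c("split", "censored", "retracted"),
      birth_direction = c(parent_dir,
                          parent_dir + gamma[i],
                          parent_dir - gamma[i]),
      birth_pos = 0.5, max_height = 1)
    events <- rbind(events, data.frame(frame = 50, parent_id = p,
                                       daughter1 = d1, daughter2 = d2))
    positions <- rbind(positions, data.frame(track_id = p, frame = 49,
                                             pos = 0.5,
                                             direction = parent_dir,
                                             height = 1))
    # gradient fixed at 0 means alpha = -parent_dir; plant the relation
    # by choosing parent_dir = -alpha[i]
    tracks_list[[i]]$birth_direction <- c(-alpha[i],
                                          -alpha[i] + gamma[i],
                                          -alpha[i] - gamma[i])
    positions$direction[nrow(positions)] <- -alpha[i]
  }
  tracks <- do.call(rbind, tracks_list)
  attr(tracks, "positions") <- positions
  st <- split_angle_statistics(events, tracks, gradient_direction = 0)
  # reflected-convention fit: gamma_r = 30 + alpha_r / 3
  expect_equal(unname(st$fit_signed[2]), 1 / 3, tolerance = 0.05)
  expect_equal(unname(st$fit_signed[1]), 30, tolerance = 3)
  # zero-bias crossing against a 55-degree baseline: alpha = (55-30)*3 = 75
  st2 <- split_angle_statistics(events, tracks, gradient_direction = 0,
                                baseline_gamma = 55)
  expect_equal(st2$zero_bias_crossing, 75, tolerance = 8)
})

test_that("chemotaxis index is signed projection over path length", {
  up <- data.frame(x = 0:10, y = rep(0, 11))
  expect_equal(chemotaxis_index(up, 0), 1)
  expect_equal(chemotaxis_index(up, 180), -1)
  th <- seq(0, 2 * pi, length.out = 400)
  circle <- data.frame(x = cos(th), y = sin(th))
  expect_lt(abs(chemotaxis_index(circle, 0)), 1 / 100)
  expect_warning(ci <- chemotaxis_index(data.frame(x = c(1, 1), y = c(2, 2)), 0),
                 "zero path")
  expect_true(is.na(ci))
})

test_that("kymograph unwraps static and rotating peaks as expected stripes", {
  mesh <- ring_mesh(5, 200)
  static <- lapply(1:30, function(t)
    list(mesh = mesh, a = gaussian_profile(mesh, 0.25, 2)))
  km <- kymograph(static, n_bins = 72)
  expect_equal(dim(km), c(30, 72))
  cols <- apply(km, 1, which.max)
  expect_equal(length(unique(cols)), 1)
  rotating <- lapply(1:30, function(t)
    list(mesh = mesh, a = gaussian_profile(mesh, (0.25 + 0.01 * t) %% 1, 2)))
  km2 <- kymograph(rotating, n_bins = 100)
  cols2 <- apply(km2, 1, which.max)
  steps <- diff(cols2) %% 100
  expect_true(all(steps %in% c(0, 1, 2)))     # monotone drift, ~1 bin/frame
  expect_equal(mean(steps), 1, tolerance = 0.2)
})

test_that("circular statistics handle wrap-around and dispersion flags", {
  cs <- circular_mean_sd(c(10, 350))
  expect_equal(wrap_angle(cs$mean), 0, tolerance = 1e-9)
  cs2 <- circular_mean_sd(c(90, 90))
  expect_equal(cs2$mean, 90)
  expect_equal(cs2$sd, 0)
  expect_true(cs2$reliable)
  cs3 <- circular_mean_sd(c(0, 90, 180, 270))
  expect_lt(cs3$resultant, 1e-9)
  expect_false(cs3$reliable)
})

test_that("fate histogram partitions non-censored tracks", {
  tracks <- data.frame(
    id = 1:5, birth_frame = 1, death_frame = 10, parent_id = NA,
    fate = c("split", "split", "retracted", "censored", "retracted"),
    birth_direction = c(5, 10, 150, 20, -170), birth_pos = 0.1,
    max_height = 1)
  h <- fate_by_direction_histogram(tracks, gradient_direction = 0,
                                   bin_width = 30)
  expect_equal(sum(h$split) + sum(h$retracted), 4)   # censored excluded
  expect_equal(sum(h$total), 4)
  expect_equal(h$split[h$bin_mid == 15], 2)
  h0 <- fate_by_direction_histogram(tracks[0, ], 0, 30)
  expect_true(all(h0$total == 0))
})
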