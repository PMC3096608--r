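test_that("linear gradients reproduce the across-the-cell end concentrations", {
  # 5.3 nM at the rear edge, 6.5 nM at the front edge, one diameter apart
  spec <- stimulus_spec("linear", reference_concentration = 5.9,
                        gradient_vector = c(0.12, 0), reference_point = c(0, 0))
  expect_equal(concentration_at(c(-5, 0), 10, spec), 5.3)
  expect_equal(concentration_at(c(5, 0), 10, spec), 6.5)
  # concentrations clip at zero rather than going negative
  expect_equal(concentration_at(c(-100, 0), 10, spec), 0)
})

test_that("no-stimulus and pre-onset cases give zero concentration", {
  expect_equal(concentration_at(c(3, 4), 5, stimulus_spec("none")), 0)
  spec <- stimulus_spec("uniform_step", reference_concentration = 10,
                        onset_time = 100)
  expect_equal(concentration_at(c(0, 0), 99, spec), 0)
  expect_equal(concentration_at(c(0, 0), 100, spec), 10)
})

test_that("point-source concentrations follow the documented radial law", {
  spec <- stimulus_spec("point_source", reference_concentration = 8,
                        source_position = c(0, 0), source_scale = 5)
  r1 <- 10; r2 <- 20
  c1 <- concentration_at(c(r1, 0), 0, spec)
  c2 <- concentration_at(c(0, r2), 0, spec)
  # direct evaluation of the 1/r profile beyond the plateau
  expect_equal(c1, 8 / (r1 / 5))
  expect_equal(c2 / c1, r1 / r2)
  # plateau inside one source_scale
  expect_equal(concentration_at(c(1, 0), 0, spec), 8)
})

test_that("receptor occupancy is hyperbolic, monotone and bounded", {
  expect_equal(receptor_occupancy(0, 30), 0)
  expect_equal(receptor_occupancy(30, 30), 0.5)
  expect_error(receptor_occupancy(-1, 30), ">= 0")
  set.seed(7)
  for (i in 1:20) {
    Kd <- stats::runif(1, 0.1, 100)
    C <- sort(stats::runif(50, 0, 1000))
    y <- receptor_occupancy(C, Kd)
    expect_true(all(y >= 0 & y <= 1))
    expect_true(all(diff(y) > 0))
  }
})

test_that("steep-gradient preset spans 0 to 20% occupancy across the cell", {
  cfg <- preset("steep_gradient")
  Kd <- cfg$model$signal$occupancy_Kd
  occ_rear <- receptor_occupancy(
    concentration_at(c(-5, 0), 1, cfg$stimulus), Kd)
  occ_front <- receptor_occupancy(
    concentration_at(c(5, 0), 1, cfg$stimulus), Kd)
  expect_equal(occ_rear, 0, tolerance = 1e-8)
  expect_equal(occ_front, 0.20, tolerance = 1e-8)
})

test_that("gradient-panel occupancy differences increase with steepness", {
  panel <- preset("gradient_panel")
  expect_length(panel, 4)
  Kd <- panel[[1]]$model$signal$occupancy_Kd
  fronts <- vapply(panel, function(cfg)
    concentration_at(c(5, 0), 1, cfg$stimulus), numeric(1))
  expect_equal(fronts, c(5.5, 5.7, 6.1, 6.6))
  rears <- vapply(panel, function(cfg)
    concentration_at(c(-5, 0), 1, cfg$stimulus), numeric(1))
  expect_equal(rears, rep(5.3, 4))
  docc <- receptor_occupancy(fronts, Kd) - receptor_occupancy(rears, Kd)
  expect_true(all(diff(docc) > 0))
})

test_that("receptor adaptation decays exponentially from onset", {
  expect_equal(adapted_occupancy(0.8, 50, 50, 30), 0.8)
  expect_equal(adapted_occupancy(0.8, 80, 50, 30), 0.8 * exp(-1))
  expect_equal(adapted_occupancy(0.8, 1e7, 50, 30), 0)
  # pre-onset returns the pre-stimulus value 0, not an error
  expect_equal(adapted_occupancy(0.8, 10, 50, 30), 0)
  expect_error(adapted_occupancy(0.8, 60, 50, -1), "tau")
})

test_that("gradient reorientation points the stimulus off the heading", {
  spec <- stimulus_spec("linear", reference_concentration = 6,
                        gradient_vector = c(0.17, 0))
  r1 <- reorient_gradient(spec, cell_heading = 0, offset = 90)
  expect_equal(r1$gradient_vector, 0.17 * c(0, 1), tolerance = 1e-12)
  # zero offset is the identity
  r0 <- reorient_gradient(spec, cell_heading = 0, offset = 0)
  expect_equal(r0$gradient_vector, spec$gradient_vector, tolerance = 1e-12)
  # offsets are relative to the heading, not cumulative
  r2 <- reorient_gradient(r1, cell_heading = 0, offset = 90)
  expect_equal(r2$gradient_vector, r1$gradient_vector, tolerance = 1e-12)
  # magnitude is preserved at any angle
  r3 <- reorient_gradient(spec, cell_heading = 37.5, offset = 90)
  expect_equal(sqrt(sum(r3$gradient_vector^2)), 0.17)
  expect_warning(reorient_gradient(stimulus_spec("none"), 0, 90), "no-op")
})

test_that("noise-free signal is a pure deterministic function", {
  prm <- signal_params(autocatalysis_noise_amplitude = 0,
                       receptor_noise_amplitude = 0)
  a <- c(0, 1, 5); y <- c(0, 0, 0)
  s1 <- signal_field(y, a, prm)
  set.seed(99)
  s2 <- signal_field(y, a, prm)
  expect_identical(s1, s2)
  expect_equal(s1, prm$baseline + prm$autocatalysis_coupling * a)
  # occupancy raises the signal through its own component
  s_occ <- signal_field(rep(0.5, 3), a, prm)
  expect_equal(s_occ - s1, rep(prm$occupancy_coupling * 0.5, 3))
})

test_that("signal noise is seed-reproducible and unbiased", {
  prm <- signal_params()
  a <- rep(2, 8); y <- rep(0.3, 8)
  set.seed(11); s1 <- signal_field(y, a, prm)
  set.seed(11); s2 <- signal_field(y, a, prm)
  expect_identical(s1, s2)
  # Monte-Carlo mean approaches the noise-free value within 3 SE
  prm0 <- signal_params(autocatalysis_noise_amplitude = 0,
                        receptor_noise_amplitude = 0)
  s_det <- signal_field(0.3, 2, prm0)
  set.seed(12)
  draws <- replicate(1e4, signal_field(0.3, 2, prm))
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - s_det), 3 * se)
})

test_that("mismatched node sets are rejected by signal_field", {
  expect_error(signal_field(c(0.1, 0.2), c(1, 2, 3), signal_params()),
               "same node set")
})

test_that("scheduled stimuli require a positive reorientation interval", {
  expect_error(stimulus_spec("scheduled", reorientation_interval = 0),
               "positive")
  sp <- stimulus_spec("scheduled", reference_concentration = 6,
                      gradient_vector = c(0.1, 0),
                      reorientation_interval = 200)
  expect_equal(sp$reorientation_interval, 200)
})
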