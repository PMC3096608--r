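test_that("P1 operators on a ring reproduce the Laplace-Beltrami spectrum", {
  mesh <- ring_mesh(5, 256)
  ops <- assemble_operators(mesh)
  # mass encodes length, stiffness annihilates constants
  expect_equal(sum(ops$M), mesh$perimeter, tolerance = 1e-12)
  expect_lt(max(abs(as.numeric(ops$K %*% rep(1, 256)))), 1e-12)
  expect_true(Matrix::isSymmetric(ops$M))
  expect_true(Matrix::isSymmetric(ops$K))
  # smallest nonzero generalized eigenvalue vs (2 pi / L)^2
  ev <- sort(Re(eigen(solve(as.matrix(ops$M), as.matrix(ops$K)),
                      only.values = TRUE)$values))
  expect_equal(ev[2], (2 * pi / mesh$perimeter)^2, tolerance = 0.01)
})

test_that("mass-matrix total equals perimeter on random star polygons", {
  set.seed(42)
  for (i in 1:5) {
    th <- sort(stats::runif(40, 0, 2 * pi))
    r <- 3 + stats::runif(40, -0.8, 0.8)
    mesh <- perimeter_mesh(cbind(r * cos(th), r * sin(th)))
    ops <- assemble_operators(mesh)
    expect_equal(sum(ops$M), mesh$perimeter, tolerance = 1e-12)
  }
})

test_that("degenerate meshes are rejected by the assembler", {
  nodes <- ring_mesh(1, 16)$nodes
  nodes[2, ] <- nodes[1, ]
  expect_error(perimeter_mesh(nodes), "degenerate")
})

test_that("reaction terms reduce correctly in limiting cases", {
  p <- model_params()
  n <- 16
  # a = 0: only basal production survives; c decays freely
  rt <- reaction_terms(rep(0, n), 1, rep(2, n), rep(1.5, n), p)
  expect_equal(rt$da,
               rep(1.5 * p$basal_production / (p$inhibitor_offset + 2), n))
  expect_equal(rt$dc, rep(-p$r_c * 2, n))
  # raising c never raises activator production
  a <- rep(3, n); s <- rep(1, n)
  da_lo <- reaction_terms(a, 3, rep(1, n), s, p)$da
  da_hi <- reaction_terms(a, 3, rep(4, n), s, p)$da
  expect_true(all(da_hi <= da_lo))
  # global inhibitor relaxes toward the mean of a
  expect_gt(reaction_terms(a, 1, rep(1, n), s, p)$db, 0)
  expect_lt(reaction_terms(a, 5, rep(1, n), s, p)$db, 0)
})

test_that("uniform steady state is an exact root, cross-checked by polyroot", {
  p <- model_params()
  s0 <- 1.3
  ss <- uniform_steady_state(p, s0)
  expect_equal(ss$b, ss$a)
  expect_equal(ss$c, p$b_c / p$r_c * ss$a)
  rt <- reaction_terms(rep(ss$a, 8), ss$b, rep(ss$c, 8), rep(s0, 8), p)
  expect_lt(max(abs(c(rt$da, rt$db, rt$dc))), 1e-10)
  # independent oracle: the steady state is a root of a quartic
  k <- p$b_c / p$r_c
  sa <- p$activator_saturation
  coefs <- c(-s0 * p$basal_production,
             p$r_a * p$inhibitor_offset - s0,
             p$r_a * k,
             p$r_a * p$inhibitor_offset * sa,
             p$r_a * k * sa)
  roots <- polyroot(coefs)
  real_pos <- Re(roots[abs(Im(roots)) < 1e-8 & Re(roots) > 0])
  expect_true(any(abs(real_pos - ss$a) < 1e-6))
})

test_that("semi-implicit diffusion step matches the heat-equation decay rate", {
  n <- 256
  mesh <- ring_mesh(5, n)
  wavenum <- 4
  kk <- 2 * pi * wavenum / mesh$perimeter
  # reactions switched off by vanishing rates; signal zero
  p <- model_params(D_a = 0.06, r_a = 1e-14, b_c = 1e-14, r_c = 1e-14,
                    basal_production = 0)
  a0 <- 1 + 0.5 * cos(wavenum * 2 * pi * mesh$arc / mesh$perimeter)
  f <- surface_fields(a0, rep(0, n), 1)
  ops <- prepare_stepper(mesh, p, dt = 1)
  nstep <- 50
  for (i in seq_len(nstep))
    f <- step_fields(f, mesh, rep(0, n), p, dt = 1, ops = ops)
  amp <- (max(f$a) - min(f$a)) / 2
  expect_equal(amp, 0.5 * exp(-p$D_a * kk^2 * nstep), tolerance = 0.05)
})

test_that("diffusion step is unconditionally stable across two decades of dt", {
  n <- 64
  mesh <- ring_mesh(5, n)
  p <- model_params(D_a = 0.5, r_a = 1e-14, b_c = 1e-14, r_c = 1e-14,
                    basal_production = 0)
  a0 <- gaussian_profile(mesh, 0.5, height = 10)
  for (dt in c(0.1, 1, 10)) {
    f <- surface_fields(a0, rep(0, n), 1)
    ops <- prepare_stepper(mesh, p, dt = dt)
    for (i in 1:30) f <- step_fields(f, mesh, rep(0, n), p, dt = dt, ops = ops)
    expect_true(all(is.finite(f$a)))
    expect_lte(max(f$a), max(a0) + 1e-9)
  }
})

test_that("uniform steady state is preserved by the full stepper", {
  n <- 64
  mesh <- ring_mesh(5, n)
  p <- model_params()
  s0 <- p$signal$baseline
  ss <- uniform_steady_state(p, s0)
  f <- surface_fields(rep(ss$a, n), rep(ss$c, n), ss$b)
  ops <- prepare_stepper(mesh, p)
  for (i in 1:1000) f <- step_fields(f, mesh, rep(s0, n), p, ops = ops)
  expect_lt(max(abs(f$a - ss$a)), 1e-6)
  expect_lt(max(abs(f$c - ss$c)), 1e-6)
  expect_lt(abs(f$b - ss$b), 1e-6)
})

test_that("scalar global inhibitor moves toward the perimeter mean", {
  n <- 32
  mesh <- ring_mesh(5, n)
  p <- model_params()
  f <- surface_fields(rep(2, n), rep(1, n), 0.5)   # b below mean(a) = 2
  f2 <- step_fields(f, mesh, rep(1, n), p)
  expect_gt(f2$b, f$b)
})

test_that("conservative transfer dilutes stretched elements and conserves mass", {
  mesh <- ring_mesh(5, 128)
  f <- surface_fields(rep(2, 128), rep(1, 128), 1)
  # identity transfer
  f_id <- transfer_fields(mesh, mesh, f)
  expect_equal(f_id$a, f$a, tolerance = 1e-9)
  # uniform dilation by 1.1: values divided by 1.1, integral conserved
  big <- ring_mesh(5.5, 128)
  f_big <- transfer_fields(mesh, big, f)
  expect_equal(f_big$a, rep(2 / 1.1, 128), tolerance = 0.01)
  int0 <- sum(f$a * pseudotax:::node_weights(mesh))
  int1 <- sum(f_big$a * pseudotax:::node_weights(big))
  expect_equal(int1, int0, tolerance = 0.01)
  # gaussian bump, mesh refined 2x: line integral conserved within 1%
  bump <- surface_fields(gaussian_profile(mesh, 0.3, height = 5), rep(0, 128), 1)
  fine <- ring_mesh(5, 256)
  bump2 <- transfer_fields(mesh, fine, bump)
  ib0 <- sum(bump$a * pseudotax:::node_weights(mesh))
  ib1 <- sum(bump2$a * pseudotax:::node_weights(fine))
  expect_equal(ib1, ib0, tolerance = 0.01)
})

test_that("transfer refuses grossly dissimilar meshes", {
  a <- ring_mesh(5, 64)
  b <- ring_mesh(5, 64, center = c(40, 0))
  f <- surface_fields(rep(1, 64), rep(1, 64), 1)
  expect_error(transfer_fields(a, b, f), "dissimilar")
})
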