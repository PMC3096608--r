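# shared fixtures: small geometric and synthetic-movie builders, plus a
# cache so expensive smoke simulations run once per test session

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, maker) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- maker()
  .run_cache[[key]]
}

smoke_random_run <- function() {
  cached_run("random", function() {
    cfg <- preset("random_migration", smoke = TRUE)
    cfg$frames <- 600
    run_simulation(cfg)
  })
}

# periodic gaussian bump profile on a mesh: height at arc-position centre
gaussian_profile <- function(mesh, centre_frac, height = 1, width_frac = 0.05,
                             base = 0) {
  d <- abs(mesh$arc / mesh$perimeter - centre_frac)
  d <- pmin(d, 1 - d)
  base + height * exp(-(d / width_frac)^2 / 2)
}

# synthetic peak movie: list of per-frame peak tables in the format
# produced by detect_pseudopods (normalized positions)
peak_frame <- function(pos, height = rep(1, length(pos)),
                       direction = pos * 360 - 180) {
  data.frame(node = seq_along(pos), arc_pos = pos, pos = pos,
             height = height, direction = direction)
}

empty_peaks <- function() peak_frame(numeric(0))
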