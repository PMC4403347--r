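test_that("displacement series are signed offsets from frame 0", {
  ts <- simple_ts(c(0, 50), n_frames = 11, vy = c(0, 1))
  d <- displacements(ts)
  expect_equal(d$dy[d$cell_id == "s01"], rep(0, 11))
  expect_equal(d$dy[d$cell_id == "s02" & d$frame == 10], 10)
  expect_equal(d$dx, rep(0, 22))
  expect_true(all(d$dy[d$frame == 0] == 0))
})

test_that("tracks that miss frame 0 are rejected for displacement analysis", {
  pts <- data.frame(cell_id = c("a", "a", "b"), frame = c(0, 1, 1),
                    x = 0, y = 0, z = 0)
  expect_error(displacements(track_set(pts)),
               class = "plategrowth_missing_frame0")
})

test_that("y speeds are per-interval signed rates", {
  ts <- simple_ts(c(0, 10), n_frames = 6, vy = c(2, 0))
  sp <- speeds(ts)
  expect_equal(sp$vy[sp$cell_id == "s01"], rep(2, 5))
  expect_equal(sp$vy[sp$cell_id == "s02"], rep(0, 5))
  one <- track_set(data.frame(cell_id = "a", frame = 0, x = 0, y = 0, z = 0))
  expect_error(speeds(one), class = "plategrowth_too_short")
})

test_that("speeds telescope to the final displacement for every cell", {
  sim <- generate_tissue(small_growth_spec(jitter_sd = 0.4, lattice_sd = 0.4))
  sp <- speeds(sim$tracks)
  d <- displacements(sim$tracks)
  final <- max(d$frame)
  sums <- tapply(sp$vy, sp$cell_id, sum) * sim$tracks$frame_interval
  dyf <- d$dy[d$frame == final]
  names(dyf) <- d$cell_id[d$frame == final]
  expect_equal(as.vector(sums[names(dyf)]), unname(dyf), tolerance = 1e-10)
})

test_that("three hand-placed cells give the expected least-squares line", {
  pts <- rbind(data.frame(cell_id = "a", frame = 0:1, x = 0, y = c(0, 0), z = 0),
               data.frame(cell_id = "b", frame = 0:1, x = 0, y = c(110, 115), z = 0),
               data.frame(cell_id = "c", frame = 0:1, x = 0, y = c(220, 230), z = 0))
  f <- fit_displacement_vs_initial(track_set(pts), "y", final_frame = 1)
  expect_equal(f$slope, 10 / 220, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$n, 3)
})

test_that("a noise-free uniform-growth tissue is exactly additive", {
  sim <- generate_tissue(small_growth_spec())
  f <- fit_displacement_vs_initial(sim$tracks, "y")
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  # anchored proximal face: intercept ties to the proximal layer offset
  expect_gt(f$slope, 0)
})

test_that("a rate-free jittered tissue shows no displacement trend", {
  sim <- generate_tissue(small_growth_spec(rate_cell_y = 0, rate_cell_x = 0,
                                           rate_ecm_y = 0, rate_ecm_x = 0,
                                           jitter_sd = 0.5, seed = 21))
  f <- fit_displacement_vs_initial(sim$tracks, "y")
  expect_lt(abs(f$slope), 0.02)
  expect_lt(f$r_squared, 0.3)
})

test_that("degenerate fits are rejected", {
  pts <- data.frame(cell_id = rep(c("a", "b", "c"), each = 2),
                    frame = rep(0:1, 3), x = 0, y = 5, z = 0)
  expect_error(fit_displacement_vs_initial(track_set(pts), "y", 1),
               class = "plategrowth_degenerate")
  expect_error(fit_displacement_vs_initial(simple_ts(c(0, 1)), "y"),
               class = "plategrowth_too_few")
})

test_that("printed-percentage helpers reproduce the worked arithmetic", {
  expect_identical(percent_elongation(85, 220), 39L)
  expect_identical(percent_elongation(500, 1600), 31L)
  expect_identical(percent_elongation(0, 100), 0L)
  expect_error(percent_elongation(10, 0), class = "plategrowth_bad_arg")

  expect_identical(coverage_percent(98, 97), 95L)
  expect_identical(coverage_percent(100, 100), 100L)
  expect_identical(coverage_percent(0, 97), 0L)
  expect_error(coverage_percent(101, 50), class = "plategrowth_bad_arg")

  expect_identical(fraction_percent(472, 481), 98L)
})
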