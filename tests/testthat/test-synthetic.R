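test_that("zero rates and zero noise give a stationary tissue", {
  sim <- generate_tissue(small_growth_spec(rate_cell_y = 0, rate_cell_x = 0,
                                           rate_ecm_y = 0, rate_ecm_x = 0))
  Y <- sapply(split(sim$tracks$points$y, sim$tracks$points$cell_id), diff)
  expect_true(all(abs(Y) == 0))
  X <- sapply(split(sim$tracks$points$x, sim$tracks$points$cell_id), diff)
  expect_true(all(abs(X) == 0))
})

test_that("pure ECM growth displaces each cell in proportion to its layer", {
  g <- 0.5
  sim <- generate_tissue(small_growth_spec(rate_cell_y = 0, rate_cell_x = 0,
                                           rate_ecm_y = g, rate_ecm_x = 0))
  p <- sim$tracks$points
  jy <- sim$truth$lattice$jy
  final <- max(p$frame)
  for (id in sample(names(jy), 10)) {
    dy <- p$y[p$cell_id == id & p$frame == final] -
      p$y[p$cell_id == id & p$frame == 0]
    expect_equal(dy, jy[[id]] * g * final, tolerance = 1e-12)
  }
})

test_that("relative y speed between neighbouring layers is uniform along the PDA", {
  sim <- generate_tissue(small_growth_spec())
  p <- sim$tracks$points
  jy <- sim$truth$lattice$jy
  # one representative cell per layer; speed difference between consecutive
  # layers equals the gap rate everywhere
  reps <- vapply(sort(unique(jy)), function(j) names(jy)[jy == j][1], "")
  v <- vapply(reps, function(id) {
    yy <- p$y[p$cell_id == id]
    mean(diff(yy))
  }, numeric(1))
  expect_equal(unname(diff(v)), rep(sim$truth$gap_rate_y, length(v) - 1),
               tolerance = 1e-10)
})

test_that("a division at theta 0 separates daughters within the xz plane", {
  div <- data.frame(frame = 4, theta_deg = 0, rearrange = FALSE)
  sim <- generate_tissue(small_growth_spec(divisions = div))
  lin <- sim$tracks$lineage
  expect_equal(nrow(lin), 1)
  p <- sim$tracks$points
  a <- p[p$cell_id == lin$daughter_a_id & p$frame == 4, ]
  b <- p[p$cell_id == lin$daughter_b_id & p$frame == 4, ]
  expect_equal(a$y, b$y, tolerance = 1e-9)
  # separated by twice the initial radius
  r <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  expect_equal(r, 2 * sim$truth$spec$cell_radius0, tolerance = 1e-9)
})

test_that("the same seed reproduces the tissue exactly", {
  s1 <- generate_tissue(small_growth_spec(jitter_sd = 0.5, lattice_sd = 0.5))
  s2 <- generate_tissue(small_growth_spec(jitter_sd = 0.5, lattice_sd = 0.5))
  expect_identical(s1$tracks$points, s2$tracks$points)
  expect_identical(s1$truth$labels, s2$truth$labels)
})

test_that("overfull regions fail with a packing error", {
  expect_error(tissue_spec(n_cells = 10000, region = c(50, 100, 50)) |>
                 generate_tissue(),
               class = "plategrowth_packing")
})

test_that("a rendered sphere has close to its analytic voxel volume", {
  pts <- data.frame(cell_id = "a", frame = 0, x = 15, y = 15, z = 15)
  stk <- render_images(track_set(pts), 5, voxel_um = 1,
                       region = c(30, 30, 30), noise_sd = 0)
  count <- sum(stk$frames[[1]] > 0.5)
  expect_lt(abs(count - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.15)
})

test_that("rendering is additive over non-overlapping cells and empty sets are dark", {
  one <- data.frame(cell_id = "a", frame = 0, x = 12, y = 12, z = 12)
  two <- rbind(one, data.frame(cell_id = "b", frame = 0, x = 36, y = 36,
                               z = 12))
  s1 <- render_images(track_set(one), 4, voxel_um = 1, region = c(48, 48, 24),
                      noise_sd = 0)
  s2 <- render_images(track_set(two), 4, voxel_um = 1, region = c(48, 48, 24),
                      noise_sd = 0)
  c1 <- sum(s1$frames[[1]] > 0.5)
  c2 <- sum(s2$frames[[1]] > 0.5)
  expect_equal(c2, 2 * c1)

  empty <- track_set(data.frame(cell_id = "a", frame = 0, x = -50, y = -50,
                                z = -50))
  s0 <- render_images(empty, 4, voxel_um = 1, region = c(20, 20, 20),
                      noise_sd = 0)
  expect_equal(sum(s0$frames[[1]]), 0)
})

test_that("sub-voxel radii are rejected", {
  pts <- data.frame(cell_id = "a", frame = 0, x = 5, y = 5, z = 5)
  expect_error(render_images(track_set(pts), 0.4, voxel_um = 1,
                             region = c(10, 10, 10)),
               class = "plategrowth_bad_radius")
})

test_that("image stacks survive a TIFF round trip", {
  pts <- data.frame(cell_id = "a", frame = 0:1, x = 10, y = c(10, 12), z = 8)
  stk <- render_images(track_set(pts), 4, voxel_um = 2, region = c(20, 24, 16),
                       noise_sd = 0)
  dir <- withr::local_tempdir()
  write_stack(stk, dir)
  back <- read_stack(dir, voxel_um = 2)
  expect_equal(length(back$frames), 2)
  expect_equal(back$frames[[1]], stk$frames[[1]], tolerance = 1e-6)
})
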