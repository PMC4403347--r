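test_that("four rectangle corners give one polygon per cell with h and w of the rectangle", {
  pts <- do.call(rbind, lapply(1:2, function(f) {
    data.frame(cell_id = c("a", "b", "c", "d"), frame = f - 1,
               x = c(0, 6, 0, 6), y = c(0, 0, 10, 10), z = 0)
  }))
  ps <- build_polygons(track_set(pts))
  expect_equal(nrow(ps$h), 4)
  expect_true(all(ps$h == 10))
  expect_true(all(ps$w == 6))
  expect_error(build_polygons(simple_ts(c(0, 1, 2))),
               class = "plategrowth_too_few")
})

test_that("equidistant neighbour ties break deterministically by cell id", {
  pts <- data.frame(cell_id = c("a", "b", "c", "d", "e"), frame = 0,
                    x = c(0, 5, -5, 0, 0), y = c(0, 0, 0, 5, -5), z = 0)
  pts <- rbind(pts, transform(pts, frame = 1))
  ps <- build_polygons(track_set(pts))
  expect_equal(sort(ps$neighbours["a", ]), c("b", "c", "d"))
})

test_that("frozen neighbour sets match a brute-force 3-NN search at frame 0", {
  sim <- generate_tissue(tissue_spec(n_cells = 60, region = c(60, 140, 60),
                                     n_frames = 3, seed = 17))
  ps <- build_polygons(sim$tracks)
  p0 <- sim$tracks$points[sim$tracks$points$frame == 0, ]
  p0 <- p0[order(p0$cell_id), ]
  for (i in sample(nrow(p0), 8)) {
    d <- sqrt((p0$x - p0$x[i])^2 + (p0$y - p0$y[i])^2 + (p0$z - p0$z[i])^2)
    d[i] <- Inf
    nn <- p0$cell_id[order(d)[1:3]]
    expect_setequal(ps$neighbours[p0$cell_id[i], ], nn)
  }
})

test_that("an unchanged tissue is classified all-EE under the boundary convention", {
  sim <- generate_tissue(small_growth_spec(rate_cell_y = 0, rate_cell_x = 0,
                                           rate_ecm_y = 0, rate_ecm_x = 0))
  cls <- classify_motion(sim$tracks)
  expect_equal(unname(cls$fractions["EE"]), 1)
})

test_that("uniform biaxial growth is classified all-EE", {
  sim <- generate_tissue(tissue_spec(n_cells = 60, region = c(60, 140, 60),
                                     n_frames = 10, jitter_sd = 0,
                                     lattice_sd = 0.5, seed = 3))
  cls <- classify_motion(sim$tracks)
  expect_equal(unname(cls$fractions["EE"]), 1)
})

test_that("global convergence with y extension is classified all-CE", {
  sim <- generate_tissue(tissue_spec(n_cells = 60, region = c(60, 140, 60),
                                     n_frames = 20, frac_ce = 1,
                                     rate_cell_x = 0, rate_ecm_x = 0,
                                     jitter_sd = 0, lattice_sd = 0.5,
                                     seed = 4))
  cls <- classify_motion(sim$tracks)
  expect_equal(unname(cls$fractions["CE"]), 1)
})

test_that("mean polygon height and width both rise on a growing jittered tissue", {
  sim <- generate_tissue(tissue_spec(n_cells = 80, region = c(60, 140, 60),
                                     n_frames = 25, jitter_sd = 0.4,
                                     seed = 6))
  ps <- build_polygons(sim$tracks)
  mh <- colMeans(ps$dh)
  mw <- colMeans(ps$dw)
  expect_gt(unname(coef(lm(mh ~ ps$hours))[2]), 0)
  expect_gt(unname(coef(lm(mw ~ ps$hours))[2]), 0)
  expect_gt(mh[length(mh)], 0)
  expect_gt(mw[length(mw)], 0)
})

test_that("trend classification with a dead band resists jitter", {
  # polygons confined to one x column carry no width signal, so a strict
  # sign rule flips coins on them under jitter; the trend statistic plus a
  # noise dead band keeps spurious width convergence rare
  sim <- generate_tissue(tissue_spec(n_cells = 60, region = c(60, 140, 60),
                                     n_frames = 30, jitter_sd = 0.5, seed = 8))
  cls <- classify_motion(sim$tracks, mode = "trend", epsilon = 0.6)
  expect_lte(unname(cls$fractions["CE"] + cls$fractions["CC"]), 0.05)
})
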