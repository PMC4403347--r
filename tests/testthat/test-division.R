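make_pair_ts <- function(offsets) {
  # parent at frames 0..1, daughters from frame 2 with a fixed joining vector
  nf <- nrow(offsets)
  pts <- rbind(
    data.frame(cell_id = "p", frame = 0:1, x = 0, y = 0, z = 0),
    data.frame(cell_id = "d1", frame = 2:(1 + nf), x = 0, y = 0, z = 0),
    data.frame(cell_id = "d2", frame = 2:(1 + nf),
               x = offsets[, 1], y = offsets[, 2], z = offsets[, 3]))
  lin <- data.frame(parent_id = "p", daughter_a_id = "d1",
                    daughter_b_id = "d2", division_frame = 2)
  track_set(pts, lin)
}

test_that("daughter angle geometry covers the axis-aligned and 3-4-5 cases", {
  ts <- make_pair_ts(cbind(c(4, 4), 0, 0))
  ev <- daughter_geometry(ts, ts$lineage[1, ])
  expect_equal(ev$theta, c(0, 0))
  expect_equal(ev$t, c(1L, 2L))

  ts <- make_pair_ts(cbind(0, c(4, 4), 0))
  expect_equal(daughter_geometry(ts, ts$lineage[1, ])$theta, c(90, 90))

  ts <- make_pair_ts(cbind(c(3, 3), c(4, 4), 0))
  ev <- daughter_geometry(ts, ts$lineage[1, ])
  expect_equal(ev$r, c(5, 5))
  expect_equal(ev$theta, rep(asin(4 / 5) * 180 / pi, 2), tolerance = 1e-9)

  # coincident daughters flagged, angle undefined
  ts <- make_pair_ts(cbind(c(0, 3), c(0, 4), 0))
  ev <- daughter_geometry(ts, ts$lineage[1, ])
  expect_true(ev$coincident[1])
  expect_true(is.na(ev$theta[1]))
})

test_that("theta is invariant to daughter relabelling and xz rotation", {
  off <- cbind(c(3, 2), c(4, 5), c(1, 2))
  ts <- make_pair_ts(off)
  th <- daughter_geometry(ts, ts$lineage[1, ])$theta
  # swap the daughters
  lin2 <- data.frame(parent_id = "p", daughter_a_id = "d2",
                     daughter_b_id = "d1", division_frame = 2)
  th_swap <- daughter_geometry(track_set(ts$points, lin2), lin2[1, ])$theta
  expect_equal(th_swap, th, tolerance = 1e-12)
  # rotate the offset within the xz plane
  ang <- 0.7
  rot <- cbind(off[, 1] * cos(ang) - off[, 3] * sin(ang), off[, 2],
               off[, 1] * sin(ang) + off[, 3] * cos(ang))
  th_rot <- daughter_geometry(make_pair_ts(rot),
                              ts$lineage[1, ])$theta
  expect_equal(th_rot, th, tolerance = 1e-9)
})

test_that("planted division angles are recovered and binned correctly", {
  set.seed(1)
  div <- data.frame(frame = sample(2:8, 17, replace = TRUE),
                    theta_deg = runif(17, 0, 14.9),
                    rearrange = FALSE)
  sim <- generate_tissue(tissue_spec(n_cells = 472, n_frames = 12,
                                     divisions = div, jitter_sd = 0,
                                     lattice_sd = 0, seed = 31))
  ev <- division_events(sim$tracks)
  expect_equal(length(ev), 17)
  planted <- sim$truth$divisions
  for (pid in names(ev)) {
    e <- as.data.frame(ev[[pid]])
    expect_equal(e$theta[e$t == 1],
                 planted$theta_deg[planted$parent_id == pid],
                 tolerance = 1e-9)
  }
  hist <- orientation_histogram(ev, at = "division", bin_width_deg = 15)
  expect_equal(hist$count[1], 17)
  expect_equal(sum(hist$count[-1]), 0)

  single <- orientation_histogram(ev[1], at = "division", bin_width_deg = 15)
  expect_equal(sum(single$count), 1)
})

test_that("rearrangement calls follow the angle-increase threshold", {
  flat <- make_pair_ts(cbind(c(4, 4, 4), 0, 0))
  rising <- make_pair_ts(cbind(c(4, 2, 0.5), c(0.35, 3.5, 4.6), 0))
  calls <- call_rearrangements(list(p1 = daughter_geometry(flat, flat$lineage[1, ]),
                                    p2 = daughter_geometry(rising, rising$lineage[1, ])))
  expect_equal(calls$calls$rearranged, c(FALSE, TRUE))
  expect_equal(calls$fraction, 0.5)
})

test_that("a planted 10% rearranging fraction is recovered exactly without jitter", {
  div <- data.frame(frame = rep(3:7, 4), theta_deg = rep(5, 20),
                    rearrange = rep(c(TRUE, rep(FALSE, 9)), 2))
  sim <- generate_tissue(tissue_spec(n_cells = 200, n_frames = 30,
                                     divisions = div, jitter_sd = 0,
                                     lattice_sd = 0.3, seed = 12))
  ev <- division_events(sim$tracks)
  rc <- call_rearrangements(ev, threshold_deg = 30)
  expect_equal(rc$fraction, 0.1)
  planted <- sim$truth$divisions
  got <- rc$calls$rearranged[match(planted$parent_id, rc$calls$parent_id)]
  expect_equal(got, planted$rearrange)
})

test_that("mitotic rate is divisions over the starting population", {
  div <- data.frame(frame = sample(2:8, 17, replace = TRUE),
                    theta_deg = 5, rearrange = FALSE)
  sim <- generate_tissue(tissue_spec(n_cells = 472, n_frames = 12,
                                     divisions = div, seed = 2))
  n0 <- length(cell_ids(sim$tracks, frame = 0))
  expect_equal(mitotic_rate(sim$tracks), 100 * 17 / n0)
  expect_lt(mitotic_rate(sim$tracks), 7)

  none <- generate_tissue(small_growth_spec())
  expect_equal(mitotic_rate(none$tracks), 0)
})
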