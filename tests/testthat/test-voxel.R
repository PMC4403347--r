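test_that("binarizing an already-binary image is exact for every threshold", {
  img <- array(0, c(10, 10, 4))
  img[3:6, 2:9, 2:3] <- 1
  b <- binarize(img)
  expect_equal(unique(b$per_threshold$bright), sum(img))
  expect_equal(b$bright, sum(img))
  expect_equal(b$dark, length(img) - sum(img))
  expect_error(binarize(array(1, c(4, 4, 2))),
               class = "plategrowth_degenerate")
})

test_that("bright and dark counts conserve the box volume at every threshold", {
  set.seed(33)
  img <- array(runif(8 * 9 * 5), c(8, 9, 5))
  b <- binarize(img)
  expect_equal(b$per_threshold$bright + b$per_threshold$dark,
               rep(length(img), 10))
  expect_equal(b$bright + b$dark, length(img))
  # bright counts fall as the threshold rises; the average lies between
  expect_true(all(diff(b$per_threshold$bright) <= 0))
  expect_gte(b$bright, min(b$per_threshold$bright))
  expect_lte(b$bright, max(b$per_threshold$bright))
})

test_that("a half-bright field splits close to evenly", {
  img <- array(rep(c(0, 1), each = 500), c(10, 10, 10))
  b <- binarize(img)
  expect_equal(b$bright / length(img), 0.5, tolerance = 0.05)
})

test_that("patch decomposition reproduces hand-computed extents", {
  mask <- matrix(0, 50, 60)
  mask[21:30, 21:40] <- 1   # 10 x 20 patch
  dec <- decompose_axes(mask, box_dims = c(50, 60), voxel_um = 1)
  expect_equal(dec$cell_x, 10)
  expect_equal(dec$cell_y, 20)
  expect_equal(dec$ecm_x, 40)
  expect_equal(dec$ecm_y, 40)

  # a second identical patch leaves the means unchanged
  mask2 <- matrix(0, 50, 60)
  mask2[21:30, 5:24] <- 1
  mask2[36:45, 30:49] <- 1
  dec2 <- decompose_axes(mask2, box_dims = c(50, 60), voxel_um = 1)
  expect_equal(dec2$cell_x, 10)
  expect_equal(dec2$cell_y, 20)
  expect_equal(dec2$n_patches, 2)

  expect_error(decompose_axes(matrix(0, 5, 5), c(5, 5)),
               class = "plategrowth_degenerate")
})

test_that("3D labelling matches the slice result for well-separated blobs", {
  arr <- array(0, c(30, 30, 10))
  arr[3:10, 3:12, 3:7] <- 1
  arr[18:25, 18:27, 3:7] <- 1
  d2 <- decompose_axes(arr, c(30, 30), voxel_um = 1, mode = "midplane")
  d3 <- decompose_axes(arr, c(30, 30), voxel_um = 1, mode = "3d")
  expect_equal(d3$cell_x, 8)
  expect_equal(d3$cell_y, 10)
  expect_equal(d2$cell_x, d3$cell_x)
  expect_equal(d2$cell_y, d3$cell_y)
  expect_equal(d3$n_patches, 2)
})

test_that("a rendered cell's measured extent tracks the scheduled diameter", {
  pts <- data.frame(cell_id = "a", frame = 0, x = 20, y = 20, z = 20)
  stk <- render_images(track_set(pts), 6, voxel_um = 1, region = c(40, 40, 40),
                       noise_sd = 0)
  dec <- decompose_axes(stk$frames[[1]] > 0.5, c(40, 40), voxel_um = 1,
                        mode = "3d")
  expect_lt(abs(dec$cell_y - 12) / 12, 0.15)
  expect_lt(abs(dec$cell_x - 12) / 12, 0.15)
})

test_that("the anchored crop box follows the anchors", {
  ts <- simple_ts(c(10, 10, 40, 40), n_frames = 4, vy = c(0, 0, 2, 2),
                  x0 = c(10, 40, 10, 40))
  stk <- image_stack4d(replicate(4, array(0.5 + runif(50 * 60 * 4, 0, 0.5),
                                          c(50, 60, 4)), simplify = FALSE))
  crop <- crop_region(stk, ts, cell_ids(ts))
  expect_equal(crop$box_um$box_x, rep(30, 4))
  expect_equal(crop$box_um$box_y, 30 + 2 * (0:3))

  lost <- track_set(rbind(
    ts$points[!(ts$points$cell_id == "s01" & ts$points$frame > 2), ]))
  expect_error(crop_region(stk, lost, cell_ids(ts)),
               class = "plategrowth_anchor_lost")
})

test_that("constant counts give flat trends and zero slopes", {
  vs <- data.frame(hours = 0:5, bright = 100, dark = 50, cell_x = 4,
                   cell_y = 5, ecm_x = 2, ecm_y = 3)
  tr <- volume_trends(vs)
  expect_equal(tr$percent_of_t0, rep(100, 6))
  expect_equal(tr$slope, rep(0, 6))

  vs2 <- transform(vs, bright = 100 + 20 * hours)
  tr2 <- volume_trends(vs2, quantities = "bright")
  expect_equal(tr2$percent_of_t0, 200)
  expect_equal(tr2$slope, 20)

  expect_error(volume_trends(transform(vs, bright = 0), "bright"),
               class = "plategrowth_degenerate")
})
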