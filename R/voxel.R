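# Cell-vs-ECM voxel volumetry. A crop box anchored on four reference cells
# grows with the tissue; each cropped frame is binarized at ten thresholds
# around its mean intensity (bright = cell, dark = ECM) and the bright mask is
# decomposed into per-patch bounding boxes to separate mean cell extent from
# ECM span along x and y.

#' Choose four corner anchor cells for the voxel crop box
#'
#' Picks, among cells tracked over the full frame range, the cells closest to
#' the four (x, y) corners of the frame-0 population, so the crop box spans
#' the tissue and expands with it.
#'
#' @param ts a [track_set()].
#' @return character vector of 4 cell ids.
#' @export
pick_anchors <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  nf <- n_frames(ts)
  len <- table(ts$points$cell_id)
  ids <- names(len)[len == nf]
  p <- ts$points[ts$points$frame == 0 & ts$points$cell_id %in% ids, ]
  if (nrow(p) < 4)
    pg_error("plategrowth_too_few", "need >= 4 full-length tracks for anchors")
  corners <- rbind(c(min(p$x), min(p$y)), c(max(p$x), min(p$y)),
                   c(min(p$x), max(p$y)), c(max(p$x), max(p$y)))
  used <- character(0)
  for (i in 1:4) {
    d2 <- (p$x - corners[i, 1])^2 + (p$y - corners[i, 2])^2
    d2[p$cell_id %in% used] <- Inf
    used <- c(used, p$cell_id[which.min(d2)])
  }
  used
}

#' Crop an image stack to the box spanned by four anchor cells
#'
#' The per-frame axis-aligned bounding box passes through the four anchor
#' cell centres in x and y (full depth in z) and therefore grows with the
#' tissue.
#'
#' @param stack an [image_stack4d()].
#' @param ts the matching [track_set()] (same frame indexing, um).
#' @param anchors 4 cell ids tracked at every rendered frame.
#' @return list with `frames` (list of cropped 3D arrays), `box_um`
#'   (data.frame: `frame`, `x0`, `x1`, `y0`, `y1`, `box_x`, `box_y` in um)
#'   and `voxel_um`.
#' @export
crop_region <- function(stack, ts, anchors) {
  stopifnot(inherits(stack, "image_stack4d"), inherits(ts, "track_set"))
  if (length(anchors) != 4)
    pg_error("plategrowth_bad_arg", "need exactly 4 anchor cells")
  h <- stack$voxel_um
  nf <- length(stack$frames)
  frames <- vector("list", nf)
  box <- data.frame(frame = 0:(nf - 1), x0 = NA_real_, x1 = NA_real_,
                    y0 = NA_real_, y1 = NA_real_)
  p <- ts$points[ts$points$cell_id %in% anchors, ]
  for (f in 0:(nf - 1)) {
    q <- p[p$frame == f, ]
    if (nrow(q) < 4) {
      missing <- setdiff(anchors, q$cell_id)
      pg_error("plategrowth_anchor_lost",
               "anchor '%s' not tracked at frame %d", missing[1], f)
    }
    x0 <- min(q$x); x1 <- max(q$x); y0 <- min(q$y); y1 <- max(q$y)
    arr <- stack$frames[[f + 1]]
    d <- dim(arr)
    ix <- max(1L, floor(x0 / h[1]) + 1L):min(d[1], ceiling(x1 / h[1]))
    iy <- max(1L, floor(y0 / h[2]) + 1L):min(d[2], ceiling(y1 / h[2]))
    frames[[f + 1]] <- arr[ix, iy, , drop = FALSE]
    box[f + 1, 2:5] <- c(x0, x1, y0, y1)
  }
  box$box_x <- box$x1 - box$x0
  box$box_y <- box$y1 - box$y0
  list(frames = frames, box_um = box, voxel_um = h)
}

#' Multi-threshold binarization of one frame
#'
#' Thresholds are placed around the frame's mean intensity in steps of
#' `spacing` standard deviations (for the default 10 thresholds: mean - 0.5 sd
#' up to mean + 0.4 sd). A voxel counts as cell (bright) when its intensity is
#' at or above the threshold, otherwise as ECM (dark); bright and dark counts
#' are averaged over the threshold set. The returned `mask` is the binary
#' image at the middle threshold (the frame mean), used for patch analysis.
#'
#' @param frame_image 2D or 3D numeric array.
#' @param n_thresholds number of thresholds (default 10).
#' @param spacing threshold spacing as a fraction of the intensity sd.
#' @return list with `bright`, `dark` (threshold-averaged voxel counts),
#'   `per_threshold` (data.frame: `threshold`, `bright`, `dark`), `mask`
#'   (logical array) and `total` (voxels in the image).
#' @export
binarize <- function(frame_image, n_thresholds = 10, spacing = 0.1) {
  v <- as.numeric(frame_image)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    pg_error("plategrowth_degenerate", "constant image: binarization undefined")
  m <- mean(v)
  offs <- (seq_len(n_thresholds) - 1 - floor(n_thresholds / 2)) * spacing
  thr <- m + offs * s
  # thresholds outside the intensity range are uninformative; keep each one
  # strictly inside (min, max] so every threshold partitions the image
  rng <- range(v)
  eps <- 1e-9 * (rng[2] - rng[1])
  thr <- pmin(pmax(thr, rng[1] + eps), rng[2])
  bright <- vapply(thr, function(t) sum(v >= t), numeric(1))
  total <- length(v)
  mid <- which.min(abs(offs))
  mask <- frame_image >= thr[mid]
  list(bright = mean(bright), dark = mean(total - bright),
       per_threshold = data.frame(threshold = thr, bright = bright,
                                  dark = total - bright),
       mask = mask, total = total)
}

#' Decompose a binary frame into mean cell extent and ECM span
#'
#' Labels connected bright patches, takes each patch's axis-aligned bounding
#' box, and averages the box dimensions along x and y: the mean cell extent.
#' Subtracting the mean extent from the crop-box dimension gives the mean ECM
#' span per axis. By default patches are labelled on the mid-depth 2D slice
#' (frames are segmented as 2D images); `mode = "3d"` labels in 3D, which
#' measures true extents rather than slice chords. Patches touching the crop
#' boundary are excluded from the extent statistics (their boxes are
#' truncated by the crop), as are patches below `min_patch` voxels.
#'
#' @param binary_frame logical/0-1 array (2D or 3D) from [binarize()].
#' @param box_dims `c(box_x, box_y)` crop-box dimensions in um.
#' @param voxel_um voxel size (um, scalar or per-axis).
#' @param mode `"midplane"` (default) or `"3d"`.
#' @param min_patch minimum patch size in voxels (default 4).
#' @return list with `cell_x`, `cell_y` (mean patch extent, um), `ecm_x`,
#'   `ecm_y` (box dimension minus mean extent, um) and `n_patches`.
#' @export
decompose_axes <- function(binary_frame, box_dims, voxel_um = 1,
                           mode = c("midplane", "3d"), min_patch = 4) {
  mode <- match.arg(mode)
  if (length(voxel_um) == 1) voxel_um <- rep(voxel_um, 3)
  d <- dim(binary_frame)
  if (mode == "midplane" && length(d) == 3)
    binary_frame <- binary_frame[, , max(1L, ceiling(d[3] / 2))]
  mask <- binary_frame != 0
  if (!any(mask))
    pg_error("plategrowth_degenerate", "empty bright mask")
  boxes <- if (mode == "3d" && length(dim(mask)) == 3)
    patch_boxes_3d(mask) else patch_boxes_2d(mask)
  dm <- dim(mask)
  interior <- boxes$x0 > 1 & boxes$y0 > 1 & boxes$x1 < dm[1] &
    boxes$y1 < dm[2] & boxes$size >= min_patch
  if (length(dm) == 3)
    interior <- interior & boxes$z0 > 1 & boxes$z1 < dm[3]
  if (any(interior)) boxes <- boxes[interior, , drop = FALSE]
  cell_x <- mean(boxes$x1 - boxes$x0 + 1) * voxel_um[1]
  cell_y <- mean(boxes$y1 - boxes$y0 + 1) * voxel_um[2]
  list(cell_x = cell_x, cell_y = cell_y,
       ecm_x = box_dims[1] - cell_x, ecm_y = box_dims[2] - cell_y,
       n_patches = nrow(boxes))
}

patch_boxes_2d <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  idx <- which(lab > 0, arr.ind = TRUE)
  g <- lab[lab > 0]
  data.frame(x0 = tapply(idx[, 1], g, min), x1 = tapply(idx[, 1], g, max),
             y0 = tapply(idx[, 2], g, min), y1 = tapply(idx[, 2], g, max),
             size = as.vector(table(g)))
}

# 6-connected 3D components via a voxel-adjacency graph
patch_boxes_3d <- function(mask) {
  d <- dim(mask)
  lin <- which(mask)
  if (length(lin) == 0) return(data.frame())
  n <- length(lin)
  pos <- arrayInd(lin, d)
  idmap <- integer(prod(d))
  idmap[lin] <- seq_len(n)
  edges <- list()
  strides <- c(1L, d[1], d[1] * d[2])
  for (a in 1:3) {
    ok <- pos[, a] < d[a]
    nbid <- idmap[lin[ok] + strides[a]]
    hit <- nbid > 0
    if (any(hit))
      edges[[a]] <- cbind(which(ok)[hit], nbid[hit])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(em) && nrow(em) > 0)
    g <- igraph::add_edges(g, as.vector(t(em)))
  comp <- igraph::components(g)$membership
  data.frame(x0 = tapply(pos[, 1], comp, min),
             x1 = tapply(pos[, 1], comp, max),
             y0 = tapply(pos[, 2], comp, min),
             y1 = tapply(pos[, 2], comp, max),
             z0 = tapply(pos[, 3], comp, min),
             z1 = tapply(pos[, 3], comp, max),
             size = as.vector(table(comp)))
}

#' Voxel summary of a cropped image stack
#'
#' Runs [binarize()] and [decompose_axes()] on every cropped frame and
#' assembles the per-frame voxel bookkeeping: threshold-averaged bright
#' (cell) and dark (ECM) counts, mean cell extent and ECM span along x and y,
#' and the crop-box dimensions.
#'
#' @param stack an [image_stack4d()].
#' @param ts the matching [track_set()].
#' @param anchors 4 anchor cell ids (default [pick_anchors()]).
#' @param n_thresholds,spacing see [binarize()].
#' @param mode,min_patch see [decompose_axes()].
#' @return object of class `voxel_summary`: data.frame with columns `frame`,
#'   `hours`, `bright`, `dark`, `total`, `cell_x`, `cell_y`, `ecm_x`,
#'   `ecm_y`, `box_x`, `box_y`; attribute `anchors`.
#' @export
analyze_stack <- function(stack, ts, anchors = pick_anchors(ts),
                          n_thresholds = 10, spacing = 0.1,
                          mode = c("midplane", "3d"), min_patch = 4) {
  mode <- match.arg(mode)
  crop <- crop_region(stack, ts, anchors)
  nf <- length(crop$frames)
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    b <- binarize(crop$frames[[f]], n_thresholds, spacing)
    dec <- decompose_axes(b$mask,
                          c(crop$box_um$box_x[f], crop$box_um$box_y[f]),
                          voxel_um = crop$voxel_um, mode = mode,
                          min_patch = min_patch)
    rows[[f]] <- data.frame(frame = f - 1L,
                            hours = (f - 1) * stack$frame_interval,
                            bright = b$bright, dark = b$dark,
                            total = b$total,
                            cell_x = dec$cell_x, cell_y = dec$cell_y,
                            ecm_x = dec$ecm_x, ecm_y = dec$ecm_y,
                            box_x = crop$box_um$box_x[f],
                            box_y = crop$box_um$box_y[f])
  }
  out <- do.call(rbind, rows)
  attr(out, "anchors") <- anchors
  class(out) <- c("voxel_summary", "data.frame")
  out
}

#' Percent change at the final frame and fitted rates
#'
#' For each summary quantity: the final value as a percentage of the frame-0
#' value (100 = no change) and the least-squares slope over time (units per
#' hour).
#'
#' @param summary a `voxel_summary` (or any data.frame with `hours` and the
#'   quantity columns).
#' @param quantities columns to summarise.
#' @return data.frame with columns `quantity`, `baseline`, `final`,
#'   `percent_of_t0`, `slope`.
#' @export
volume_trends <- function(summary,
                          quantities = c("bright", "dark", "cell_x", "cell_y",
                                         "ecm_x", "ecm_y")) {
  summary <- as.data.frame(summary)
  if (nrow(summary) < 2)
    pg_error("plategrowth_too_short", "need >= 2 frames for trends")
  rows <- lapply(quantities, function(q) {
    v <- summary[[q]]
    if (v[1] == 0)
      pg_error("plategrowth_degenerate", "zero baseline for '%s'", q)
    data.frame(quantity = q, baseline = v[1], final = v[length(v)],
               percent_of_t0 = 100 * v[length(v)] / v[1],
               slope = unname(stats::coef(stats::lm(v ~ summary$hours))[2]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count inter-layer y gaps between the anchor cells
#'
#' Groups the frame-0 y positions of cells inside the anchor box into levels
#' (positions closer than `level_tol` share a level) and returns the number
#' of inter-level gaps spanned by the box. This is the gap count that
#' converts box-level growth rates into per-cell-gap increments.
#'
#' @param ts a [track_set()].
#' @param anchors 4 anchor cell ids.
#' @param level_tol merge tolerance for y levels (um).
#' @return integer number of gaps (levels - 1).
#' @export
count_gaps_y <- function(ts, anchors, level_tol = 1) {
  p <- ts$points[ts$points$frame == 0, ]
  a <- p[p$cell_id %in% anchors, ]
  if (nrow(a) < 4) pg_error("plategrowth_too_few", "anchors absent at frame 0")
  inbox <- p$y >= min(a$y) - level_tol & p$y <= max(a$y) + level_tol &
    p$x >= min(a$x) - level_tol & p$x <= max(a$x) + level_tol
  y <- sort(p$y[inbox])
  if (length(y) < 2) pg_error("plategrowth_too_few", "fewer than 2 cells in box")
  levels <- cumsum(c(TRUE, diff(y) > level_tol))
  max(levels) - 1L
}
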