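# Polygon test for convergent extension: each cell and its three nearest
# neighbours (fixed at frame 0) define a quadrilateral whose axis-aligned
# height (y extent) and width (x extent) are followed over time. A cell whose
# polygon gains height while losing width moved by convergent extension.

#' Build fixed three-nearest-neighbour polygons
#'
#' Neighbours are the 3 cells minimising 3D distance at frame 0 (ties broken
#' by cell-id order) and the membership is frozen thereafter, so the height
#' and width series measure relative motion, not neighbour exchange. Only
#' cells tracked over the full frame range participate, so every polygon has
#' a complete height/width series.
#'
#' @param ts a [track_set()].
#' @return object of class `polygon_set`: list with `neighbours` (n x 3
#'   character matrix), `h`, `w` (n x frames matrices of polygon y/x extents,
#'   um, rows named by focal cell), `dh`, `dw` (changes from frame 0) and
#'   `hours`.
#' @export
build_polygons <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  nf <- n_frames(ts)
  len <- table(ts$points$cell_id)
  ids <- sort(names(len)[len == nf])
  if (length(ids) < 4)
    pg_error("plategrowth_too_few",
             "need >= 4 full-length tracks (found %d)", length(ids))
  sub <- subset_tracks(ts, ids)
  X <- coord_matrix(sub, "x")
  Y <- coord_matrix(sub, "y")
  Z <- coord_matrix(sub, "z")
  xyz0 <- cbind(X[, 1], Y[, 1], Z[, 1])
  nn <- nn3_neighbours(xyz0)
  poly <- cbind(seq_along(ids), nn)
  h <- w <- matrix(NA_real_, length(ids), nf,
                   dimnames = list(ids, colnames(X)))
  for (f in seq_len(nf)) {
    h[, f] <- poly_extent(Y[, f], poly)
    w[, f] <- poly_extent(X[, f], poly)
  }
  structure(list(neighbours = matrix(ids[nn], ncol = 3,
                                     dimnames = list(ids, NULL)),
                 h = h, w = w, dh = h - h[, 1], dw = w - w[, 1],
                 hours = (0:(nf - 1)) * ts$frame_interval),
            class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("<polygon_set> %d polygons over %d frames; mean dh %.2f um, mean dw %.2f um at final frame\n",
              nrow(x$h), ncol(x$h),
              mean(x$dh[, ncol(x$dh)]), mean(x$dw[, ncol(x$dw)])))
  invisible(x)
}

#' Classify local motion from polygon height/width changes
#'
#' Labels each cell from the signs of the polygon's height change (y) and
#' width change (x): `CE` (width converges, height extends), `EE` (both
#' extend), `CC` (both converge), `EC` (width extends, height converges).
#' Zero change counts as extension, so an unchanged polygon is `EE`.
#'
#' @param polygons a `polygon_set` from [build_polygons()], or a
#'   [track_set()] (polygons are built first).
#' @param mode `"final"` uses the change at the final frame (the default);
#'   `"mean"` uses the time-averaged change over all frames after 0;
#'   `"trend"` uses the least-squares slope of the extent over time scaled by
#'   the observation span, which is robust to frame-level jitter (unlike the
#'   other modes it does not inherit the frame-0 measurement noise).
#' @param epsilon boundary dead band (um): a change above `-epsilon` counts
#'   as extension. The default 0 is the strict sign rule; for jittery data a
#'   dead band of about three times the propagated positional noise of the
#'   chosen statistic keeps signal-free polygons from being labelled
#'   convergent by noise alone.
#' @return list with `labels` (data.frame: `cell_id`, `dh`, `dw`, `label`)
#'   and `fractions` (named fractions over the labels, summing to 1).
#' @export
classify_motion <- function(polygons, mode = c("final", "mean", "trend"),
                            epsilon = 0) {
  mode <- match.arg(mode)
  if (inherits(polygons, "track_set")) polygons <- build_polygons(polygons)
  stopifnot(inherits(polygons, "polygon_set"))
  nf <- ncol(polygons$dh)
  if (nf < 2) pg_error("plategrowth_too_short", "need >= 2 frames to classify")
  if (mode == "final") {
    dh <- polygons$dh[, nf]
    dw <- polygons$dw[, nf]
  } else if (mode == "mean") {
    dh <- rowMeans(polygons$dh[, -1, drop = FALSE])
    dw <- rowMeans(polygons$dw[, -1, drop = FALSE])
  } else {
    tt <- polygons$hours
    span <- tt[nf] - tt[1]
    slope_of <- function(m) {
      tc <- tt - mean(tt)
      as.vector(m %*% tc) / sum(tc^2)
    }
    dh <- slope_of(polygons$h) * span
    dw <- slope_of(polygons$w) * span
  }
  h_ext <- dh >= -epsilon
  w_ext <- dw >= -epsilon
  label <- ifelse(w_ext & h_ext, "EE",
                  ifelse(!w_ext & h_ext, "CE",
                         ifelse(w_ext & !h_ext, "EC", "CC")))
  labels <- data.frame(cell_id = rownames(polygons$dh), dh = unname(dh),
                       dw = unname(dw), label = unname(label))
  fr <- table(factor(label, levels = c("CE", "EE", "CC", "EC")))
  list(labels = labels,
       fractions = stats::setNames(as.vector(fr) / sum(fr), names(fr)))
}
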