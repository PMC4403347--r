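# Cell-cell distance distributions: per-cell mean centre-to-centre distance
# to every other cell, per frame, in 3D or projected onto a single axis, and
# the drift of the grand mean over time.

#' Per-cell mean centre-to-centre distances at a frame
#'
#' For every cell present at `frame`, the mean over all other cells of the
#' Euclidean distance (`axis = "3d"`) or of the absolute coordinate
#' difference along a single axis.
#'
#' @param ts a [track_set()].
#' @param frame frame index.
#' @param axis `"3d"`, `"x"`, `"y"` or `"z"`.
#' @return object of class `distance_distribution`: list with `frame`,
#'   `axis`, `per_cell` (named numeric, um), `grand_mean` (um), `n`.
#' @export
mean_distances <- function(ts, frame, axis = c("3d", "x", "y", "z")) {
  stopifnot(inherits(ts, "track_set"))
  axis <- match.arg(axis)
  p <- ts$points[ts$points$frame == frame, , drop = FALSE]
  if (nrow(p) < 2)
    pg_error("plategrowth_too_few",
             "need >= 2 cells at frame %d (found %d)", frame, nrow(p))
  m <- if (axis == "3d") as.matrix(stats::dist(p[c("x", "y", "z")]))
  else as.matrix(stats::dist(p[[axis]]))
  per <- rowSums(m) / (nrow(p) - 1)
  names(per) <- p$cell_id
  structure(list(frame = frame, axis = axis, per_cell = per,
                 grand_mean = mean(per), n = nrow(p)),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("<distance_distribution> frame %d, axis %s, %d cells, grand mean %.2f um\n",
              x$frame, x$axis, x$n, x$grand_mean))
  invisible(x)
}

#' Drift of the mean cell-cell distance over time
#'
#' The grand mean of the per-cell mean distances, per frame, tracing how the
#' distance distribution shifts as the tissue grows (monotonicity is not
#' assumed). Frames with fewer than 2 cells are skipped.
#'
#' @param ts a [track_set()].
#' @param axis `"3d"`, `"x"`, `"y"` or `"z"`.
#' @return data.frame with columns `frame`, `hours`, `grand_mean` (um), `n`.
#' @export
distribution_drift <- function(ts, axis = c("3d", "x", "y", "z")) {
  stopifnot(inherits(ts, "track_set"))
  axis <- match.arg(axis)
  frames <- sort(unique(ts$points$frame))
  counts <- table(ts$points$frame)
  frames <- frames[counts[as.character(frames)] >= 2]
  rows <- lapply(frames, function(f) {
    dd <- mean_distances(ts, f, axis)
    data.frame(frame = f, hours = f * ts$frame_interval,
               grand_mean = dd$grand_mean, n = dd$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Long-format per-cell mean-distance table over frames
#'
#' Tidy export of [mean_distances()] over all frames and the requested axes.
#'
#' @param ts a [track_set()].
#' @param axes character vector of axis tags.
#' @return data.frame with columns `frame`, `axis`, `cell_id`,
#'   `mean_distance`.
#' @export
distance_table <- function(ts, axes = c("3d", "x", "y")) {
  frames <- sort(unique(ts$points$frame))
  counts <- table(ts$points$frame)
  frames <- frames[counts[as.character(frames)] >= 2]
  out <- do.call(rbind, lapply(axes, function(a) {
    do.call(rbind, lapply(frames, function(f) {
      dd <- mean_distances(ts, f, a)
      data.frame(frame = f, axis = a, cell_id = names(dd$per_cell),
                 mean_distance = unname(dd$per_cell))
    }))
  }))
  rownames(out) <- NULL
  out
}
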