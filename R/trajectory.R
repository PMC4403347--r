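# Per-axis trajectory decomposition: displacement series relative to frame 0,
# hourly y-speed series, and the linear displacement-vs-initial-position fit
# that quantifies additive spreading along the proximo-distal axis.

#' Per-frame displacement components relative to frame 0
#'
#' For every cell, the signed displacement `(dx, dy, dz)` at each frame is the
#' coordinate at that frame minus the coordinate at frame 0.
#'
#' @param ts a [track_set()]; every track must span frame 0.
#' @return data.frame with columns `cell_id`, `frame`, `dx`, `dy`, `dz` (um).
#' @export
displacements <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  p <- ts$points
  if (nrow(p) == 0) pg_error("plategrowth_empty", "empty track set")
  first <- tapply(p$frame, p$cell_id, min)
  if (any(first != 0))
    pg_error("plategrowth_missing_frame0",
             "track '%s' does not span frame 0 (starts at frame %d)",
             names(first)[first != 0][1], first[first != 0][1])
  o <- p[p$frame == 0, c("cell_id", "x", "y", "z")]
  i <- match(p$cell_id, o$cell_id)
  data.frame(cell_id = p$cell_id, frame = p$frame,
             dx = p$x - o$x[i], dy = p$y - o$y[i], dz = p$z - o$z[i])
}

#' Per-interval y speeds
#'
#' The speed over each frame interval is the signed y distance moved divided
#' by the frame interval (um/h). Cells tracked for a single frame are an
#' error; partial tracks yield speeds over their observed intervals.
#'
#' @param ts a [track_set()].
#' @return data.frame with columns `cell_id`, `frame` (interval start) and
#'   `vy` (um/h).
#' @export
speeds <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  if (n_frames(ts) < 2)
    pg_error("plategrowth_too_short", "need at least 2 frames for speeds")
  p <- ts$points
  len <- table(p$cell_id)
  if (any(len < 2))
    pg_error("plategrowth_too_short",
             "track '%s' spans a single frame", names(len)[len < 2][1])
  sp <- do.call(rbind, lapply(split(p, p$cell_id), function(g) {
    data.frame(cell_id = g$cell_id[-1], frame = g$frame[-nrow(g)],
               vy = diff(g$y) / ts$frame_interval)
  }))
  rownames(sp) <- NULL
  sp
}

#' Fit total displacement against initial proximo-distal position
#'
#' Ordinary least-squares fit of each cell's signed total displacement along
#' `axis` at `final_frame` against its initial y position. Under additive
#' uniform growth the relationship is linear (slope = fractional elongation
#' per unit initial y) with R-squared of 1; the fitted R-squared quantifies
#' how additive the observed spreading is. Only cells observed at both frame
#' 0 and `final_frame` enter the fit.
#'
#' @param ts a [track_set()].
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param final_frame frame at which total displacement is taken (default:
#'   last frame).
#' @return an object of class `additive_fit`: list with `slope` (um per um
#'   initial y), `intercept` (um), `r_squared`, `n`, `axis`, `final_frame`.
#' @export
fit_displacement_vs_initial <- function(ts, axis = c("y", "x", "z"),
                                        final_frame = NULL) {
  stopifnot(inherits(ts, "track_set"))
  axis <- match.arg(axis)
  if (is.null(final_frame)) final_frame <- n_frames(ts) - 1L
  p <- ts$points
  at0 <- p[p$frame == 0, ]
  atf <- p[p$frame == final_frame, ]
  ids <- intersect(at0$cell_id, atf$cell_id)
  if (length(ids) < 3)
    pg_error("plategrowth_too_few",
             "need >= 3 cells present at frames 0 and %d", final_frame)
  y0 <- at0$y[match(ids, at0$cell_id)]
  d <- atf[[axis]][match(ids, atf$cell_id)] -
    at0[[axis]][match(ids, at0$cell_id)]
  if (stats::sd(y0) == 0)
    pg_error("plategrowth_degenerate",
             "all cells share the same initial y; fit undefined")
  fit <- stats::lm(d ~ y0)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((d - mean(d))^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(ids), axis = axis,
                 final_frame = final_frame, lm = fit),
            class = "additive_fit")
}

#' @export
print.additive_fit <- function(x, ...) {
  cat(sprintf(paste0("<additive_fit> d%s(frame %d) ~ initial y, n = %d\n",
                     "  slope %.4g um/um, intercept %.4g um, R^2 = %.4f\n"),
              x$axis, x$final_frame, x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
coef.additive_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Percent elongation, rounded to the nearest integer
#'
#' `round(100 * delta / initial_length)`: e.g. a displacement difference of
#' 85 um across an initially 220 um region is a 39 percent elongation, and
#' 500 um of growth on a 1600 um bone is 31 percent.
#'
#' @param delta length change (um).
#' @param initial_length initial length (um), positive.
#' @return integer percent.
#' @export
percent_elongation <- function(delta, initial_length) {
  if (any(initial_length <= 0))
    pg_error("plategrowth_bad_arg", "initial_length must be positive")
  as.integer(round(100 * delta / initial_length))
}

#' Combined segmentation coverage percent
#'
#' The fraction of all cells covered when a tracked fraction is measured on a
#' labelled subpopulation: `round(tracked * labelled / 100)` (e.g. tracking
#' 98 percent of the 97 percent of cells that carry the label covers 95
#' percent of all cells).
#'
#' @param tracked_fraction,labelled_fraction percentages in `[0, 100]`.
#' @return integer percent.
#' @export
coverage_percent <- function(tracked_fraction, labelled_fraction) {
  if (any(tracked_fraction < 0 | tracked_fraction > 100) ||
      any(labelled_fraction < 0 | labelled_fraction > 100))
    pg_error("plategrowth_bad_arg", "fractions must be in [0, 100]")
  as.integer(round(tracked_fraction * labelled_fraction / 100))
}

#' Integer percentage of a count over a total
#'
#' Bookkeeping helper: `round(100 * n / total)` (e.g. 472 analysed of 481
#' identified cells is 98 percent).
#'
#' @param n count.
#' @param total positive total.
#' @return integer percent.
#' @export
fraction_percent <- function(n, total) {
  if (any(total <= 0)) pg_error("plategrowth_bad_arg", "total must be positive")
  as.integer(round(100 * n / total))
}
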