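# The parameter-free additive anisotropic growth model: every
# nearest-neighbour centre-to-centre gap along the proximo-distal axis grows
# per time step by the ECM-span increment plus both cells' radius increments,
# so positions rebuilt cumulatively from the proximal anchor displace each
# cell in proportion to the number of gaps proximal to it. The only inputs
# are the measured rates; there are no free parameters.

#' Growth rates driving the additive model
#'
#' @param d_cell_y change of mean cell extent (diameter) along y, um/h; the
#'   two half-extent (radius) increments of a neighbouring pair sum to this.
#' @param d_ecm_y change of mean ECM span per cell gap along y, um/h.
#' @param d_cell_x,d_ecm_x optional transverse rates (not used by the y-only
#'   model; carried for bookkeeping).
#' @return object of class `growth_rates` with the per-gap centre-to-centre
#'   increment `gap_increment = d_cell_y + d_ecm_y` (um/h).
#' @export
growth_rates <- function(d_cell_y, d_ecm_y, d_cell_x = NA_real_,
                         d_ecm_x = NA_real_) {
  if (!is.finite(d_cell_y) || !is.finite(d_ecm_y))
    pg_error("plategrowth_bad_arg", "rates must be finite")
  structure(list(d_cell_y = d_cell_y, d_ecm_y = d_ecm_y,
                 d_cell_x = d_cell_x, d_ecm_x = d_ecm_x,
                 gap_increment = d_cell_y + d_ecm_y),
            class = "growth_rates")
}

#' @export
print.growth_rates <- function(x, ...) {
  cat(sprintf("<growth_rates> cell y %.4g um/h, ECM y %.4g um/h (gap increment %.4g um/h)\n",
              x$d_cell_y, x$d_ecm_y, x$gap_increment))
  invisible(x)
}

#' Estimate growth rates from a voxel summary
#'
#' Least-squares slopes over time of the mean cell extent and the ECM span
#' along y, converted to per-cell-gap increments: the box-level y growth rate
#' (the sum of the two slopes, since ECM span is the box dimension minus the
#' mean cell extent) divided by the number of inter-layer gaps in the
#' measured region gives the centre-to-centre gap increment; the cell-extent
#' slope is already per cell, and the per-gap ECM increment is the remainder.
#'
#' @param summary a `voxel_summary` from [analyze_stack()].
#' @param n_gaps number of inter-layer y gaps spanned by the crop box (see
#'   [count_gaps_y()]).
#' @return a [growth_rates()] object.
#' @export
estimate_rates <- function(summary, n_gaps) {
  summary <- as.data.frame(summary)
  if (nrow(summary) < 2)
    pg_error("plategrowth_too_short", "need >= 2 frames to estimate rates")
  if (n_gaps < 1) pg_error("plategrowth_bad_arg", "n_gaps must be >= 1")
  slope <- function(v) unname(stats::coef(stats::lm(v ~ summary$hours))[2])
  s_cell <- slope(summary$cell_y)
  s_ecm <- slope(summary$ecm_y)
  gap <- (s_cell + s_ecm) / n_gaps      # box growth rate per gap
  growth_rates(d_cell_y = s_cell, d_ecm_y = gap - s_cell,
               d_cell_x = slope(summary$cell_x),
               d_ecm_x = NA_real_)
}

#' Additive anisotropic growth model
#'
#' Couples a set of [growth_rates()] to the gap-accumulation rule. Use
#' [predict.growth_model()] to produce trajectories from frame-0 positions.
#'
#' @param rates a [growth_rates()] object.
#' @param anchor `"proximal"` holds the most proximal cell fixed (default);
#'   `"origin"` holds the y origin fixed instead.
#' @param level_tol cells whose initial y differ by at most this (um) share a
#'   level and move together.
#' @return object of class `growth_model`.
#' @export
growth_model <- function(rates, anchor = c("proximal", "origin"),
                         level_tol = 1e-6) {
  stopifnot(inherits(rates, "growth_rates"))
  anchor <- match.arg(anchor)
  structure(list(rates = rates, anchor = anchor, level_tol = level_tol),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("<growth_model> gap increment %.4g um/h per step, anchor: %s\n",
              x$rates$gap_increment, x$anchor))
  invisible(x)
}

#' @export
coef.growth_model <- function(object, ...) {
  unlist(object$rates[c("d_cell_y", "d_ecm_y", "gap_increment")])
}

#' Predict cell trajectories under the additive growth model
#'
#' Starting from the frame-0 y positions, the cells are grouped into y
#' levels; at every time step each inter-level gap increases by the per-gap
#' increment (`d_ecm_y + d_cell_y` times the frame interval) and positions
#' are rebuilt cumulatively from the anchor, so a cell's displacement is the
#' sum of the increments of all gaps proximal to it. The step positions feed
#' the next step iteratively; with constant rates this reproduces the closed
#' form `y_i(k) = y_i(0) + rank_i * k * g`.
#'
#' @param object a [growth_model()].
#' @param newdata a [track_set()] (frame-0 positions are used) or a named
#'   numeric vector of initial y positions (um).
#' @param n_frames number of frames to predict, including frame 0.
#' @param frame_interval hours per step (taken from the track set when one is
#'   given).
#' @param ... unused.
#' @return object of class `predicted_trajectories`: list with `y` (cells x
#'   frames matrix, um), `rank` (gaps proximal to each cell), `rates`,
#'   `hours`.
#' @export
predict.growth_model <- function(object, newdata, n_frames,
                                 frame_interval = 1, ...) {
  if (inherits(newdata, "track_set")) {
    frame_interval <- newdata$frame_interval
    p <- newdata$points[newdata$points$frame == 0, ]
    y0 <- stats::setNames(p$y, p$cell_id)
  } else {
    y0 <- newdata
    if (is.null(names(y0)))
      names(y0) <- sprintf("cell%03d", seq_along(y0))
  }
  if (length(y0) < 2)
    pg_error("plategrowth_too_few", "need >= 2 cells to predict")
  if (!is.finite(object$rates$gap_increment))
    pg_error("plategrowth_bad_arg", "non-finite gap increment")
  ord <- order(y0)
  ys <- y0[ord]
  lev <- cumsum(c(TRUE, diff(ys) > object$level_tol))
  level_y0 <- tapply(ys, lev, min)
  nl <- length(level_y0)
  g <- object$rates$gap_increment * frame_interval
  Yl <- matrix(NA_real_, nl, n_frames)
  Yl[, 1] <- level_y0
  for (k in seq_len(n_frames - 1)) {
    gaps <- diff(Yl[, k])
    gaps <- gaps + g                              # every gap grows additively
    Yl[, k + 1] <- Yl[1, k] + cumsum(c(0, gaps))  # rebuilt from the anchor
  }
  if (object$anchor == "origin") {
    # hold y = 0 fixed: shift so the level nearest the origin keeps its y
    ref <- which.min(abs(level_y0))
    Yl <- Yl - outer(rep(1, nl), Yl[ref, ] - Yl[ref, 1])
  }
  Y <- matrix(NA_real_, length(y0), n_frames,
              dimnames = list(names(ys), as.character(0:(n_frames - 1))))
  Y[] <- Yl[lev, ]
  rank <- stats::setNames(lev - 1L, names(ys))
  out <- list(y = Y[names(y0), , drop = FALSE],
              rank = rank[names(y0)],
              rates = object$rates,
              hours = (0:(n_frames - 1)) * frame_interval)
  class(out) <- "predicted_trajectories"
  out
}

#' @export
print.predicted_trajectories <- function(x, ...) {
  cat(sprintf("<predicted_trajectories> %d cells x %d frames, gap increment %.4g um/h\n",
              nrow(x$y), ncol(x$y), x$rates$gap_increment))
  invisible(x)
}

#' @export
plot.predicted_trajectories <- function(x, observed = NULL, n_cells = 6, ...) {
  sel <- unique(round(seq(1, nrow(x$y), length.out = n_cells)))
  graphics::matplot(x$hours, t(x$y[sel, , drop = FALSE]), type = "l",
                    lty = 1, xlab = "time (h)", ylab = "y (um)",
                    main = "Predicted y trajectories", ...)
  if (inherits(observed, "track_set")) {
    Yo <- coord_matrix(observed, "y")
    keep <- intersect(rownames(x$y)[sel], rownames(Yo))
    graphics::matlines(x$hours, t(Yo[keep, seq_along(x$hours), drop = FALSE]),
                       lty = 2, col = "grey40")
  }
  invisible(x)
}

#' Percent error of predicted against observed trajectories
#'
#' Per cell and frame, `100 * |y_pred - y_obs| / |y_obs|`. Because the
#' percent error diverges near the origin, entries with `|y_obs|` below
#' `floor_um` are masked (NA) and excluded from the maximum.
#'
#' @param pred a `predicted_trajectories`.
#' @param observed a [track_set()] containing the same cells.
#' @param floor_um mask threshold on `|y_obs|` (um, default 5).
#' @return object of class `trajectory_error`: list with `errors` (cells x
#'   frames percent matrix, NA where masked), `max_percent`,
#'   `mean_percent`, `n_masked`.
#' @export
trajectory_error <- function(pred, observed, floor_um = 5) {
  stopifnot(inherits(pred, "predicted_trajectories"),
            inherits(observed, "track_set"))
  Yo <- coord_matrix(observed, "y")
  ids <- rownames(pred$y)
  if (!all(ids %in% rownames(Yo)))
    pg_error("plategrowth_mismatch",
             "observed track set lacks %d predicted cell(s)",
             sum(!ids %in% rownames(Yo)))
  nf <- min(ncol(pred$y), ncol(Yo))
  Yo <- Yo[ids, seq_len(nf), drop = FALSE]
  Yp <- pred$y[, seq_len(nf), drop = FALSE]
  err <- 100 * abs(Yp - Yo) / abs(Yo)
  masked <- abs(Yo) < floor_um
  masked[is.na(masked)] <- FALSE
  err[masked] <- NA_real_
  structure(list(errors = err,
                 max_percent = max(err, na.rm = TRUE),
                 mean_percent = mean(err, na.rm = TRUE),
                 n_masked = sum(masked, na.rm = TRUE)),
            class = "trajectory_error")
}

#' @export
print.trajectory_error <- function(x, ...) {
  cat(sprintf("<trajectory_error> max %.3g%%, mean %.3g%% (%d entries masked near y = 0)\n",
              x$max_percent, x$mean_percent, x$n_masked))
  invisible(x)
}
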