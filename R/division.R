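# Division-orientation and daughter-rearrangement analysis. For each division
# the 3D distance r between daughter centres and the unsigned angle Theta of
# the daughter-joining vector to the xz plane are followed over time, with
# relative time t = 1 denoting the moment of division. Theta = 0 means the
# division plane is orthogonal to the proximo-distal axis; Theta = 90 means
# the daughters separate along it.

#' Daughter-pair distance and angle series for one division
#'
#' `r(t)` is the Euclidean distance between daughter centres and
#' `Theta(t) = asin(|dy| / r)` in degrees (in `[0, 90]`, invariant to which
#' daughter is taken as origin and to rotations within the xz plane). Time is
#' re-indexed so that `t = 1` is the division frame. Frames where the
#' daughters coincide (`r = 0`) have undefined angle and are flagged.
#'
#' @param ts a [track_set()].
#' @param event a single row of `ts$lineage` (or a list with `daughter_a_id`,
#'   `daughter_b_id`, `division_frame`, `parent_id`).
#' @return object of class `division_event`: data.frame with columns `t`
#'   (1-based relative time), `frame`, `r` (um), `theta` (degrees),
#'   `coincident` (logical); attributes `parent_id`, `daughter_ids`.
#' @export
daughter_geometry <- function(ts, event) {
  stopifnot(inherits(ts, "track_set"))
  event <- as.list(event)
  a <- ts$points[ts$points$cell_id == event$daughter_a_id, ]
  b <- ts$points[ts$points$cell_id == event$daughter_b_id, ]
  if (nrow(a) == 0 || nrow(b) == 0)
    pg_error("plategrowth_unknown_cell", "daughter track missing")
  frames <- intersect(a$frame, b$frame)
  df <- as.integer(event$division_frame)
  if (!df %in% frames)
    pg_error("plategrowth_bad_lineage",
             "daughters not both tracked at division frame %d", df)
  frames <- sort(frames)
  ia <- match(frames, a$frame); ib <- match(frames, b$frame)
  dx <- a$x[ia] - b$x[ib]; dy <- a$y[ia] - b$y[ib]; dz <- a$z[ia] - b$z[ib]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  theta <- ifelse(r > 0, asin(pmin(1, abs(dy) / r)) * 180 / pi, NA_real_)
  out <- data.frame(t = frames - df + 1L, frame = frames, r = r,
                    theta = theta, coincident = r == 0)
  structure(out, class = c("division_event", "data.frame"),
            parent_id = event$parent_id,
            daughter_ids = c(event$daughter_a_id, event$daughter_b_id))
}

#' Daughter geometry for every lineage link
#' @param ts a [track_set()] with lineage links.
#' @return list of [daughter_geometry()] results, named by parent id.
#' @export
division_events <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  lin <- ts$lineage
  if (nrow(lin) == 0) return(list())
  ev <- lapply(seq_len(nrow(lin)), function(i) daughter_geometry(ts, lin[i, ]))
  names(ev) <- lin$parent_id
  ev
}

#' Angular histogram of division orientations
#'
#' Counts of the daughter angle Theta in bins over `[0, 90]` degrees, taken
#' either at the moment of division (`t = 1`) or at the final tracked frame.
#' Suitable for a polar (rose) display.
#'
#' @param events list of `division_event`s (see [division_events()]).
#' @param at `"division"` or `"final"`.
#' @param bin_width_deg angular bin width (degrees; default 15).
#' @return data.frame with columns `bin_lo`, `bin_hi`, `count`.
#' @export
orientation_histogram <- function(events, at = c("division", "final"),
                                  bin_width_deg = 15) {
  at <- match.arg(at)
  if (length(events) == 0)
    pg_error("plategrowth_too_few", "no division events")
  th <- vapply(events, function(e) {
    e <- as.data.frame(e)
    row <- if (at == "division") which(e$t == 1) else nrow(e)
    e$theta[row]
  }, numeric(1))
  th <- th[!is.na(th)]
  breaks <- seq(0, 90, by = bin_width_deg)
  if (breaks[length(breaks)] < 90) breaks <- c(breaks, 90)
  cnt <- table(cut(th, breaks, include.lowest = TRUE, right = FALSE))
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             count = as.vector(cnt))
}

#' Call daughter-cell rearrangements
#'
#' A daughter pair rearranged if its angle to the xz plane increased by more
#' than `threshold_deg` between the division frame and the final tracked
#' frame (i.e. the pair rotated toward the proximo-distal axis).
#'
#' @param events list of `division_event`s.
#' @param threshold_deg rearrangement threshold (degrees, default 30).
#' @return list with `calls` (data.frame: `parent_id`, `theta_division`,
#'   `theta_final`, `rearranged`) and `fraction` (rearranged fraction).
#' @export
call_rearrangements <- function(events, threshold_deg = 30) {
  if (length(events) == 0)
    pg_error("plategrowth_too_few", "no division events")
  rows <- lapply(names(events), function(id) {
    e <- as.data.frame(events[[id]])
    if (nrow(e) < 2)
      pg_error("plategrowth_too_short",
               "division event '%s' has fewer than 2 frames", id)
    data.frame(parent_id = id,
               theta_division = e$theta[which(e$t == 1)],
               theta_final = e$theta[nrow(e)])
  })
  calls <- do.call(rbind, rows)
  calls$rearranged <- (calls$theta_final - calls$theta_division) > threshold_deg
  list(calls = calls, fraction = mean(calls$rearranged))
}

#' Mitotic rate as a percent of the starting population
#'
#' `100 * (number of division events) / (number of cells at frame 0)`.
#'
#' @param ts a [track_set()].
#' @return percent (numeric).
#' @export
mitotic_rate <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  n0 <- length(cell_ids(ts, frame = 0))
  if (n0 == 0) pg_error("plategrowth_empty", "no cells at frame 0")
  100 * nrow(ts$lineage) / n0
}
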