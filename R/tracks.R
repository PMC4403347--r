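# Tissue coordinate convention used throughout the package:
#   y  - proximo-distal axis (PDA), +y distal
#   x  - in-plane transverse axis
#   z  - imaging (optical) axis
# Lengths are micrometres, times are hours, frames are 0-based integers
# (1 frame = frame_interval hours, default 1 h).

pg_error <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "plategrowth_error", "error")))
}

#' Construct a validated 4D track set
#'
#' A `track_set` is the central exchange object of the package: tissue-aligned
#' cell trajectories, optional lineage links between parent and daughter
#' tracks, and the frame interval. The y axis is the proximo-distal axis
#' (+y distal); x is the in-plane transverse axis; z is the imaging axis.
#'
#' @param points data.frame with columns `cell_id`, `frame` (0-based integer),
#'   `x`, `y`, `z` (micrometres).
#' @param lineage optional data.frame with columns `parent_id`,
#'   `daughter_a_id`, `daughter_b_id`, `division_frame`. The parent track must
#'   end at or before the division frame and both daughter tracks must begin
#'   at the division frame.
#' @param frame_interval hours per frame (default 1).
#' @return An object of class `track_set` with elements `points`, `lineage`
#'   and `frame_interval`. Rows of `points` are stored sorted by
#'   (`cell_id`, `frame`).
#' @examples
#' pts <- data.frame(cell_id = "a", frame = 0:2, x = 0, y = 0:2, z = 0)
#' ts <- track_set(pts)
#' n_frames(ts)
#' @export
track_set <- function(points, lineage = NULL, frame_interval = 1) {
  req <- c("cell_id", "frame", "x", "y", "z")
  miss <- setdiff(req, names(points))
  if (length(miss) > 0)
    pg_error("plategrowth_missing_column",
             "missing track column(s): %s", paste(miss, collapse = ", "))
  points <- points[req]
  points$cell_id <- as.character(points$cell_id)
  for (cc in c("x", "y", "z")) {
    v <- points[[cc]]
    if (!is.numeric(v))
      pg_error("plategrowth_nonnumeric",
               "column '%s' is not numeric", cc)
    if (any(!is.finite(v)))
      pg_error("plategrowth_nonnumeric",
               "non-finite %s coordinate at row %d", cc,
               which(!is.finite(v))[1])
  }
  if (any(points$frame != round(points$frame)) || any(points$frame < 0))
    pg_error("plategrowth_bad_frame", "frames must be non-negative integers")
  points$frame <- as.integer(points$frame)
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      frame_interval <= 0)
    pg_error("plategrowth_bad_frame", "frame_interval must be a positive number")

  key <- paste(points$cell_id, points$frame)
  if (anyDuplicated(key))
    pg_error("plategrowth_duplicate_row",
             "duplicated (cell_id, frame) at row %d: %s",
             which(duplicated(key))[1], key[which(duplicated(key))[1]])
  points <- points[order(points$cell_id, points$frame), , drop = FALSE]
  rownames(points) <- NULL

  # frames within a track must be consecutive
  by_cell <- split(points$frame, points$cell_id)
  for (id in names(by_cell)) {
    f <- by_cell[[id]]
    if (length(f) > 1 && any(diff(f) != 1L))
      pg_error("plategrowth_frame_gap",
               "track '%s' has a frame gap after frame %d",
               id, f[which(diff(f) != 1L)[1]])
  }

  lineage <- validate_lineage(lineage, by_cell)

  structure(list(points = points, lineage = lineage,
                 frame_interval = frame_interval),
            class = "track_set")
}

validate_lineage <- function(lineage, by_cell) {
  cols <- c("parent_id", "daughter_a_id", "daughter_b_id", "division_frame")
  if (is.null(lineage) || nrow(as.data.frame(lineage)) == 0) {
    lineage <- data.frame(parent_id = character(), daughter_a_id = character(),
                          daughter_b_id = character(),
                          division_frame = integer())
    return(lineage)
  }
  lineage <- as.data.frame(lineage)
  miss <- setdiff(cols, names(lineage))
  if (length(miss) > 0)
    pg_error("plategrowth_missing_column",
             "missing lineage column(s): %s", paste(miss, collapse = ", "))
  lineage <- lineage[cols]
  for (cc in cols[1:3]) lineage[[cc]] <- as.character(lineage[[cc]])
  lineage$division_frame <- as.integer(lineage$division_frame)
  for (i in seq_len(nrow(lineage))) {
    ids <- unlist(lineage[i, 1:3])
    for (id in ids)
      if (!id %in% names(by_cell))
        pg_error("plategrowth_unknown_cell",
                 "lineage row %d references unknown cell '%s'", i, id)
    df <- lineage$division_frame[i]
    if (max(by_cell[[lineage$parent_id[i]]]) > df)
      pg_error("plategrowth_bad_lineage",
               "parent '%s' tracked past its division frame %d",
               lineage$parent_id[i], df)
    for (d in ids[2:3])
      if (min(by_cell[[d]]) != df)
        pg_error("plategrowth_bad_lineage",
                 "daughter '%s' does not begin at division frame %d", d, df)
  }
  lineage <- lineage[order(lineage$parent_id), , drop = FALSE]
  rownames(lineage) <- NULL
  lineage
}

#' Number of frames spanned by a track set
#'
#' Frames are 0-based, so a set whose last observed frame is `k` has
#' `k + 1` frames.
#' @param ts a `track_set`.
#' @return integer frame count.
#' @export
n_frames <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  if (nrow(ts$points) == 0) return(0L)
  max(ts$points$frame) + 1L
}

#' Cell identifiers present in a track set
#' @param ts a `track_set`.
#' @param frame optional frame; if given, only cells observed at that frame.
#' @return character vector of cell ids (sorted).
#' @export
cell_ids <- function(ts, frame = NULL) {
  p <- ts$points
  if (!is.null(frame)) p <- p[p$frame == frame, , drop = FALSE]
  sort(unique(p$cell_id))
}

#' Restrict a track set to a subset of cells
#' @param ts a `track_set`.
#' @param cells character vector of cell ids to keep.
#' @param drop_lineage drop lineage rows referencing removed cells
#'   (default TRUE).
#' @return a `track_set`.
#' @export
subset_tracks <- function(ts, cells, drop_lineage = TRUE) {
  pts <- ts$points[ts$points$cell_id %in% cells, , drop = FALSE]
  lin <- ts$lineage
  if (drop_lineage && nrow(lin) > 0) {
    keep <- lin$parent_id %in% cells & lin$daughter_a_id %in% cells &
      lin$daughter_b_id %in% cells
    lin <- lin[keep, , drop = FALSE]
  }
  track_set(pts, lin, ts$frame_interval)
}

# per-cell coordinate matrix (cells x frames), NA where a cell is absent
coord_matrix <- function(ts, coord = "y") {
  ids <- cell_ids(ts)
  nf <- n_frames(ts)
  m <- matrix(NA_real_, length(ids), nf,
              dimnames = list(ids, as.character(0:(nf - 1))))
  p <- ts$points
  m[cbind(match(p$cell_id, ids), p$frame + 1L)] <- p[[coord]]
  m
}

#' @export
print.track_set <- function(x, ...) {
  nc <- length(unique(x$points$cell_id))
  cat(sprintf("<track_set> %d cells, %d frames (%g h/frame), %d division link(s)\n",
              nc, n_frames(x), x$frame_interval, nrow(x$lineage)))
  if (nrow(x$points) > 0) {
    r <- apply(x$points[c("x", "y", "z")], 2, range)
    cat(sprintf("  extent (um): x [%.1f, %.1f], y [%.1f, %.1f], z [%.1f, %.1f]\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
  invisible(x)
}

#' Default column mapping for delimited track tables
#'
#' The on-disk dialect is a delimited text table with one row per cell per
#' frame. `parent` names an optional column carrying the parent id of daughter
#' tracks (empty for non-daughters), from which lineage links are rebuilt.
#'
#' @param cell_id,frame,x,y,z,parent column names in the file.
#' @param sep field separator.
#' @return a named list usable as the `dialect` argument of [read_tracks()].
#' @export
track_dialect <- function(cell_id = "cell_id", frame = "frame",
                          x = "x_um", y = "y_um", z = "z_um",
                          parent = "parent_id", sep = ",") {
  list(cell_id = cell_id, frame = frame, x = x, y = y, z = z,
       parent = parent, sep = sep)
}

#' Read a cell-track table
#'
#' Reads a delimited text file of cell positions over time and returns a
#' validated [track_set()]. Lineage links are reconstructed from the parent
#' column: every parent must have exactly two daughter tracks, both starting
#' at the same frame (the division frame).
#'
#' @param path file path.
#' @param dialect column mapping from [track_dialect()], or a path to a YAML
#'   file holding the same keys.
#' @return a `track_set`.
#' @export
read_tracks <- function(path, dialect = track_dialect()) {
  if (is.character(dialect) && length(dialect) == 1)
    dialect <- utils::modifyList(track_dialect(), yaml::read_yaml(dialect))
  if (!file.exists(path))
    pg_error("plategrowth_io", "track file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell_id", "frame", "x", "y", "z")
  for (k in need)
    if (!dialect[[k]] %in% names(raw))
      pg_error("plategrowth_missing_column",
               "column '%s' (mapped to %s) missing from %s",
               dialect[[k]], k, path)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (any(is.na(v) & !is.na(raw[[col]])))
      pg_error("plategrowth_nonnumeric",
               "non-numeric %s value at data row %d of %s",
               what, which(is.na(v))[1], path)
    v
  }
  pts <- data.frame(cell_id = raw[[dialect$cell_id]],
                    frame = num(dialect$frame, "frame"),
                    x = num(dialect$x, "x"), y = num(dialect$y, "y"),
                    z = num(dialect$z, "z"),
                    stringsAsFactors = FALSE)
  lineage <- NULL
  pc <- dialect$parent
  if (!is.null(pc) && pc %in% names(raw)) {
    par <- raw[[pc]]
    par[is.na(par)] <- ""
    has <- par != ""
    if (any(has)) {
      map <- unique(data.frame(cell = pts$cell_id[has], parent = par[has],
                               stringsAsFactors = FALSE))
      first <- tapply(pts$frame[has], pts$cell_id[has], min)
      lineage <- do.call(rbind, lapply(split(map, map$parent), function(g) {
        if (nrow(g) != 2)
          pg_error("plategrowth_bad_lineage",
                   "parent '%s' has %d daughter track(s); expected 2",
                   g$parent[1], nrow(g))
        d <- sort(g$cell)
        data.frame(parent_id = g$parent[1], daughter_a_id = d[1],
                   daughter_b_id = d[2],
                   division_frame = as.integer(first[[d[1]]]),
                   stringsAsFactors = FALSE)
      }))
    }
  }
  track_set(pts, lineage)
}

#' Write a cell-track table
#'
#' Writes the delimited representation read back by [read_tracks()]:
#' `read_tracks(write_tracks(ts, f))` reproduces `ts`. Daughter rows carry
#' their parent id in the parent column.
#'
#' @param ts a `track_set`.
#' @param path output file path.
#' @param dialect column mapping, see [track_dialect()].
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path, dialect = track_dialect()) {
  stopifnot(inherits(ts, "track_set"))
  p <- ts$points
  parent <- rep("", nrow(p))
  if (nrow(ts$lineage) > 0) {
    dmap <- c(stats::setNames(ts$lineage$parent_id, ts$lineage$daughter_a_id),
              stats::setNames(ts$lineage$parent_id, ts$lineage$daughter_b_id))
    hit <- p$cell_id %in% names(dmap)
    parent[hit] <- dmap[p$cell_id[hit]]
  }
  out <- data.frame(a = p$cell_id, b = p$frame,
                    c = sprintf("%.10g", p$x), d = sprintf("%.10g", p$y),
                    e = sprintf("%.10g", p$z), f = parent,
                    stringsAsFactors = FALSE)
  names(out) <- unlist(dialect[c("cell_id", "frame", "x", "y", "z", "parent")])
  ok <- tryCatch({
    utils::write.table(out, path, sep = dialect$sep, quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) pg_error("plategrowth_io", "cannot write track file: %s", path)
  invisible(path)
}

#' Recentre the proximo-distal origin
#'
#' Shifts the y coordinate so that the midpoint of the frame-0 y range lies at
#' the origin ("the middle of the tissue"); x and z are unchanged. Idempotent,
#' and preserves all pairwise distances.
#'
#' @param ts a `track_set`.
#' @return a `track_set` with shifted y.
#' @export
recentre <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  if (nrow(ts$points) == 0)
    pg_error("plategrowth_empty", "cannot recentre an empty track set")
  y0 <- ts$points$y[ts$points$frame == 0]
  if (length(y0) == 0)
    pg_error("plategrowth_empty", "no cells at frame 0")
  mid <- (min(y0) + max(y0)) / 2
  ts$points$y <- ts$points$y - mid
  ts
}
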