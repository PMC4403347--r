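# Voxel image stacks and the synthetic renderer. Voxel (i, j, k) covers the
# physical interval [(i-1)*h, i*h) x ... so voxel centres sit at (i - 0.5)*h.

#' Construct a 4D image stack
#'
#' @param frames list of 3D numeric arrays (x, y, z order), one per frame,
#'   all the same shape, non-negative intensities.
#' @param voxel_um physical voxel size, either a scalar (isotropic) or
#'   `c(hx, hy, hz)` micrometres per voxel.
#' @param frame_interval hours between frames.
#' @return an object of class `image_stack4d`.
#' @export
image_stack4d <- function(frames, voxel_um = 1, frame_interval = 1) {
  if (!is.list(frames) || length(frames) == 0)
    pg_error("plategrowth_bad_stack", "frames must be a non-empty list")
  dims <- dim(frames[[1]])
  if (length(dims) != 3)
    pg_error("plategrowth_bad_stack", "each frame must be a 3D array")
  for (f in frames) {
    if (!identical(dim(f), dims))
      pg_error("plategrowth_bad_stack", "inconsistent frame shapes")
    if (any(f < 0)) pg_error("plategrowth_bad_stack",
                             "intensities must be non-negative")
  }
  if (length(voxel_um) == 1) voxel_um <- rep(voxel_um, 3)
  structure(list(frames = frames, voxel_um = voxel_um,
                 frame_interval = frame_interval),
            class = "image_stack4d")
}

#' @export
print.image_stack4d <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack4d> %d frame(s), %d x %d x %d voxels (%g x %g x %g um)\n",
              length(x$frames), d[1], d[2], d[3],
              x$voxel_um[1], x$voxel_um[2], x$voxel_um[3]))
  invisible(x)
}

#' Render a track set as a synthetic 4D image stack
#'
#' Rasterises each cell as a bright ellipsoid (intensity ~ 1) on a dark
#' background (~ 0), with additive Gaussian noise, standing in for a
#' cytoplasmic-fluorescence channel. Cell semi-axes follow the radius
#' schedule, so anisotropic cell-extent growth is reflected in the images.
#'
#' @param ts a [track_set()].
#' @param radius_schedule data.frame with columns `frame`, `rx`, `ry`, `rz`
#'   (um; see [radius_schedule()]), or a numeric vector of per-frame isotropic
#'   radii, or a single radius.
#' @param voxel_um isotropic voxel size (um).
#' @param region `c(Lx, Ly, Lz)` extent of the rendered volume (um); cells
#'   outside are clipped.
#' @param noise_sd sd of the additive Gaussian intensity noise (intensity
#'   units; clamped at 0 from below).
#' @param frames which frames to render (default all).
#' @return an [image_stack4d()].
#' @export
render_images <- function(ts, radius_schedule, voxel_um = 1,
                          region = c(90, 220, 90), noise_sd = 0.005,
                          frames = NULL) {
  stopifnot(inherits(ts, "track_set"))
  nf <- n_frames(ts)
  if (is.null(frames)) frames <- 0:(nf - 1)
  rs <- normalise_radius_schedule(radius_schedule, nf)
  if (any(unlist(rs[c("rx", "ry", "rz")]) <= 0))
    pg_error("plategrowth_bad_radius", "radii must be positive")
  if (any(unlist(rs[c("rx", "ry", "rz")]) < voxel_um))
    pg_error("plategrowth_bad_radius",
             "cell radius smaller than one voxel (%g um)", voxel_um)
  dims <- pmax(1L, as.integer(ceiling(region / voxel_um)))
  out <- vector("list", length(frames))
  for (qi in seq_along(frames)) {
    fr <- frames[qi]
    arr <- array(0, dims)
    p <- ts$points[ts$points$frame == fr, , drop = FALSE]
    r <- rs[rs$frame == fr, ]
    if (nrow(r) == 0)
      pg_error("plategrowth_bad_radius", "no radius scheduled for frame %d", fr)
    for (ci in seq_len(nrow(p)))
      arr <- paint_ellipsoid(arr, c(p$x[ci], p$y[ci], p$z[ci]),
                             c(r$rx, r$ry, r$rz), voxel_um)
    if (noise_sd > 0) {
      arr <- arr + array(stats::rnorm(length(arr), 0, noise_sd), dims)
      arr[arr < 0] <- 0
    }
    out[[qi]] <- arr
  }
  image_stack4d(out, voxel_um = voxel_um, frame_interval = ts$frame_interval)
}

normalise_radius_schedule <- function(radius_schedule, nf) {
  if (is.data.frame(radius_schedule)) {
    need <- c("frame", "rx", "ry", "rz")
    if (!all(need %in% names(radius_schedule)))
      pg_error("plategrowth_bad_radius",
               "radius schedule needs columns frame, rx, ry, rz")
    return(radius_schedule)
  }
  r <- as.numeric(radius_schedule)
  if (length(r) == 1) r <- rep(r, nf)
  if (length(r) != nf)
    pg_error("plategrowth_bad_radius",
             "radius schedule length %d does not match %d frames",
             length(r), nf)
  data.frame(frame = 0:(nf - 1), rx = r, ry = r, rz = r)
}

paint_ellipsoid <- function(arr, centre, semi, h) {
  dims <- dim(arr)
  lo <- pmax(1L, floor((centre - semi) / h) + 1L)
  hi <- pmin(dims, ceiling((centre + semi) / h))
  if (any(lo > hi)) return(arr)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  cx <- (ii - 0.5) * h; cy <- (jj - 0.5) * h; cz <- (kk - 0.5) * h
  qx <- ((cx - centre[1]) / semi[1])^2
  qy <- ((cy - centre[2]) / semi[2])^2
  qz <- ((cz - centre[3]) / semi[3])^2
  q <- outer(outer(qx, qy, `+`), qz, `+`)
  sel <- which(q <= 1, arr.ind = TRUE)
  if (nrow(sel) > 0)
    arr[cbind(ii[sel[, 1]], jj[sel[, 2]], kk[sel[, 3]])] <- 1
  arr
}

#' Write an image stack as multi-page TIFF files
#'
#' One multi-page TIFF per frame (`frame_0000.tif`, ...), pages along z.
#' Intensities are clamped to `[0, 1]` for storage.
#'
#' @param stack an [image_stack4d()].
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "image_stack4d"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fi in seq_along(stack$frames)) {
    arr <- stack$frames[[fi]]
    arr[arr < 0] <- 0
    arr[arr > 1] <- 1
    pages <- lapply(seq_len(dim(arr)[3]), function(k) t(arr[, , k]))
    tiff::writeTIFF(pages, file.path(dir, sprintf("frame_%04d.tif", fi - 1)),
                    bits.per.sample = 16L)
  }
  invisible(dir)
}

#' Read an image stack written by [write_stack()]
#'
#' @param dir directory of `frame_*.tif` files.
#' @param voxel_um voxel size metadata to attach (um).
#' @param frame_interval hours between frames.
#' @return an [image_stack4d()].
#' @export
read_stack <- function(dir, voxel_um = 1, frame_interval = 1) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.tif$",
                           full.names = TRUE))
  if (length(files) == 0)
    pg_error("plategrowth_io", "no frame_*.tif files in %s", dir)
  frames <- lapply(files, function(f) {
    pages <- tiff::readTIFF(f, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
    arr
  })
  image_stack4d(frames, voxel_um = voxel_um, frame_interval = frame_interval)
}
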