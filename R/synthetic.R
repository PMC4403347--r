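# Synthetic growing-tissue generator.
#
# Emulates a proliferative-zone region (default 90 x 220 x 90 um, y = PDA)
# imaged hourly, growing additively along y: every inter-layer centre-centre
# gap increases per hour by the ECM-span rate plus the cell-extent rate, so a
# cell's displacement is proportional to the number of gaps proximal to it.
# Optional planted behaviours: convergent-extension movers, oriented divisions
# with or without daughter rearrangement, per-frame positional jitter.

#' Specify a synthetic growing tissue
#'
#' The specification holds the study conditions for the generator: geometry,
#' additive growth rates of mean cell extent and mean ECM span along the
#' proximo-distal (y) and transverse (x) axes, and the planted behaviours.
#' Rates are micrometres per hour; all lengths micrometres.
#'
#' @param n_cells target number of cells; the realised lattice count (reported
#'   in the ground truth) is the achievable product of per-axis counts closest
#'   to this target.
#' @param region `c(Lx, Ly, Lz)` tissue extent in micrometres.
#' @param n_frames number of hourly frames (frames 0..n_frames-1).
#' @param cell_radius0 initial cell radius (um).
#' @param ecm_gap0_y,ecm_gap0_x initial ECM gap between cell surfaces along y
#'   and along x/z (um); together with `cell_radius0` these set the packing
#'   pitch of the close-packed lattice, which is then thinned uniformly to the
#'   target cell count.
#' @param rate_cell_y,rate_cell_x change of mean cell extent (diameter), um/h.
#' @param rate_ecm_y,rate_ecm_x change of mean ECM span per cell gap, um/h.
#' @param frac_ce fraction of cells planted as convergent-extension movers
#'   (converge in x while extending in y).
#' @param ce_shrink fractional approach per hour of a CE mover toward the x
#'   centroid of its own 3-nearest-neighbour polygon (toward the tissue x
#'   mid-line when every cell converges), emulating intercalation-like
#'   narrowing of the local neighbourhood; the approach ramps linearly and
#'   saturates at 95 percent, so the default 0.1/h settles within ~10 h.
#' @param ce_margin minimum final-frame polygon-width decrease (um) a planted
#'   CE mover must produce; movers are planted only where this is achievable
#'   without disturbing any other cell's polygon label.
#' @param divisions `NULL`, or a data.frame with columns `frame` (division
#'   frame, 1-based to n_frames-2), `theta_deg` (angle of the daughter-joining
#'   vector to the xz plane at division, degrees in `[0, 90]`) and `rearrange`
#'   (logical: daughters subsequently rotate toward the y axis).
#' @param rearrange_target,rearrange_frames final angle (degrees) and number
#'   of frames over which rearranging daughter pairs rotate.
#' @param jitter_sd per-frame isotropic Gaussian positional noise sd (um).
#' @param lattice_sd static Gaussian perturbation of lattice sites (um).
#' @param seed integer seed; the same seed reproduces the tissue exactly.
#' @return an object of class `tissue_spec` (a validated list).
#' @export
tissue_spec <- function(n_cells = 472, region = c(90, 220, 90), n_frames = 56,
                        cell_radius0 = 6, ecm_gap0_y = 3, ecm_gap0_x = 3,
                        rate_cell_y = 0.026, rate_cell_x = 0.022,
                        rate_ecm_y = 0.022, rate_ecm_x = 0.011,
                        frac_ce = 0, ce_shrink = 0.1, ce_margin = 0.25,
                        divisions = NULL, rearrange_target = 80,
                        rearrange_frames = 15,
                        jitter_sd = 0.5, lattice_sd = 0.5, seed = 1) {
  spec <- as.list(environment())
  if (length(region) != 3 || any(!is.finite(region)) || any(region <= 0))
    pg_error("plategrowth_bad_spec", "region must be 3 positive lengths")
  if (n_frames < 2) pg_error("plategrowth_bad_spec", "n_frames must be >= 2")
  if (cell_radius0 <= 0 || ecm_gap0_y <= 0 || ecm_gap0_x <= 0)
    pg_error("plategrowth_bad_spec", "lengths must be positive")
  if (frac_ce < 0 || frac_ce > 1)
    pg_error("plategrowth_bad_spec", "frac_ce must be in [0, 1]")
  if (jitter_sd < 0 || lattice_sd < 0)
    pg_error("plategrowth_bad_spec", "noise sds must be non-negative")
  if (!is.null(divisions)) {
    divisions <- as.data.frame(divisions)
    need <- c("frame", "theta_deg", "rearrange")
    if (!all(need %in% names(divisions)))
      pg_error("plategrowth_bad_spec",
               "divisions needs columns frame, theta_deg, rearrange")
    if (any(divisions$frame < 1 | divisions$frame > n_frames - 2))
      pg_error("plategrowth_bad_spec",
               "division frames must lie in [1, n_frames - 2]")
    if (any(divisions$theta_deg < 0 | divisions$theta_deg > 90))
      pg_error("plategrowth_bad_spec", "theta_deg must be in [0, 90]")
    spec$divisions <- divisions
  }
  structure(spec, class = "tissue_spec")
}

#' @export
print.tissue_spec <- function(x, ...) {
  cat(sprintf(paste0("<tissue_spec> ~%d cells in %g x %g x %g um, %d frames\n",
                     "  rates (um/h): cell y %g / x %g, ECM y %g / x %g\n",
                     "  frac_ce %g, %d division(s), jitter sd %g, seed %d\n"),
              x$n_cells, x$region[1], x$region[2], x$region[3], x$n_frames,
              x$rate_cell_y, x$rate_cell_x, x$rate_ecm_y, x$rate_ecm_x,
              x$frac_ce,
              if (is.null(x$divisions)) 0L else nrow(x$divisions),
              x$jitter_sd, x$seed))
  invisible(x)
}

# choose per-axis lattice counts whose product approximates n_cells while
# keeping pitch >= 2 * cell_radius0 on every axis
lattice_counts <- function(spec) {
  r0 <- spec$cell_radius0
  L <- spec$region
  pitch0 <- c(2 * r0 + spec$ecm_gap0_x, 2 * r0 + spec$ecm_gap0_y,
              2 * r0 + spec$ecm_gap0_x)
  cap <- pmax(1L, floor(L / pitch0))
  cap[2] <- max(cap[2], 2L)
  if (spec$n_cells > prod(cap))
    pg_error("plategrowth_packing",
             "region too small for %d cells at cell_radius0 = %g (capacity %d)",
             spec$n_cells, r0, prod(cap))
  best <- NULL
  for (ny in 2:cap[2]) {
    target_xz <- spec$n_cells / ny
    nx <- max(1L, min(cap[1], round(sqrt(target_xz * L[1] / L[3]))))
    for (dx in -1:1) {
      nxx <- nx + dx
      if (nxx < 1 || nxx > cap[1]) next
      nz <- max(1L, min(cap[3], round(target_xz / nxx)))
      for (dz in -1:1) {
        nzz <- nz + dz
        if (nzz < 1 || nzz > cap[3]) next
        prod_n <- nxx * ny * nzz
        aspect <- abs(log((L[2] / ny) / (L[1] / nxx)) -
                        log(pitch0[2] / pitch0[1]))
        score <- abs(prod_n - spec$n_cells) / spec$n_cells + 0.5 * aspect
        if (is.null(best) || score < best$score)
          best <- list(n = c(nxx, ny, nzz), score = score)
      }
    }
  }
  best$n
}

#' Generate a synthetic growing tissue with known ground truth
#'
#' Builds cells on a (perturbed) rectangular lattice filling the region, then
#' lets the tissue grow additively: each inter-layer y gap increases every
#' hour by `rate_ecm_y + rate_cell_y`, so total y displacement is proportional
#' to a cell's initial y (anchored at the proximal face); x gaps grow
#' analogously about the tissue mid-line. Planted convergent-extension movers
#' additionally contract toward the x mid-line; planted divisions split a
#' parent into two daughters `2 * cell_radius0` apart along a direction at the
#' planted angle to the xz plane, with rearranging pairs rotating toward the
#' y axis afterwards. Seeded per-frame jitter is added last.
#'
#' With `jitter_sd = 0`, `lattice_sd = 0` and `frac_ce = 0` the trajectories
#' satisfy the additive law exactly (displacement linear in initial y).
#'
#' @param spec a [tissue_spec()].
#' @return list with elements `tracks` (a [track_set()]) and `truth` (a list:
#'   per-cell `labels` — normal / CE / divider —, true `positions` before
#'   jitter, lattice layout, planted `divisions`, `ce_cells` and the rates).
#' @export
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  withr::with_seed(spec$seed, generate_tissue_impl(spec))
}

generate_tissue_impl <- function(spec) {
  L <- spec$region
  nxyz <- lattice_counts(spec)
  nx <- nxyz[1]; ny <- nxyz[2]; nz <- nxyz[3]
  pitch <- L / nxyz
  if (any(pitch < 2 * spec$cell_radius0))
    pg_error("plategrowth_packing", "lattice pitch below cell diameter")
  grid <- expand.grid(ix = 0:(nx - 1), jy = 0:(ny - 1), kz = 0:(nz - 1))
  n <- nrow(grid)
  ids <- sprintf("c%04d", seq_len(n))
  base <- cbind(x = (grid$ix + 0.5) * pitch[1],
                y = (grid$jy + 0.5) * pitch[2],
                z = (grid$kz + 0.5) * pitch[3])
  base <- base + matrix(stats::rnorm(3 * n, 0, spec$lattice_sd), n, 3)

  nf <- spec$n_frames
  hours <- 0:(nf - 1)
  g_y <- spec$rate_ecm_y + spec$rate_cell_y   # per-gap centre-centre rate
  g_x <- spec$rate_ecm_x + spec$rate_cell_x
  cx <- L[1] / 2

  # baseline additive trajectories: n x nf per coordinate
  X <- outer(base[, "x"], rep(1, nf)) +
    outer((grid$ix - (nx - 1) / 2) * g_x, hours)
  Y <- outer(base[, "y"], rep(1, nf)) + outer(grid$jy * g_y, hours)
  Z <- outer(base[, "z"], rep(1, nf))

  # jitter drawn up-front so frame-0 geometry is fixed before planting
  jit <- if (spec$jitter_sd > 0)
    array(stats::rnorm(3 * n * nf, 0, spec$jitter_sd), c(n, nf, 3))
  else array(0, c(n, nf, 3))

  # --- divisions -----------------------------------------------------------
  div <- spec$divisions
  parents <- character(0)
  div_truth <- NULL
  daughter_pts <- NULL
  if (!is.null(div) && nrow(div) > 0) {
    interior <- which(grid$ix > 0 & grid$ix < nx - 1 &
                        grid$jy > 0 & grid$jy < ny - 1 &
                        (nz < 3 | (grid$kz > 0 & grid$kz < nz - 1)))
    if (length(interior) < nrow(div)) interior <- seq_len(n)
    pick <- sample(interior, nrow(div))
    parents <- ids[pick]
    r0 <- spec$cell_radius0
    rows <- list()
    for (e in seq_len(nrow(div))) {
      i <- pick[e]
      f <- div$frame[e]
      th0 <- div$theta_deg[e]
      phi <- stats::runif(1, 0, 2 * pi)
      t_rel <- 0:(nf - 1 - f)
      th <- if (isTRUE(div$rearrange[e]))
        pmin(spec$rearrange_target,
             th0 + (spec$rearrange_target - th0) *
               pmin(1, t_rel / spec$rearrange_frames))
      else rep(th0, length(t_rel))
      thr <- th * pi / 180
      dvec <- cbind(cos(thr) * cos(phi), sin(thr), cos(thr) * sin(phi))
      cen <- cbind(X[i, (f + 1):nf], Y[i, (f + 1):nf], Z[i, (f + 1):nf])
      for (s in c(1, -1)) {
        did <- paste0(ids[i], if (s > 0) "a" else "b")
        rows[[length(rows) + 1]] <- data.frame(
          cell_id = did, frame = f + t_rel,
          x = cen[, 1] + s * r0 * dvec[, 1],
          y = cen[, 2] + s * r0 * dvec[, 2],
          z = cen[, 3] + s * r0 * dvec[, 3])
      }
    }
    daughter_pts <- do.call(rbind, rows)
    div_truth <- data.frame(parent_id = parents,
                            daughter_a_id = paste0(parents, "a"),
                            daughter_b_id = paste0(parents, "b"),
                            division_frame = div$frame,
                            theta_deg = div$theta_deg,
                            rearrange = as.logical(div$rearrange))
  }

  # --- convergent-extension movers ----------------------------------------
  full <- setdiff(seq_len(n), match(parents, ids))  # full-length tracks
  ce_idx <- integer(0)
  ce_target <- numeric(0)
  if (spec$frac_ce >= 1) {
    # whole-population convergence: contraction toward the tissue mid-line
    ce_idx <- full
    ce_target <- rep(cx, length(full))
  } else if (spec$frac_ce > 0) {
    plan <- plant_ce(spec, full, frame0 = cbind(
      x = X[, 1] + jit[, 1, 1], y = Y[, 1] + jit[, 1, 2],
      z = Z[, 1] + jit[, 1, 3]), X = X, Y = Y, hours = hours)
    ce_idx <- plan$idx
    ce_target <- plan$target
  }
  if (length(ce_idx) > 0) {
    shrinkage <- pmin(0.95, spec$ce_shrink * hours)  # fractional contraction
    X[ce_idx, ] <- ce_target +
      (X[ce_idx, , drop = FALSE] - ce_target) *
      matrix(1 - shrinkage, length(ce_idx), nf, byrow = TRUE)
  }

  # --- assemble ------------------------------------------------------------
  keep_frames <- function(i) {
    if (ids[i] %in% parents)
      seq_len(div$frame[match(ids[i], parents)])  # frames 0..f-1
    else seq_len(nf)
  }
  pts <- do.call(rbind, lapply(seq_len(n), function(i) {
    fr <- keep_frames(i)
    data.frame(cell_id = ids[i], frame = fr - 1L,
               x = X[i, fr] + jit[i, fr, 1],
               y = Y[i, fr] + jit[i, fr, 2],
               z = Z[i, fr] + jit[i, fr, 3])
  }))
  true_pts <- do.call(rbind, lapply(seq_len(n), function(i) {
    fr <- keep_frames(i)
    data.frame(cell_id = ids[i], frame = fr - 1L,
               x = X[i, fr], y = Y[i, fr], z = Z[i, fr])
  }))
  if (!is.null(daughter_pts)) {
    djit <- matrix(stats::rnorm(3 * nrow(daughter_pts), 0, spec$jitter_sd),
                   ncol = 3)
    obs <- daughter_pts
    obs[c("x", "y", "z")] <- obs[c("x", "y", "z")] + djit
    pts <- rbind(pts, obs)
    true_pts <- rbind(true_pts, daughter_pts)
  }

  labels <- stats::setNames(rep("normal", n), ids)
  labels[ce_idx] <- "CE"
  labels[match(parents, ids)] <- "divider"
  if (!is.null(div_truth))
    labels <- c(labels,
                stats::setNames(rep("normal", 2 * nrow(div_truth)),
                                c(div_truth$daughter_a_id,
                                  div_truth$daughter_b_id)))

  ts <- track_set(pts, lineage = if (is.null(div_truth)) NULL else
    div_truth[1:4], frame_interval = 1)
  truth <- list(labels = labels,
                positions = true_pts[order(true_pts$cell_id,
                                           true_pts$frame), ],
                lattice = list(n = nxyz, pitch = pitch,
                               ix = stats::setNames(grid$ix, ids),
                               jy = stats::setNames(grid$jy, ids),
                               kz = stats::setNames(grid$kz, ids)),
                gap_rate_y = g_y, gap_rate_x = g_x,
                ce_cells = ids[ce_idx],
                divisions = div_truth,
                region = L, spec = spec)
  rownames(truth$positions) <- NULL
  list(tracks = ts, truth = truth)
}

# Plant CE movers only where the intercalation-like contraction is
# identifiable: each mover converges toward the x centroid of its own
# frozen 3-nearest-neighbour polygon, and a candidate is accepted only if,
# on the noise-free trajectories, every full-track cell's final-frame
# polygon label stays consistent with the planted labels (mover polygons
# lose at least ce_margin of width while still extending in height; all
# other polygons keep a non-negative width change). Only the neighbour
# graph comes from the observed frame-0 geometry.
plant_ce <- function(spec, full, frame0, X, Y, hours) {
  n_target <- round(spec$frac_ce * length(full))
  if (n_target == 0) return(list(idx = integer(0), target = numeric(0)))
  nn <- nn3_neighbours(frame0[full, , drop = FALSE])
  poly <- cbind(seq_along(full), nn)          # indices into `full`
  nf <- length(hours)
  npoly <- nrow(poly)
  shrink <- pmin(0.95, spec$ce_shrink * hours)
  Xb <- X[full, , drop = FALSE]
  w0 <- poly_extent(Xb[, 1], poly)
  centroid <- rowMeans(matrix(Xb[, 1][poly], npoly, 4))
  dh_base <- poly_extent(Y[full, nf], poly) - poly_extent(Y[full, 1], poly)
  # a planted CE mover must also visibly extend in y, so its polygon has to
  # span at least one growing inter-layer gap
  eligible <- dh_base >= 0.5

  # width change of one polygon over all frames under a mover set
  dw_series <- function(r, acc) {
    m <- Xb[poly[r, ], , drop = FALSE]
    movers <- acc[poly[r, ]]
    if (any(movers)) {
      tgt <- centroid[poly[r, ][movers]]
      m[movers, ] <- tgt + (m[movers, , drop = FALSE] - tgt) *
        matrix(1 - shrink, sum(movers), nf, byrow = TRUE)
    }
    apply(m, 2, max) - apply(m, 2, min) - w0[r]
  }
  polys_touching <- function(cells)
    which(rowSums(matrix(poly %in% cells, npoly, 4)) > 0)
  # planted labels must be recoverable from both the final and the
  # time-averaged width change of every polygon (no transient narrowing of
  # non-mover polygons while a mover settles)
  consistent <- function(acc, rows) {
    for (r in rows) {
      dw <- dw_series(r, acc)
      dw_final <- dw[nf]
      dw_mean <- mean(dw[-1])
      if (acc[r]) {
        if (dw_final > -spec$ce_margin || dw_mean > -spec$ce_margin * 0.8)
          return(r)
      } else if (dw_final < 0 || dw_mean < 0) return(r)
    }
    0L
  }
  # Greedy planting with cascades: intercalation is regional, so when a
  # seed mover's convergence narrows a neighbour's polygon, that neighbour
  # is converted into a mover as well (its narrowing is then a planted
  # signal, not a disturbance); the cluster is kept only if it settles into
  # a fully label-consistent state within the target count.
  accepted <- logical(length(full))
  for (seed_cand in sample(seq_along(full))) {
    if (sum(accepted) >= n_target) break
    if (accepted[seed_cand] || !eligible[seed_cand]) next
    trial <- accepted
    trial[seed_cand] <- TRUE
    ok <- FALSE
    for (step in seq_len(length(full))) {
      bad <- consistent(trial, polys_touching(which(trial)))
      if (bad == 0L) {
        ok <- TRUE
        break
      }
      if (trial[bad] || !eligible[bad] || sum(trial) >= n_target) break
      trial[bad] <- TRUE                      # convert the disturbed cell
    }
    if (ok) accepted <- trial
  }
  if (!any(accepted))
    pg_error("plategrowth_bad_spec",
             "no identifiable CE movers could be planted in this geometry")
  # planting is best-effort: identifiability caps the achievable fraction,
  # and the ground truth records what was actually planted
  list(idx = full[accepted], target = centroid[accepted])
}

# 3 nearest neighbours (3D distance, ties broken by row order) for each row
nn3_neighbours <- function(xyz) {
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  t(apply(d, 1, function(r) order(r)[1:3]))
}

# axis-aligned extent (max - min) of each 4-cell polygon
poly_extent <- function(coord, poly) {
  m <- matrix(coord[poly], nrow(poly), 4)
  do.call(pmax, as.data.frame(m)) - do.call(pmin, as.data.frame(m))
}

#' Per-frame cell radius schedule implied by a tissue specification
#'
#' Cell extent (diameter) grows linearly at the spec's cell rates, so the
#' semi-axes grow at half those rates; the z semi-axis stays at the initial
#' radius (no growth is modelled along the imaging axis).
#'
#' @param spec a [tissue_spec()].
#' @param n_frames number of frames (default from the spec).
#' @return data.frame with columns `frame`, `rx`, `ry`, `rz` (um).
#' @export
radius_schedule <- function(spec, n_frames = spec$n_frames) {
  stopifnot(inherits(spec, "tissue_spec"))
  h <- 0:(n_frames - 1)
  data.frame(frame = h,
             rx = spec$cell_radius0 + spec$rate_cell_x * h / 2,
             ry = spec$cell_radius0 + spec$rate_cell_y * h / 2,
             rz = spec$cell_radius0)
}
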