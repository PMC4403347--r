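# End-to-end orchestration. A run config (list or YAML file) names a
# subcommand and its inputs/outputs; every JSON artifact embeds the config
# digest and seed so reruns are attributable. Angles are degrees, lengths um,
# times hours at every interface.

#' Run a pipeline subcommand from a config
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{generate a synthetic tissue (`tissue` holds
#'     [tissue_spec()] arguments); writes the track table (`out_tracks`), a
#'     ground-truth label sidecar (`out_truth`) and optionally a rendered
#'     TIFF stack (`render: yes`, `out_stack`).}
#'   \item{analyze-tracks}{read `tracks` and write a JSON fit report
#'     (`out`): displacement-vs-initial-y fits per axis, distance drift,
#'     polygon classification and division statistics.}
#'   \item{analyze-voxels}{read `tracks` and a stack (`stack`, written by
#'     [write_stack()]), run the voxel pipeline and write the per-frame
#'     summary CSV (`out_summary`) plus a rates JSON (`out_rates`).}
#'   \item{predict}{read frame-0 positions from `tracks` and rates from a
#'     `rates` JSON, predict `n_frames` frames to `out_pred`; when
#'     `observed` is given, also write an error report (`out_error`).}
#'   \item{report}{single JSON summary of a track table mirroring the main
#'     quantitative read-outs.}
#' }
#'
#' @param config named list, or path to a YAML file with the same keys;
#'   must contain `command`.
#' @return the primary result of the subcommand, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (is.null(config$command))
    pg_error("plategrowth_bad_config", "config lacks a 'command'")
  cmd <- config$command
  known <- c("simulate", "analyze-tracks", "analyze-voxels", "predict",
             "report")
  if (!cmd %in% known)
    pg_error("plategrowth_bad_config",
             "unknown subcommand '%s' (known: %s)", cmd,
             paste(known, collapse = ", "))
  switch(cmd,
         "simulate" = cmd_simulate(config),
         "analyze-tracks" = cmd_analyze_tracks(config),
         "analyze-voxels" = cmd_analyze_voxels(config),
         "predict" = cmd_predict(config),
         "report" = cmd_report(config))
}

config_meta <- function(config) {
  cfg <- config[order(names(config))]
  list(config_digest = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))),
       seed = if (is.null(config$seed)) NA else config$seed,
       package_version = as.character(utils::packageVersion("plategrowth")))
}

write_json_artifact <- function(x, path, config) {
  x$meta <- config_meta(config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

cmd_simulate <- function(config) {
  args <- config$tissue
  if (!is.null(config$seed)) args$seed <- config$seed
  if (!is.null(args$divisions)) args$divisions <- as.data.frame(args$divisions)
  if (!is.null(args$region)) args$region <- as.numeric(args$region)
  spec <- do.call(tissue_spec, args)
  sim <- generate_tissue(spec)
  if (!is.null(config$out_tracks)) write_tracks(sim$tracks, config$out_tracks)
  if (!is.null(config$out_truth)) {
    lab <- data.frame(cell_id = names(sim$truth$labels),
                      label = unname(sim$truth$labels))
    utils::write.csv(lab, config$out_truth, row.names = FALSE)
  }
  if (isTRUE(config$render) && !is.null(config$out_stack)) {
    stack <- render_images(sim$tracks, radius_schedule(spec),
                           voxel_um = config$voxel_um %||% 1,
                           region = spec$region)
    write_stack(stack, config$out_stack)
  }
  invisible(sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cmd_analyze_tracks <- function(config) {
  ts <- read_tracks(config$tracks)
  full <- full_track_subset(ts)
  fits <- lapply(c("x", "y", "z"), function(a) {
    f <- fit_displacement_vs_initial(full, a)
    list(axis = a, slope = f$slope, intercept = f$intercept,
         r_squared = f$r_squared, n = f$n)
  })
  cls <- classify_motion(full, mode = config$ce_mode %||% "final")
  drift_y <- distribution_drift(full, "y")
  drift_x <- distribution_drift(full, "x")
  div <- division_summary(ts, config$rearrange_threshold %||% 30)
  out <- list(fits = fits, motion_fractions = as.list(cls$fractions),
              mean_distance_y_t0 = drift_y$grand_mean[1],
              mean_distance_y_final = drift_y$grand_mean[nrow(drift_y)],
              mean_distance_x_t0 = drift_x$grand_mean[1],
              mean_distance_x_final = drift_x$grand_mean[nrow(drift_x)],
              divisions = div)
  if (!is.null(config$out)) write_json_artifact(out, config$out, config)
  invisible(out)
}

full_track_subset <- function(ts) {
  len <- table(ts$points$cell_id)
  subset_tracks(ts, names(len)[len == n_frames(ts)])
}

division_summary <- function(ts, threshold_deg = 30) {
  if (nrow(ts$lineage) == 0)
    return(list(n_events = 0, mitotic_rate_percent = mitotic_rate(ts)))
  ev <- division_events(ts)
  rc <- call_rearrangements(ev, threshold_deg)
  list(n_events = length(ev),
       mitotic_rate_percent = mitotic_rate(ts),
       fraction_rearranged = rc$fraction,
       max_theta_at_division = max(rc$calls$theta_division, na.rm = TRUE),
       max_theta_final = max(rc$calls$theta_final, na.rm = TRUE))
}

cmd_analyze_voxels <- function(config) {
  ts <- read_tracks(config$tracks)
  stack <- read_stack(config$stack, voxel_um = config$voxel_um %||% 1)
  anchors <- config$anchors %||% pick_anchors(ts)
  vs <- analyze_stack(stack, ts, anchors = unlist(anchors),
                      mode = config$patch_mode %||% "midplane",
                      n_thresholds = config$n_thresholds %||% 10)
  if (!is.null(config$out_summary))
    utils::write.csv(as.data.frame(vs), config$out_summary, row.names = FALSE)
  rates <- estimate_rates(vs, count_gaps_y(ts, unlist(anchors)))
  if (!is.null(config$out_rates))
    write_json_artifact(list(d_cell_y = rates$d_cell_y,
                             d_ecm_y = rates$d_ecm_y,
                             gap_increment = rates$gap_increment),
                        config$out_rates, config)
  invisible(list(summary = vs, rates = rates))
}

cmd_predict <- function(config) {
  ts <- read_tracks(config$tracks)
  rj <- jsonlite::read_json(config$rates, simplifyVector = TRUE)
  gm <- growth_model(growth_rates(rj$d_cell_y, rj$d_ecm_y))
  nf <- config$n_frames %||% n_frames(ts)
  pred <- stats::predict(gm, ts, n_frames = nf)
  if (!is.null(config$out_pred)) {
    long <- data.frame(cell_id = rep(rownames(pred$y), times = ncol(pred$y)),
                       frame = rep(0:(ncol(pred$y) - 1), each = nrow(pred$y)),
                       y_pred = as.vector(pred$y))
    utils::write.csv(long, config$out_pred, row.names = FALSE)
  }
  res <- list(pred = pred)
  if (!is.null(config$observed)) {
    obs <- read_tracks(config$observed)
    te <- trajectory_error(pred, obs, floor_um = config$error_floor %||% 5)
    res$error <- te
    if (!is.null(config$out_error))
      write_json_artifact(list(max_percent = te$max_percent,
                               mean_percent = te$mean_percent,
                               n_masked = te$n_masked),
                          config$out_error, config)
  }
  invisible(res)
}

cmd_report <- function(config) {
  out <- cmd_analyze_tracks(config)
  invisible(out)
}
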