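# Small fixtures built in code.

# minimal hand-built track set: cells on given y positions, optionally moving
simple_ts <- function(y0, n_frames = 3, vy = 0, x0 = 0, z0 = 0) {
  n <- length(y0)
  pts <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(cell_id = sprintf("s%02d", i), frame = 0:(n_frames - 1),
               x = rep_len(x0, n)[i],
               y = y0[i] + rep_len(vy, n)[i] * (0:(n_frames - 1)),
               z = rep_len(z0, n)[i])
  }))
  track_set(pts)
}

# noise-free uniform-growth tissue at unit-test scale
small_growth_spec <- function(n_cells = 48, n_frames = 12, seed = 11, ...) {
  args <- list(n_cells = n_cells, region = c(60, 140, 60),
               n_frames = n_frames, jitter_sd = 0, lattice_sd = 0,
               seed = seed)
  do.call(tissue_spec, utils::modifyList(args, list(...)))
}
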