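# plategrowth

Quantitative dissection of growth-plate cartilage elongation from 4D
(x, y, z, t) cell tracks and voxel image stacks.

During embryonic long-bone growth, the chondrocytes of the proliferative zone
(PZ) spread apart almost exclusively along the proximo-distal axis (PDA, the
`y` axis in the tissue frame used throughout this package). Several cellular
processes could drive that spreading: convergent extension (CE, cell
intercalation narrowing the tissue while lengthening it), oriented mitotic
division, post-division daughter-cell rearrangement, deposition of
extracellular matrix (ECM) into the intercellular gaps, and cell volume
enlargement. `plategrowth` implements the analysis toolkit needed to separate
these contributions from time-lapse cell-tracking data, plus the predictive
model that ties the measured ECM and cell growth rates back to the observed
trajectories. It is aimed at quantitative developmental biologists working
with 4D microscopy of cartilage (or any tissue with near-unidirectional
growth).

## What it computes

* **Trajectory decomposition** (`displacements`, `speeds`,
  `fit_displacement_vs_initial`): per-axis displacement and speed series, and
  the ordinary least-squares fit of total y displacement against initial y
  position. Under additive uniform growth, displacement is linear in initial
  position — each cell is pushed by the growth of every cell and gap proximal
  to it — so the fit's R² measures how additive the spreading is.
* **Cell–cell distance distributions** (`mean_distances`,
  `distribution_drift`): per-cell mean centre-to-centre distance to all other
  cells, per frame, in 3D or projected per axis; the drift of the grand mean
  traces anisotropic spreading.
* **Polygon CE test** (`build_polygons`, `classify_motion`): each cell and
  its three nearest neighbours (frozen at frame 0) form a quadrilateral whose
  height *h* (y extent) and width *w* (x extent) are followed over time.
  Δh > 0 with Δw < 0 is the CE signature; both increasing is
  extension–extension.
* **Division statistics** (`daughter_geometry`, `orientation_histogram`,
  `call_rearrangements`, `mitotic_rate`): the distance *r* and unsigned angle
  Θ between daughter centres relative to the xz plane (Θ = 0: division
  orthogonal to the PDA; Θ = 90°: along it), a polar histogram of Θ, and
  rearrangement calls when Θ increases by more than a threshold (default
  30°) after division.
* **Voxel volumetry** (`analyze_stack`, `binarize`, `decompose_axes`,
  `volume_trends`): a crop box anchored on four reference cells grows with
  the tissue; each frame is binarized at 10 thresholds around its mean
  intensity (bright = cell, dark = ECM), and per-patch bounding boxes
  separate mean cell extent from ECM span along x and y.
* **Additive growth model** (`growth_model`, `estimate_rates`, `predict`,
  `trajectory_error`): with no free parameters, every nearest-neighbour
  centre-to-centre gap along y grows per hour by
  `d_ecm_y + d_cell_y` (ECM-span increment plus both cells' radius
  increments), and positions are rebuilt cumulatively from the proximal
  anchor: `y_i(k) = y_i(0) + rank_i · k · g`.
* **Synthetic tissue generator** (`tissue_spec`, `generate_tissue`,
  `render_images`): seeded growing tissues with known ground truth — planted
  CE movers, oriented divisions, daughter rearrangements, jitter — and
  matching rendered image stacks, so every stage above is testable against
  a ground truth.

## Worked example

Generate a noise-free PZ block (the scale of a measured voxel subregion,
~110 cells over 55 h), render it, estimate growth rates from the images
alone, and predict the trajectories:

```r
library(plategrowth)

spec <- tissue_spec(n_cells = 109, region = c(60, 105, 60), n_frames = 56,
                    jitter_sd = 0, lattice_sd = 0, seed = 1)
sim <- generate_tissue(spec)
sim$tracks
#> <track_set> 112 cells, 56 frames (1 h/frame), 0 division link(s)
#>   extent (um): x [4.8, 55.2], y [7.5, 113.3], z [7.5, 52.5]

fit_displacement_vs_initial(sim$tracks, axis = "y")
#> <additive_fit> dy(frame 55) ~ initial y, n = 112
#>   slope 0.176 um/um, intercept -1.32 um, R^2 = 1.0000

set.seed(2)
stack <- render_images(sim$tracks, radius_schedule(spec), voxel_um = 1,
                       region = spec$region)
anchors <- pick_anchors(sim$tracks)
vs <- analyze_stack(stack, sim$tracks, anchors, mode = "3d")
rates <- estimate_rates(vs, count_gaps_y(sim$tracks, anchors))
rates
#> <growth_rates> cell y 0.02475 um/h, ECM y 0.02325 um/h (gap increment 0.048 um/h)

pred <- predict(growth_model(rates), sim$tracks, n_frames = 56)
trajectory_error(pred, sim$tracks)
#> <trajectory_error> max 6.02e-13%, mean 1.2e-13% (0 entries masked near y = 0)

classify_motion(sim$tracks)$fractions
#> CE EE CC EC
#>  0  1  0  0

percent_elongation(85, 220)
#> [1] 39
```

Reading the numbers: the fit's R² of 1.0 is the additive-growth signature
(displacement exactly linear in initial y). The voxel pipeline recovers the
planted rates (cell extent 0.026, ECM span 0.022 µm/h) to within ~5% from the
images alone, and the per-gap increment (their sum, 0.048 µm/h) exactly;
feeding those rates into the parameter-free model reproduces every
trajectory to machine precision, i.e. far below the few-percent error one
should demand of a self-consistent pipeline. A uniformly growing tissue is
classified 100% extension–extension — no spurious CE. The last line is the
elongation bookkeeping helper: an 85 µm displacement difference across an
initially 220 µm region is a 39% elongation.

A thin command-line wrapper over the same pipeline lives at
`inst/cli/plategrowth.R`
(`Rscript inst/cli/plategrowth.R simulate --config cfg.yaml`).

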