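---
title: "Methods: the additive growth model and its validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the additive growth model and its validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design decisions behind
`plategrowth`: what each analysis assumes, which parameters matter and why
their defaults are what they are, what the synthetic-tissue generator does
and does not emulate, and the numerical corner cases. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## Coordinate frame and units

All analyses use a tissue-aligned Cartesian frame: `y` is the proximo-distal
axis (PDA, +y distal), `x` the in-plane transverse axis, `z` the imaging
axis. Lengths are micrometres, times hours, angles degrees, and frames are
0-based integers separated by `frame_interval` hours (default 1). `recentre()`
shifts the y origin to the midpoint of the frame-0 y range ("middle of the
tissue"); it is idempotent and distance-preserving. Inside the division
analysis only, time is re-indexed so that t = 1 is the division frame.

## The additive growth model

The model asserts that PZ cell spreading along the PDA is driven entirely by
two measurable quantities: the rate of change of mean cell extent (diameter)
along y, `d_cell_y`, and the rate of change of mean ECM span per
intercellular gap along y, `d_ecm_y`, both in µm/h. For a nearest-neighbour
pair, the centre-to-centre distance gains, per hour,

    ΔD = Δecm + Δr_A + Δr_B = d_ecm_y + d_cell_y

(the two radius increments of a pair sum to one extent increment). Cells are
grouped into y levels (positions within `level_tol` share a level and move
together); at every time step each inter-level gap grows by the increment
and positions are rebuilt cumulatively from the anchor — by default the most
proximal cell, configurably the y origin. The model has **no free
parameters**: its only inputs are measured rates and frame-0 positions.
Because the update is linear, the iteration equals the closed form
`y_i(k) = y_i(0) + rank_i · k · g` (verified to machine tolerance in the
tests), sub-stepping would change nothing, and non-negative increments can
never reorder cells along y.

Two consequences give the model its observable signatures:

* total displacement is proportional to the number of gaps proximal to a
  cell, hence linear in initial y (R² = 1 on noise-free synthetic tissue);
* the relative speed of nearest-neighbour pairs is the same everywhere along
  the PDA.

`estimate_rates()` converts voxel-pipeline slopes to the model's inputs. The
measured "ECM span" of a frame is the crop-box dimension minus the mean cell
extent, so the sum of the cell-extent slope and the ECM-span slope equals
the box growth rate; dividing by the number of inter-level gaps spanned by
the box (`count_gaps_y()`) gives the per-gap increment, and the cell-extent
slope — already a per-cell quantity — splits it into `d_cell_y` and
`d_ecm_y`. This decomposition makes the *sum* (the gap increment, which is
all the trajectory model uses) immune to segmentation bias: any bias in the
cell/ECM split cancels because the box dimensions come from tracked anchor
cells, not from binarization.

`trajectory_error()` reports `100·|y_pred − y_obs|/|y_obs|` per cell and
frame. The percent error diverges near y = 0, so entries with
`|y_obs| < floor_um` (default 5 µm) are masked and excluded from the
maximum.

## Voxel volumetry

The crop box passes through the centres of four anchor cells (chosen at the
corners of the frame-0 population by `pick_anchors()`) and therefore expands
with the tissue; z spans the full stack depth. Each cropped frame is
binarized at `n_thresholds = 10` thresholds spaced `0.1·sd` apart around the
frame-mean intensity (mean − 0.5·sd … mean + 0.4·sd); a voxel at or above a
threshold counts as cell, below as ECM, and counts are averaged over the
threshold set (averaging, not voting, was an open choice; averaging keeps
the result continuous in the image). Thresholds are clamped to lie strictly
inside the frame's intensity range, since a threshold at or below the
minimum classifies every voxel identically and carries no information. A
constant image is an error. Bright + dark always equals the box volume, at
every threshold.

Patch analysis labels connected bright components and averages their
bounding-box dimensions along x and y (the mean cell extent); ECM span is
the box dimension minus the mean extent. Two modes exist:

* `midplane` (default): components of the mid-depth 2D slice, matching
  frame-by-frame 2D segmentation of image stacks;
* `3d`: full 3D components. The 2D slice of a sphere is a chord, not a
  diameter — slices systematically shorten extents and, worse, inflate
  extent *slopes* (a chord grows faster than its diameter) — so rate
  estimation in the validation pipeline uses `3d`.

Patches touching the crop boundary are excluded from the extent statistics
(their boxes are truncated by the crop — the anchors themselves sit on the
boundary), as are patches below `min_patch = 4` voxels (noise speckle).
2D labelling uses `EBImage::bwlabel`; 3D labelling builds the 6-neighbour
voxel adjacency graph and takes `igraph` components, since no installed
package labels 3D arrays directly.

## Polygon test for convergent extension

Every cell tracked over the full frame range gets a polygon: itself plus its
three nearest neighbours by 3D distance at frame 0, ties broken by cell-id
order. Membership is frozen — the series then measures relative motion, not
neighbour exchange. Height `h` is the y extent and width `w` the x extent of
the 4-point set (axis-aligned extents, not area or perimeter). The CE
signature is Δh ≥ 0 with Δw < 0; both non-negative is EE; the boundary
convention (Δ = 0 counts as extension) is explicit and a zero-growth tissue
is therefore 100% EE.

`classify_motion()` offers three statistics: the final-frame change
(default), the time-averaged change, and the least-squares trend (slope ×
span). The trend exists because both other statistics subtract the single
frame-0 measurement, whose positional noise becomes a persistent offset of
the whole series. A configurable dead band `epsilon` (default 0, the strict
sign rule) absorbs residual noise: polygons whose members share an x column
have *no* width signal, and under jitter any strict sign rule labels half of
them convergent by chance. For jittered data a dead band of about three
times the propagated noise of the chosen statistic is appropriate; for the
trend statistic over T frames of jitter with standard deviation σ the
propagated noise is of order `σ·sqrt(12/T)` (about 0.2 µm at σ = 0.5 µm and
T = 56), and the shipped validation uses `epsilon = 0.6` µm, three times
that.

## Division and rearrangement analysis

For each lineage link, `daughter_geometry()` computes `r(t)` (Euclidean
distance between daughter centres) and `Θ(t) = asin(|Δy|/r)` in degrees,
folded into [0, 90]: Θ is invariant to which daughter is the origin and to
any rotation within the xz plane. Coincident daughters (r = 0) have
undefined angle and are flagged rather than dropped. A pair is called
rearranged when Θ at the final frame exceeds Θ at division by more than
`threshold_deg` (default 30°, exposed in the API); the mitotic rate is
divisions per frame-0 cell, as a percent.

## The synthetic-tissue generator

`generate_tissue()` produces the study conditions every analysis is
validated against: a (perturbed) rectangular lattice filling a
`90 × 220 × 90` µm PZ region by default, imaged "hourly" for 56 frames.

**Geometry defaults.** Cells have initial radius 6 µm with 3 µm ECM gaps
between surfaces, i.e. a 15 µm packing pitch — a close-packed field in which
cells occupy roughly a quarter of the volume and the rendered images are
substantially bright. This matters: the mean-centred multi-threshold
binarization presumes a bright, cell-filled field (as in cytoplasmic
fluorescence imaging of the PZ); on a sparse field the lower thresholds fall
to the intensity floor and the scheme degenerates. The requested `n_cells`
is met by thinning the close-packed lattice uniformly (the search balances
count accuracy against the packing aspect ratio); requesting more cells than
the close-packed capacity is a packing error.

**Growth.** Each inter-layer y gap grows by `rate_ecm_y + rate_cell_y` per
hour — the generator implements the additive model exactly, anchored at the
proximal face; x gaps grow analogously about the tissue mid-line, z is
static. Defaults (`rate_cell_y = 0.026`, `rate_cell_x = 0.022`,
`rate_ecm_y = 0.022`, `rate_ecm_x = 0.011` µm/h) correspond, at the default
geometry and 55 h, to relative increases of about +12%/+10% in cell extent
and +40%/+20% in ECM span along y/x — anisotropic expansion dominated by
ECM deposition along the PDA. Growth is additive (linear in time), not
multiplicative, because the model takes constant measured slopes as its
inputs. An early proximal-ward phase seen in some preparations is not
emulated by default (the core model is monotone growth); signed rates can
produce it.

**Noise.** Two independent knobs: `lattice_sd` statically perturbs lattice
sites and `jitter_sd` adds per-frame isotropic Gaussian noise (both default
0.5 µm; segmentation centroid noise of roughly half a voxel). With both at
zero and no planted behaviours, trajectories satisfy the additive law
exactly.

**Planted divisions** split a parent (its track ends) into two daughters
2·r₀ apart along a direction at the planted angle Θ to the xz plane at the
given frame; rearranging pairs rotate their joining vector toward the y axis
(to 80° over 15 frames by default), others keep Θ constant.

**Planted CE movers** converge in x while extending in y. A mover's x
relaxes toward the x centroid of its own frozen 3-NN polygon (intercalation
narrows the local neighbourhood; converging on the tissue mid-line would
carry a cell *away* from its neighbours and widen its polygon), ramping to a
95% approach at `ce_shrink = 0.1`/h so the motion settles within ~10 h.
Because a mover that is the inward x extreme of a neighbour's polygon would
also narrow that polygon, planting is constrained: movers are accepted
greedily only if, on the noise-free trajectories, every polygon's final and
time-averaged width change remains consistent with the planted labels
(mover polygons narrow by at least `ce_margin`; all others never narrow),
and a disturbed neighbour is converted into a mover itself — intercalation
is regional, so clusters are the natural planted unit. Planting is
best-effort: the identifiable fraction is capped by geometry, and the ground
truth records what was actually planted. With `frac_ce = 1` the whole
population converges on the mid-line instead (global contraction is
self-consistent).

**What the generator does not emulate**: mechanical force balance, cell
cycle kinetics, neighbour exchange/T1 transitions, photobleaching, a
realistic point-spread function, or anisotropic voxel sizes. Passing tests
therefore demonstrate correctness of the *measurement and inference
machinery* under the stated model, not that real tissue obeys the model.

**Rendering.** `render_images()` rasterises each cell as a bright ellipsoid
(semi-axes from the radius schedule, so anisotropic extent growth is
visible in the images) on a dark background with additive Gaussian
intensity noise (default sd 0.005, a high-SNR fluorescence regime), at an
isotropic default voxel of 1 µm (the optical sectioning interval of typical
two-photon stacks). Determinism: everything is driven by the spec's single
seed; the same seed reproduces the tissue byte-for-byte.

## Validation problem sizes

The shipped end-to-end validation generates ~112 cells in a
`60 × 105 × 60` µm block — the scale of a measured voxel subregion of the
upper PZ — for 56 hourly frames, renders ~380k voxels per frame, estimates
rates in `3d` patch mode, and predicts all trajectories. CE-recovery runs
use 200 cells in the full default region; rearrangement recovery plants 20
divisions with 10% rearranging. These sizes keep the full suite around a
minute or two of compute while leaving parameter-recovery statistics
(dozens of interior cells averaged over 56 frames) well-determined.

## Degenerate inputs and numerical choices

* Track tables: duplicated (cell, frame) rows, frame gaps within a track,
  non-numeric or non-finite coordinates, and lineage links violating the
  parent-ends/daughters-begin contract are classed validation errors naming
  the offence.
* Fits require ≥ 3 cells present at both endpoint frames and non-degenerate
  initial-y variance.
* Distance distributions require ≥ 2 cells at the frame; cells absent at a
  frame are excluded pairwise, never imputed.
* Polygon building requires ≥ 4 full-length tracks; neighbour ties break by
  cell-id order, deterministically.
* `binarize` rejects constant images; `decompose_axes` rejects an empty
  bright mask.
* Prediction requires ≥ 2 cells and finite rates; `level_tol` (default
  1e-6 µm) controls which cells share a y level.
* Angles are computed with `asin` clamped at 1 to guard rounding; Θ is NA
  (flagged) when daughters coincide.

## Known limitations

* The y-only model ignores transverse (x/z) prediction by design.
* Width-degenerate polygons are unclassifiable from width alone; the dead
  band makes this explicit rather than letting noise decide.
* The per-axis distance statistic uses absolute coordinate differences
  (projections), not direction-binned 3D distances.
* The ECM/cell split of the voxel pipeline inherits rasterisation bias at
  coarse voxels; only their sum is bias-cancelled. Rate-recovery accuracy
  therefore depends on voxel size and cell drift (which dithers the
  quantisation); the shipped validation quantifies it at 1 µm voxels.
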