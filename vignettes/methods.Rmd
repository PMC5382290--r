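---
title: "Quantifying collective cell migration in 4D: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collective cell migration in 4D: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmigrate)
```

`ccmigrate` quantifies the behaviour of every nucleus and cell in a small,
closely packed cluster of collectively migrating cells imaged as a 4D
(3D + time) two-channel fluorescence movie. The motivating system is the
*Drosophila* border-cell cluster: two non-motile central polar cells
surrounded by six to ten motile border cells, crawling between large nurse
cells. This vignette explains each stage of the pipeline, the assumptions
behind it, the tunable parameters and the numerical choices made where the
design was genuinely open.

## Coordinate conventions

All arrays are ordered `(z, y, x)` with 0-based voxel indices; physical
positions in micrometres are `index * voxel size`. After resampling, all
geometry lives on an isotropic grid (0.33 um by default), which removes any
anisotropy bookkeeping from the downstream stages.

## Pre-processing

Confocal stacks arrive with a coarser z step than their x-y resolution, low
signal-to-noise, and progressive photobleaching.

* **Isotropic resampling** (`resample_isotropic`): per-frame trilinear
  interpolation onto the target grid, preserving the physical extent within
  one voxel.
* **Photobleaching correction** (`correct_photobleaching`): assuming the
  specimen holds a constant amount of fluorophore, each frame is rescaled so
  its total intensity matches frame one. Totals are computed over the whole
  frame because no foreground mask exists yet at this stage; the amplified
  late-frame noise this can cause is mitigated by the subsequent smoothing.
  The correction is idempotent - a second application yields unit gains.
* **Denoising** (`denoise_background`): Gaussian smoothing (default sigma
  0.5 um - the scale of the finest structures worth keeping, chosen here
  because no reference value is published) followed by grey-scale top-hat
  background removal. The top-hat uses a cubic window (half-width 10 um,
  about one cell diameter) realized with separable running min/max filters;
  a true rolling ball offers no practical advantage at this scale.

## Nucleus segmentation: a brightness-weighted Gaussian mixture

The number of nuclei `c` is fixed and known from the one manual input of the
whole pipeline: a first-frame annotation of the two polar and all border
nucleus centers. Per frame:

1. **Boundary enhancement**: nuclei touch, so the frame is sharpened by
   subtracting `kappa` times its discrete Laplacian (default `kappa = 1`),
   deepening the intensity valleys between adjacent nuclei.
2. **Mass-conserving foreground**: the threshold is chosen so the enclosed
   intensity mass is closest to a target fixed at frame one (from a seeding
   threshold at half the mean intensity of the annotated centers). Holding
   the mass fixed stops the segmented nuclear volume from drifting with
   residual bleaching.
3. **Weighted EM**: a `c`-component spatial Gaussian mixture is fitted over
   the masked voxel coordinates with per-voxel weights proportional to
   `brightness^alpha` (default `alpha = 1`). A formulation that instead
   appends brightness as a fourth feature dimension would mix incommensurate
   units; the weight interpretation reproduces the intensity-weighted
   geometric center of each nucleus exactly, which is the quantity tracked
   downstream. After every M-step a ridge `lambda_reg` (default 1e-3 um^2)
   is added to each covariance diagonal - without it the likelihood is
   unbounded (a component can collapse onto one voxel). EM stops at a
   relative log-likelihood change of 1e-6 or 200 iterations.
4. **Labelling**: each masked voxel takes its maximum-posterior component;
   exact ties go to the lower label so the partition is deterministic.

Frame `t` is initialized from frame `t - 1`'s fit (frame one from the
annotation with isotropic 2 um covariances), which implements the temporal
coherence the movie physically has and keeps component identities stable.

## Tracking by global assignment

Between consecutive frames the segments are associated by maximizing the
summed tracking confidence

\[ S_{ij} = \frac{|\Omega_i(t) \cap \Omega_j(t+1)| + 1}
                 {\lVert c_i(t) - c_j(t+1) \rVert + \varepsilon}, \]

overlap in voxels, distance in um, `epsilon` one voxel (0.33 um) by
default. The `+1` keeps fully disjoint pairs rankable by distance - without
it a nucleus that jumps its own diameter in one interval (bursts near
10 um/min occur) would present an all-zero row and the assignment would be
arbitrary. The maximization is solved exactly as a min-cost assignment by
shortest augmenting paths; among tied optima the lexicographically smallest
permutation is returned so reruns are bit-identical. The solver is checked
against brute-force permutation enumeration in the test suite.

Per-step assignments are chained into stable labels, from which per-entity
displacement vectors, speeds and unit directions follow.

## Cell segmentation under a volume constraint

Cells neither gain nor lose mass over the movie, so the cluster volume is
constrained to a constant set at frame one: `c_border * V_border + 2 *
V_polar`, with reference volumes 1250 um^3 (border; the midpoint of the
published 1000-1500 um^3 range) and 600 um^3 (polar; never published -
calibrate per dataset). Voxels of the smoothed membrane
channel - whose shell traces the cluster surface - are accumulated in
descending intensity until the target volume is reached. Descending all the
way to the target count matters: the coarse axial sampling attenuates the
membrane at the cluster's z-caps, and a less greedy threshold would leave
the shell open there, with deep polar dents in the mask. The largest
connected component is kept, the interior recovered by hole filling (which
overshoots the target, since the shell band now encloses its interior), and
if any tracked nucleus would fall outside, the threshold descends further
until every seed is enclosed. The overshoot is then peeled back to exactly
the target volume along the level sets of the Gaussian-smoothed mask
indicator (scale 1 um) - one step of discrete curvature flow that
simultaneously removes the voxel-scale surface roughness which would
otherwise register as spurious opening residue in the protrusion stage. A
final deviation of more than 10% from the target volume is logged as a
warning.

The weak membrane signal is enhanced with an oriented second-derivative
"plate" filter bank: kernels of scale `sigma_k = 0.66` um rotated every 30
degrees within the x-y, x-z and y-z planes (18 orientations), taking the
maximum response. Because the response of a plate kernel with unit normal
`n` equals `-n' H n` with `H` the Gaussian-scale Hessian, the bank is
evaluated through six separable Hessian convolutions plus cheap per-voxel
quadratic forms - mathematically identical to convolving 18 rotated kernels
and an order of magnitude faster.

Cell bodies are then recovered by a marker-controlled watershed: a priority
flood of the enhanced image restricted to the cluster mask, seeded by the
tracked nuclei. Equal-priority voxels go to the front that queued them
first - a basin therefore keeps its own ridge flank even when another
front arrives later at the same level (a pure lower-label tie rule lets
whichever basin first crosses the cluster's outer ridge sweep the exterior
and then win every crest contest) - with the lower label as the final,
rarely reached tie-break. The result is deterministic, partitions the mask
exactly, and each cell contains its nucleus. Per-cell volume equality
constraints inside the watershed were deliberately not added - the cluster
volume constraint already anchors the totals.

Cell-cell and cell-substrate contact areas are measured by dilating each
cell with the 3 x 3 x 3 structuring element and counting overlap voxels
with each neighbour (internal interface) and with the complement of the
cluster (external interface), converted via the squared voxel size.

## Coordination: order parameters and migration modes

With `K` tracked unit directions per frame step (entities with zero
displacement are excluded frame by frame, because a direction is undefined
at zero speed - they are not given arbitrary directions),

* **group polarization** `P(t) = |sum d_k| / K` is 1 for perfectly aligned
  translation ("running"),
* **angular momentum** `M(t) = |sum r_k x d_k| / K`, with `r_k` the unit
  vector from the cluster center, is 1 for coherent equatorial rotation
  ("rotating").

A two-class quadratic classifier (one bivariate Gaussian per mode over
`(P, M)`, class-frequency priors, equal-posterior boundary) separates the
modes while exposing the posterior, so the continuum of intermediate frames
remains visible. The published fitted boundary parameters are not available,
so the package ships a default trained on simulated coherent-translation and
coherent-rotation direction sets (`default_mode_classifier()`); refitting on
annotated data is a one-liner and recommended for real movies.

The polar axis - the undirected line through the two polar-cell centers -
is summarized by per-step rotation angles `acos |a_t . a_{t+1}|` and their
centered 5-point moving average.

## Neighbour exchange

A border cell sliding past its neighbours permanently rearranges the
cluster's internal geometry, while rigid translation plus rotation leaves
all pairwise distances unchanged. The temporal topology change metric

\[ g(t, s) = \max_{ij} \left| D(t+s)_{ij} - D(t)_{ij} \right|, \qquad
   D(t)_{ij} = \lVert c_i(t) - c_j(t) \rVert \]

is therefore exactly zero for any rigid movie and produces a hot spot when
an exchange occurs. Events are the connected supra-threshold regions of the
`(t, s)` scale space with the default threshold `tau` of 30 working voxels
(9.9 um, about twice a nucleus diameter). Within a region the peak compares
the last undisturbed frame with the exchange's closest approach at its
temporal midpoint; the event is therefore localized at the near-peak cell
whose comparison ends earliest, and the full duration is reported as twice
the peak step. The synthetic generator's exchange events move the two
implicated centers along smooth arcs that pass at a closest approach of
about one nucleus diameter (`0.12 x` the chord on either side), matching the
observed squeezing of exchanging nuclei; a trans-cluster exchange then
clears `tau` with margin while rigid scenes stay identically at zero.

## Protrusions and surface morphodynamics

**Cluster external protrusions** are the residue of a morphological opening
of the cluster mask with a ball whose radius comes from fitting the mean
border-cell volume to a sphere (`r = (3V/4pi)^(1/3)`, about 6.7 um at
default volumes): anything thinner than the ball - the elongated outward
extensions - survives the subtraction. On a voxel grid the exact Euclidean
opening chips a one-voxel rind off even a perfect ball, so the erosion gets
a half-voxel radius tolerance, restoring the continuum invariant that a
smooth ball has no residue. The remaining body is the "cluster body"; its
mass center defines cluster speed and direction. Per frame the protrusion
volume, rate (volume per minute), direction (body center to protrusion
center) and owner cell (modal cell label inside the residue, the assignment
rule being otherwise unspecified) are reported, along with the alignment
`PA = d_prot . d_cluster` (signed, so opposite protrusions give -1), the
combined-direction statistic CD and the protrusion-mass statistic CS (both
Pearson correlations against cluster speed).

**Surface deformation** between consecutive frames of one cell uses a
bidirectional nearest-surface mapping, realizing the linear small-interval
assumption symmetrically without any mesh correspondence: surface voxels
(6-connected boundary) of the later frame lying outside the earlier cell
are positive samples (extension), those of the earlier frame outside the
later cell are negative samples (retraction), each with the distance and
displacement vector to the nearest surface voxel of the other frame (exact
Euclidean feature transform, computed on the union bounding box, which is
lossless). Summaries per cell: MPD/MND (maximum positive/negative
deformation, um) and PDE/NDE (summed magnitudes). Together with nucleus and
cell speeds these form the six mobility parameters.

**Rotation association**: per frame, `R = sum r_k x v_k` (nuclei
displacement vectors) is the combined cluster rotating vector and `Q = sum
r_k x u_k` (per-cell sums of positive deformation vectors) the combined
protrusion rotating vector; the angle between them and the movie-level
Pearson correlation of their magnitudes quantify how tightly tangential
cell extensions drive cluster rotation.

## The synthetic movie generator

Every stage is validated end to end on `generate_movie()` scenes with exact
ground truth. The default scene matches the reference system: 2 polar + 6
border cells, border volume 1250 um^3 and polar volume 600 um^3 (cluster
ball radius 12.75 um), nucleus blobs of sigma 1.7 um (diameter about 5 um)
on a ring of radius 8.5 um with polar nuclei 2.5 um either side of the
center, 0.33 um isotropic voxels, 1 min frames, three-fold z decimation,
photobleaching at 2% per frame, Poisson shot noise plus additive Gaussian
read noise (sd 3 on peak amplitudes of 120/80). Cell bodies are the Voronoi
partition of the cluster ball seeded by the nuclei - cheap, label-exact and
sufficient for validating watershed and interface code; protrusions are
cylinders unioned onto their owner's label. Motion schedules compose
running (rigid translation), rotating (rigid rotation, optional slow
drift) and chaotic (per-cell isotropic random steps around home positions -
a stand-in, since chaotic-mode statistics are not quantified anywhere)
segments. Ground truth (labels, tracks, event log, per-frame mode) is
recorded before any degradation, so noise settings can never leak into it.

What the generator does **not** emulate: optical point-spread anisotropy
beyond z decimation, deformable cell shapes (rigid Voronoi bodies only),
nurse-cell dynamics, imaging drift. Passing tests therefore demonstrate
the correctness of the algorithms under realistic geometry and noise, not
performance on every real-microscope artefact.

## Problem sizes and determinism

Most unit tests exercise reduced scenes (4-6 border cells of 200-400 um^3
at 0.5 um voxels, 4-10 frames) so the whole suite runs in a few minutes.
Properties that depend on the geometry ratios of the reference system -
interface symmetry, per-cell volume stability, protrusion alignment - are
asserted on short movies at the full default scale (0.33 um voxels), since
a toy cluster whose radius is only twice the opening radius genuinely
behaves differently. The benchmark script (`scripts/acceptance.R`)
regenerates everything at the full default scale (10-20 frames). All
stochastic stages derive per-stage sub-seeds deterministically from one
master seed, so every pipeline run, table and manifest digest is
bit-reproducible.

## Known limitations

* The cell number must be constant: division, entry or loss of cells is a
  count-mismatch error by design.
* The polar-cell reference volume is a configuration value, not a measured
  default.
* Protrusion ownership by modal label is a heuristic; protrusions spanning
  two cells near their interface can flip owner between frames.
* Mode classification ships with a synthetic-trained default boundary;
  quantitative mode frequencies on real data should use a refitted
  classifier.
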