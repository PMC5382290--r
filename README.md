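# ccmigrate

Quantitative 3D analysis of collectively migrating cell clusters from 4D
(3D + time) two-channel fluorescence movies, built around the *Drosophila*
border-cell cluster: a pair of non-motile polar cells surrounded by six to
ten motile border cells crawling between nurse cells. The package segments
and tracks every nucleus and cell, then quantifies how the cells move
together — and how individual cells misbehave — on a cell-by-cell basis.

The pipeline, stage by stage:

1. **Pre-processing** — trilinear resampling to an isotropic grid
   (0.33 µm default), photobleaching correction by total-fluorescence
   normalization, Gaussian denoising and top-hat background removal.
2. **Nucleus segmentation** — a fixed-component 3D Gaussian mixture fitted
   by EM over foreground voxel coordinates with per-voxel weights
   ∝ brightness^α, initialized from a one-off first-frame annotation and
   thereafter from the previous frame. The fitted means are the
   intensity-weighted nucleus centers.
3. **Tracking** — frame-to-frame association maximizing the summed
   confidence `S_ij = (|Ω_i ∩ Ω_j| + 1) / (‖c_i − c_j‖ + ε)` (overlap plus
   inverse distance), solved exactly with a Hungarian-type assignment
   solver.
4. **Cell segmentation** — a cluster mask obtained by greedy thresholding
   under a constant total-volume constraint, membrane enhancement by an
   oriented second-derivative plate-filter bank (maximum response over 18
   orientations, computed via the Gaussian Hessian), and marker-controlled
   watershed seeded by the tracked nuclei. Cell–cell and cell–substrate
   interface areas come from 3×3×3 dilations.
5. **Coordination** — per-frame group polarization
   `P(t) = |Σ d̂_k| / K` and angular momentum `M(t) = |Σ r̂_k × d̂_k| / K`,
   a two-Gaussian running/rotating mode classifier over (P, M), and
   polar-axis rotation statistics.
6. **Neighbour exchange** — the temporal topology change metric
   `g(t, s) = max_ij |D(t+s)_ij − D(t)_ij|` over pairwise center-distance
   matrices, zero for any rigid motion, thresholded at ~twice the nucleus
   diameter to detect cells sliding past their neighbours.
7. **Protrusions & morphodynamics** — cluster external protrusions as the
   residue of a morphological opening with a sphere fitted to the mean
   border-cell volume; signed cell-surface deformation fields by
   bidirectional nearest-surface mapping with summary statistics
   (MPD/MND/PDE/NDE), protrusion–direction alignment (PA), and the
   association between tangential cell extensions and cluster rotation.

A seeded synthetic-movie generator (`generate_movie()`) renders
ground-truthed clusters — Voronoi cell bodies in a ball, Gaussian nucleus
blobs, membrane shells, bleaching, shot/read noise, anisotropic z sampling,
running/rotating/chaotic schedules, injected neighbour exchanges and
protrusions — so every stage is validated end to end without real data.
See the methods vignette (`vignettes/methods.Rmd`) for models, parameters
and design decisions.

## Worked example

Simulate a small running cluster, run the full pipeline, and look at the
coordination of the tracked nuclei:

```r
library(ccmigrate)

scene <- scene_config(
  n_border = 4, v_border_um3 = 400, v_polar_um3 = 200,
  nucleus_sigma_um = 1.2, border_ring_radius_um = 5, polar_offset_um = 2,
  voxel_um = 0.5, z_subsample_factor = 2,
  motion_schedule = list(list(mode = "running", n_frames = 4,
                              speed = 1, axis = c(0, 0, 1))),
  seed = 7)

cfg <- pipeline_config(target_voxel_um = 0.5, v_border_ref = 340,
                       v_polar_ref = 330, seed = 7)
res <- run_pipeline(cfg, input = "simulate", outdir = "run1", scene = scene)

head(res$tracks[res$tracks$frame == 1, c("label", "identity", "speed")])
#>    label identity    speed
#> 1      1    polar 1.043759
#> 5      2    polar 1.028106
#> 9      3   border 1.106826
#> 13     4   border 1.007807
#> 17     5   border 1.055102
#> 21     6   border 0.988305

res$coordination
#>   frame         P          M K    mode posterior
#> 1     1 0.9984341 0.03089304 6 running         1
#> 2     2 0.9988091 0.01068671 6 running         1
#> 3     3 0.9984679 0.01785733 6 running         1
#> 4     4        NA         NA 0    <NA>        NA
```

All six entities move at ≈ 1 µm/min (the scheduled speed), the group
polarization is ≈ 1 and the angular momentum ≈ 0 — a textbook running
frame, which the classifier labels accordingly. The last frame has no
outgoing displacement, so its order parameters are undefined by design.
`run1/` now holds the per-stage CSV tables (tracks, coordination,
interfaces, exchanges, protrusions, mobility, rotation), the label-volume
TIFFs and a JSON run manifest whose digests are reproducible given the same
seed.

A command-line front end wrapping the same functions is installed as
`exec/ccmigrate` (`ccmigrate simulate`, `ccmigrate run`).

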