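---
title: "Methods: infant tractometry and R1 development models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infant tractometry and R1 development models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

`babytract` quantifies early white-matter development along named fiber
bundles. Its pipeline has four stages, each usable on its own:

1. **Bundle segmentation.** A whole-brain tractogram (TCK/TRK, subject
   RAS mm) is classified into up to 24 bundles — 11 per hemisphere plus the
   two forceps — using ordered waypoint ROIs defined on an infant template
   and transformed into the subject's space. A streamline is a *candidate*
   for a bundle when it passes through all of the bundle's 2–3 include
   waypoints in order (either traversal direction), and avoids all exclude
   ROIs. Candidates qualifying for several bundles are resolved by a
   probabilistic atlas: the bundle whose probability map has the highest
   mean trilinear value along the streamline wins; exact ties go to the
   lexicographically first bundle name, deterministically. Bundles are then
   cleaned by removing members whose mean Mahalanobis ("gaussian") distance
   from the bundle core exceeds 4 SD.
2. **Tract profiling.** Each cleaned member is resampled to 100 equidistant
   nodes (piecewise-linear, arc-length parameterisation). The *core* is the
   per-node member mean; node covariances are sample covariances with
   (0.1 mm)^2 added to the diagonal. A scalar map (R1 in s^-1 or MD in
   mm^2/s) is sampled trilinearly at every member node and averaged per
   node, by default with gaussian weights exp(-d^2/2) in Mahalanobis
   distance d.
3. **Relaxometry.** T1 (and R1 = 1/T1) is estimated per voxel from
   inversion-recovery magnitude series by fitting |a (1 - b e^(-t/T1))|
   with the Levenberg–Marquardt algorithm.
4. **Development models.** Linear mixed models (LMMs) fitted with lme4:
   per-bundle and per-node models of metric ~ age (days) with a random
   intercept per subject, and three staged models of the node-wise rate —
   rate ~ newborn value; rate ~ spatial coordinates (|x|, y, z, z-scored,
   plus their pairwise interactions); and their union — each with a random
   intercept per bundle, compared by likelihood-ratio test.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| nodes per bundle | 100 | – | standard along-tract resolution; 1-based indices |
| cleaning threshold | 4 | SD | conventional outlier cut for Mahalanobis cleaning |
| cleaning iterations | ≤ 5 | – | removing outliers shifts the core, so cleaning repeats until stable |
| covariance regularisation | (0.1 mm)^2 | mm^2 | keeps near-parallel bundles from producing singular node covariances |
| densification step | half voxel | mm | "passes through" is vertex-in-voxel membership, resolution-anchored |
| node subsampling | every 10th | – | nodes 10, 20, …, 100; neighbouring nodes are strongly dependent |
| TI schedule | 50 + 150k ms, 20 TIs | ms | the package's reference inversion-recovery acquisition |
| T1 multi-start grid | 300…4000 | ms | the absolute-value signal has local minima around the null point |
| T1 bounds | [50, 10000], b in [1, 2.2] | ms | physiological range at 3 T; guards divergence |

Design choices where the convention had to be fixed once:

* **Waypoint membership** is vertex-in-voxel after densification to
  half-voxel steps (half-open voxel boxes centred on voxel centres), not a
  distance threshold — reproducible and resolution-anchored.
* **Atlas conflict score** is the *mean* probability along the streamline,
  not the maximum, so single-voxel peaks cannot hijack an assignment.
  Resolution happens *before* cleaning, so cleaning statistics are computed
  on each bundle's final membership.
* **Orientation.** Storage direction of streamlines is arbitrary; the
  matched traversal direction from candidacy is kept as a flag and applied
  before any node-wise statistic, so node 1 always sits at the order-1
  waypoint end.
* **Z-scoring** uses the sample SD (n−1). Interaction columns are formed
  from the standardized main effects. Subsampled nodes are anchored at
  {10, 20, …, 100} (1-based); the stride is exposed as an argument.
* **LMM contract.** REML for reported fits; ML refits for likelihood-ratio
  tests. The model-3 vs model-2 LRT has 1 df (the newborn term). The
  random-slope comparison uses 2 df (slope variance + covariance), which is
  conservative at the variance boundary. R^2 is *marginal*: the squared
  correlation between the fixed-effects-only prediction and the response;
  the adjusted version applies 1 − (1 − R²)(n − 1)/(n − p − 1). Wald
  ±1.96 SE intervals are reported as 95% CIs.
* **Missing data** are dropped listwise per LMM; profile nodes with no
  valid samples propagate as missing rather than erroring. Strict trilinear
  sampling (any invalid neighbour → missing) is the default so that masked
  structures such as ventricles cannot leak partial-volume values into
  profiles; a lenient mode renormalises over valid neighbours.
* **Relaxometry convergence**: relative RSS tolerance 1e-10, 500
  iterations per start; non-identifiable voxels (constant or all-zero
  signal, too-short schedules) are flagged `converged = FALSE` and come
  back invalid in maps, and profiling simply skips invalid voxels.

# The phantom: what it emulates, and what it does not

All validation runs on a synthetic longitudinal phantom
(`generate_phantom()`) because the package must be exercisable with known
ground truth and no external data. Its defaults are the package's study
conditions and are not tuned per experiment:

* **Geometry.** 24 bundles (11 bilateral pairs mirrored in x, plus two
  midline-crossing forceps) laid out as separated arcs and S-curves in an
  80³ grid of 2 mm voxels centred on a commissure-analog origin. Curvy
  bundles carry a third waypoint. Streamlines are the centerline plus
  smooth random radial jitter (SD 1 mm), stored in random direction to
  exercise orientation handling, with 500 random distractor streamlines.
* **Newborn R1.** Per-bundle means span 0.42–0.55 s^-1 with grand mean
  0.46 s^-1, highest in the projection bundles and lowest in the forceps
  minor and IFOF, plus a small smooth spatial texture (0.002 s^-1).
* **Development.** The voxel-wise rate field combines an
  inferior-to-superior and anterior-to-posterior spatial gradient (applied
  to z-scored coordinates; coefficients of order 1e-4 s^-1/day per
  z-scored unit) with a negative dependence on newborn R1
  (−0.003 day^-1 per s^-1). The mean rate is 0.16/180 s^-1/day, so the
  calibrated newborn and 6-month grand means are 0.46 and 0.62 s^-1.
  Interaction columns in the rate field are centred over the every-10th
  node records; without this the nonzero sample correlation between
  coordinates would shift the grand-mean rate away from its calibrated
  value.
* **Sessions.** 13 subjects, 9/10/10 sessions at nominal ages 10/100/190
  days (six subjects longitudinal across all three timepoints), subject
  random intercept SD 0.01 s^-1, Rician voxel noise SD 0.01 s^-1. The
  nominal ages sit inside the 0/3/6-month recruitment windows and are
  chosen so the newborn→6-month gap is 180 days, which makes the three
  calibration identities (newborn mean, 6-month mean, mean LMM slope ×
  180 d) mutually consistent.
* **MD** mirrors R1 with a negative coupling (higher MD where R1 is lower)
  and negative rates, at realistic infant magnitudes (~1.0–1.3e-3 mm²/s).

What the phantom does **not** emulate: crossing fibers and real
tractography failure modes, partial-volume anatomy beyond a single
ventricle-analog blob, B1/field inhomogeneities, registration error (the
phantom's template and subject grids coincide; the ROI-transform machinery
is tested separately on constructed transforms), and nonlinear growth.
Passing round-trips therefore demonstrates the correctness of the
machinery under controlled conditions, not robustness to real acquisition
artifacts.

# Problem sizes used in validation

The package's own test suite runs the full default phantom once for the
grand-mean round trip, and a reduced design — 12 streamlines per bundle,
50 distractors, three fully longitudinal subjects — for repeated
experiments (20-seed end-to-end sign recovery, coefficient-coverage
sweeps). The reduced design keeps every structural feature (all 24
bundles, all noise sources at their default levels) and only lowers the
replication counts; coefficient-recovery experiments use the record-level
generator (`simulate_slope_records()`, 240 records, residual SD
2e-5 s^-1/day) rather than re-simulating volumes, matching how the staged
models consume node-level rates.

# Numerical notes and degenerate inputs

* Arc-length resampling clamps the final node against floating-point
  overshoot of the total length (`rule = 2` interpolation).
* Mahalanobis distances use regularised covariances throughout; a
  single-member bundle gets the regularisation floor rather than an error.
* Bundles with fewer than 5 members skip cleaning with a warning; empty
  bundles are reported empty, never as errors.
* Dice of two empty masks is defined as 0 with a warning.
* The tie-break in candidate resolution, the node subsampling anchor, and
  profile-table row ordering are all deterministic, so identical inputs
  and seeds give byte-identical outputs.
* TCK is the only streamline output dialect; TRK is normalised to RAS mm
  on read through its header affine and voxel size.

# Known limitations

* The waypoint atlas shipped for validation is the phantom's own; real
  infant-template ROIs are consumed as user-supplied NIfTI inputs and are
  not redistributed.
* `transform_rois_to_subject()` accepts affine transforms; dense
  displacement fields are out of scope.
* Node-wise LMMs are fitted independently; no multiplicity correction is
  applied across nodes.
* The random-slope LRT's chi-square reference is conservative near the
  variance boundary; with few groups, fixed-effect LRTs on group-level
  covariates can be mildly anti-conservative, which is why the staged
  model comparison is also reported with its R² values rather than the
  test alone.
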