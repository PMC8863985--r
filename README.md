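# babytract

Tractometry and quantitative-MRI development modeling for the infant
brain.

In the first six months of life the longitudinal relaxation rate R1
[s⁻¹] of white matter — which is linearly related to its myelin fraction —
rises steeply, and not uniformly. `babytract` is an R toolkit for
quantifying that development along named white-matter bundles in
individual infants:

* **Bundle segmentation** of whole-brain tractograms (TCK/TRK) into up to
  24 bundles (11 per hemisphere + forceps major/minor) using ordered
  waypoint ROIs, a probabilistic atlas for multi-bundle candidates, and
  iterative Mahalanobis-distance cleaning of outlier streamlines at 4 SD
  from the bundle core.
* **Tract profiling**: each bundle resampled to 100 equidistant nodes;
  per-node core coordinates, covariances, and gaussian-weighted means of
  R1 or mean-diffusivity (MD) maps sampled trilinearly, with strict
  missing-data propagation around excluded structures (ventricles).
* **Inversion-recovery relaxometry**: voxel-wise T1 (and R1 = 1/T1) from
  magnitude IR series by Levenberg–Marquardt fits of
  |a (1 − b e^(−t/T1))|, multi-started across a T1 grid.
* **Validation**: dice coefficients DC = 2|A∩B| / (|A| + |B|) between
  bundle voxel masks.
* **Development models** (lme4): per-bundle and per-node linear mixed
  models `metric ~ age + (1 | subject)`, and the three staged models of
  the node-wise development rate

  ```
  rate ~ 1 + R1_newborn                                  + (1 | bundle)   # initial value
  rate ~ 1 + |x| + y + z + |x|·y + |x|·z + y·z           + (1 | bundle)   # spatial gradients
  rate ~ 1 + R1_newborn + |x| + y + z + interactions     + (1 | bundle)   # combined
  ```

  on every 10th node with z-scored coordinates, compared by
  likelihood-ratio tests.
* **A synthetic longitudinal phantom** with fully known ground truth —
  bundle geometry, streamlines, waypoint/probability atlases, longitudinal
  R1/MD volumes, IR series — implementing configurable speed-up
  (rate depends negatively on newborn value) and spatial-gradient effects,
  so the entire pipeline can be exercised end-to-end without any study
  data.

## Worked example

Simulate a phantom, segment it, profile R1, and fit the staged models:

```r
library(babytract)

cfg <- phantom_config(seed = 1)
ph  <- generate_phantom(cfg, metrics = "r1")

bundles <- segment_all(ph$streamlines, ph$atlas)
bundles[["CS_L"]]
#> <segmented_bundle> CS_L: 50 members (1 removed by cleaning)

tab <- do.call(rbind, lapply(ph$sessions, function(s) {
  profs <- lapply(bundles, compute_profile, vol = s$r1,
                  set = ph$streamlines, metric = "r1")
  profile_table(profs, s$meta)
}))

dev <- fit_mean_bundle_development(tab, "r1")
round(mean(dev$summary$newborn_mean), 3)       # grand newborn mean, s^-1
#> [1] 0.459
round(mean(dev$summary$slope_per_day) * 180, 3) # mean 6-month increase, s^-1
#> [1] 0.161

map <- fit_nodewise_development(tab, "r1", nodes = seq(10, 100, 10))
fits <- fit_slope_models(subsample_every_kth(map, 10))
round(fits$model3$beta[c("newborn_mean", "z", "y")], 5)
#> newborn_mean            z            y 
#>     -0.00303      0.00017     -0.00011
fits$lrt$pvalue < 0.05   # combined model beats the spatial model
#> [1] TRUE
```

The negative `newborn_mean` coefficient is the speed-up effect (bundle
sections with lower newborn R1 develop faster); the positive `z` and
negative `y` coefficients are the inferior-to-superior and
anterior-to-posterior gradients of development rate, in s⁻¹/day per
z-scored coordinate. All three match the phantom's generating values.

A command-line wrapper over the same functions is installed at
`inst/cli/babytract.R` with subcommands `simulate`, `t1fit`, `segment`,
`profile`, `dice`, `model` and `run-all`.

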