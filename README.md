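# matt4d

Macrovascular arterial transit time (mATT) mapping from arterial-spin-labeling
(ASL) based 4D magnetic resonance angiography.

Time-resolved 4D-MRA acquires one 3D volume per labeling duration; the
control-minus-label difference signal at an arterial voxel is zero until the
labelled blood bolus arrives and then rises toward saturation. `matt4d` fits a
two-piece saturation model per voxel,

    f(t) = 0                    for t <= b
    f(t) = m * t / (h + t)      for t >  b        (shifted form available)

whose breakpoint `b` is the macrovascular arterial transit time — the time for
the leading edge of the label bolus to reach that voxel. `m` is the saturation
level and `h` the half-rise time. This quantifies hemodynamic timing in the
large conduit arteries (internal carotid, middle/anterior cerebral and their
branches), complementary to tissue-level transit times from multi-delay ASL,
and is aimed at cerebrovascular questions such as steno-occlusive disease
(moyamoya), vasodilatory reactivity (acetazolamide challenges) and bypass
evaluation.

The package provides the complete processing chain:

* **Vessel isolation** — pairwise label/control subtraction, temporal-maximum
  image, multiscale 2D Frangi vesselness in the three cartesian planes,
  directional-mask intersection, morphological area opening, and
  vessel-mask-guided joint bilateral smoothing.
* **Model fitting** — profiled nonlinear least squares per voxel with an
  exhaustive breakpoint grid plus Levenberg–Marquardt polish; noise-floor
  detection of unreliable voxels; mATT / amplitude / fit-quality maps and the
  global maximum mATT (`matt_total`).
* **Atlas projection** — regional averaging of the sparse vessel map into a
  region-label volume, filled parametric maps, pre/post difference tables and
  a common-vessel-mask correction for vasodilation comparisons.
* **Hemodynamic statistics** — slice-wise mATT profiles versus caudal-cranial
  distance, linear distance regression with adjusted R², group summaries, and
  regional cross-modal correlation (e.g. mATT versus tissue ATT).
* **Synthetic data** — a seeded generator of vascular-tree phantoms with known
  per-voxel transit times, noise, pulsatility-artifact blobs, block atlases
  and tissue-ATT maps, used for all quantitative validation.

NIfTI volumes are read and written with `RNifti`; a thin command-line wrapper
(`exec/matt4d`) exposes `simulate`, `isolate`, `fit`, `project`, `delta`,
`stats`, `run` and `demo` subcommands.

## Worked example

A fully synthetic end-to-end run (no input files needed):

```r
library(matt4d)

cfg <- pipeline_config(
  sim = sim_config(shape = c(64, 64, 64), gradient = 7.7, b0 = 500,
                   m0 = 10, m_taper = 0, noise_sigma = 1, blob_count = 3,
                   n_trunks = 4, seed = 101),
  isolation = isolation_params(min_size = 200),
  atlas_blocks = c(4, 4, 2), group_size = 3, seed = 101)

res <- run_pipeline(cfg, write_outputs = FALSE)
res$regression
#> mATT-distance regression: slope 7.89 ms/mm, intercept 516 ms, adj. R2 0.985 (n = 21)
res$matt_tot
#> [1] 1114.891
tab <- res$projection$table
tab[!is.na(tab$mean_matt_ms), ][1:3, ]
#>    region_label mean_matt_ms n_vessel_voxels region_volume
#> 6             6     658.6388            1055          8192
#> 7             7     670.3473             704          8192
#> 11           11     625.3047             185          8192
```

The fixture simulates labelled blood entering the most caudal slice at
500 ms and arriving 7.7 ms later per mm travelled along the vessels; the
pipeline isolates the synthetic arteries, fits every retained voxel and
recovers the gradient as the slope of the slice-wise regression
(7.89 ms/mm). `res$matt_tot` is the global maximum mATT: the arrival time
at the most distal vessels still visible at this SNR. Regional means come
from projecting the sparse vessel voxels onto a 32-region block atlas;
regions without vessel voxels stay undefined.

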