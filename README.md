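# filotrack

Reconstruction, tracking and quantification of filopodia in time-lapse
confocal z-stacks of developing muscle tips.

Migrating myotubes probe for their tendon-cell targets with filopodia —
thin, actin-rich protrusions a few micrometres long. Their number and
maximum length are the standard readouts of this exploratory behaviour,
but extracting them from live recordings (5–7 z-sections 0.7 µm apart,
one stack every 15 s) is hard: filopodia are one or two pixels thick,
dim, crowded, and dynamic. filotrack is an R implementation of a
semi-automated reconstruction pipeline for exactly these recordings,
aimed at quantitative cell biologists working on protrusion dynamics.

## The method

**Per-frame detection** (steps in `detect_segments()`):
superpixel foreground extraction (SLIC-style, 3 labels, no enforced
connectivity) → cell-body masking (σ=5 blur, adaptive thresholding
against a large Gaussian-weighted neighbourhood, 5-px disk erosion) →
Frangi vesselness on the Hessian eigenvalues |λ₁| ≤ |λ₂| ≤ |λ₃|,

> V = (1 − e^(−r_a²/2α²)) · e^(−r_b²/2β²) · (1 − e^(−s²/2c²)),  r_a = |λ₂|/|λ₃|,  r_b = |λ₁|/√|λ₂λ₃|

(zeroed where λ₂ > 0 or λ₃ > 0) → superpixel segmentation of the
vesselness output (compactness 10) with 3D binary closing → removal of
3D regions under 200 voxels → topology-preserving 3D skeletonization →
decomposition of branched skeletons into line segments.

**Curation**: a JSON-scriptable edit contract (`remove` / `merge` /
`accept`; see `apply_edits()`, `auto_accept()`) replaces interactive
cleanup.

**Linking** (`track_movie()`): for each frame, candidate matches are
previous filopodia within a 25-pixel cutoff over the preceding five
time points; each pair is scored S = 0.46·M_L + 0.6·M_D with
M_L = |L_c − L_p| / max{L_c, L_p} and M_D = (1 − cos θ)/2 on the mean
direction vectors, then linked greedily from the lowest score. Leftover
filopodia start new tracks.

**Quantification**: tracks are kept if they reach ≥ 3 µm and exist for
≥ 2 frames (`filter_tracks()`); readouts are per-frame counts
(`count_filopodia()`), the ECDF of maximum lengths
(`ecdf_max_length()`), a shifted-exponential fit of the length
distribution (`exponential_diagnostic()`, with `tidy()`/`glance()`
methods) and Mann–Whitney group comparisons (`compare_groups()`).

A ground-truthed synthetic movie generator (`simulate_movie()`) and a
scorer (`score_against_truth()`) validate every stage without
microscope data.

## Worked example

```r
library(filotrack)

# a 15-minute synthetic recording: 60 frames, 6 z-sections, 8 filopodia
sim <- simulate_movie(sim_config(seed = 1))

# detection -> auto-curation -> linking
tracks <- run_pipeline(sim$stack)

# keep quantifiable filopodia (>= 3 um, >= 2 frames)
passing <- filter_tracks(tracks)
track_summary(passing)
#> # A tibble: 8 × 5
#>   track_id birth_frame last_frame lifetime_frames max_length_um
#>      <int>       <int>      <int>           <int>         <dbl>
#> 1        1           4         42              39          9.94
#> 2        2           5         46              39          8.77
#> 3        3           8         46              39         10.2
#> 4        5          17         47              30          8.28
#> 5        6          18         47              26          6.75
#> 6       10          24         40              16          5.62
#> 7       17          33         44              12          3.62
#> 8       18          35         47              12          3.68
```

Eight tracks survive the filter — one per simulated filopodium — and
their maximum lengths land within a few tenths of a micrometre of the
true values (3.4–9.6 µm in this scene).

```r
summary(count_filopodia(passing))
#> # A tibble: 1 × 2
#>   mean_count distinct_tracks
#>        <dbl>           <int>
#> 1       3.55               8
```

On average 3.55 filopodia exist per frame of the 15-minute window, from
8 distinct identities (births are staggered, so fewer coexist than
exist overall).

```r
fit <- exponential_diagnostic(3 + rexp(500, 0.5), offset = 3)
fit
#> <shifted exponential fit> rate = 0.5235 / um (mean = 3 + 1.91 um), n = 500
#>   KS distance 0.0380 (p = 0.465)
```

Maximum lengths above the 3 µm cut-off are summarised by the rate of a
shifted exponential (here recovering the true rate 0.5/µm within 5%);
the Kolmogorov–Smirnov distance quantifies how exponential the sample
is. `autoplot()` methods draw the ECDF, the fitted distribution and
per-track length histories.

```r
score_against_truth(tracks, sim$truth)
#> # A tibble: 1 × 9
#>   recall precision identity_accuracy length_bias_um length_rmse_um ...
#> 1      1         1             0.900          0.204          0.404
```

Against the generator's ground truth the automated pipeline recovers
every filopodium instance (recall and precision 1.0) with a
per-filopodium maximum-length RMSE of 0.40 µm, about half a voxel
diagonal.

## Layout

- `R/` — implementation; `src/core.cpp` holds the separable filtering,
  Hessian eigenvalue, 3D morphology/labelling and thinning kernels.
- `tests/testthat/` — oracle-backed unit and property tests plus the
  end-to-end recovery suite.
- `vignettes/filopodia-reconstruction.Rmd` — the methods account:
  model, parameters, numerical choices, generator realism, limitations.
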