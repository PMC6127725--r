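---
title: "Reconstructing and tracking filopodia in time-lapse confocal z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and tracking filopodia in time-lapse confocal z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filotrack)
```

## The problem

Elongating myotubes in the *Drosophila* embryo probe their surroundings
with filopodia — actin-rich protrusions a few micrometres long and well
under half a micrometre thick — before attaching to tendon cells. Live
confocal recordings of these muscle tips are short z-stacks (5–7
sections, 0.7 µm apart) acquired every 15 s for about 15 minutes. The
biological readouts are simple: how many filopodia exist at a muscle tip
over a recording window, and what maximum length each filopodium reaches
over its lifetime. Getting there is not simple: filopodia are thin,
dim, densely packed, embedded in a crowded tissue, and they grow,
retract and wave between frames.

filotrack implements a semi-automated reconstruction in three layers:

1. **per-frame detection** — seven image-processing steps turning a raw
   z-stack into curated line segments;
2. **curation** — a scriptable edit contract (remove / merge / accept)
   standing in for the interactive cleanup an expert would do;
3. **linking** — greedy score-based association of filopodia across
   frames into identity tracks, followed by filtering and
   quantification.

A ground-truthed synthetic movie generator (`simulate_movie()`) makes
every stage testable without microscope data.

## Per-frame detection

Each frame (a Z×Y×X volume) passes through:

1. **Pixel segmentation** (`segment_pixels`). Each z-plane is clustered
   into three superpixel labels (SLIC-style k-means over intensity and
   position, no connectivity enforcement). Labels whose mean intensity
   stays within 25% of the label-mean spread above the dimmest label are
   treated as background. We deliberately do not call everything outside
   the single dimmest label foreground: when most of a plane is
   background, the three clusters simply split the noise distribution,
   and such a rule would promote the upper noise tertiles into
   foreground. The contrast rule retains the cell and its protrusions
   and rejects noise partitions; `background = "lowest-mean"` and
   `"none"` remain available.
2. **Cell-body identification** (`find_cell_body`). Aggressive Gaussian
   blurring (σ = 5 px) followed by adaptive thresholding against a
   Gaussian-weighted neighbourhood mean (nominal side 999 px, clamped to
   the image) and erosion with a 5-px disk. Two numerical choices
   matter. First, the threshold carries an offset of 10% of the blurred
   plane's intensity range — with a zero offset, half of any flat
   background lies above its own local mean. Second, before the erosion
   we apply a binary opening with a disk of radius 2σ: the blur widens a
   bright filopodial ridge to roughly four blur sigmas, which survives a
   5-px erosion, so without the opening the shafts of long isolated
   filopodia are classified as cell body and later deleted from the
   skeleton. The opening removes anything thinner than ~2·(2σ)+1 px
   while leaving the much wider body intact.
3. **Vesselness filtering** (`frangi_filter`). The Hessian is computed
   with Gaussian derivatives at scales {1, 1.5, 2} px (filopodia are
   1–2 px in radius) on the foreground-gated intensity frame — the
   pixel segmentation supplies the gate, while the retained intensity
   amplitudes keep the structureness term informative. Per voxel the
   eigenvalues are ordered |λ₁| ≤ |λ₂| ≤ |λ₃| and combined into the
   Frangi measure
   V = (1 − exp(−r_a²/2α²)) · exp(−r_b²/2β²) · (1 − exp(−s²/2c²)),
   with r_a = |λ₂|/|λ₃|, r_b = |λ₁|/√|λ₂λ₃|, s the Frobenius norm,
   α = β = 0.5 and c resolved per scale to half the maximum Frobenius
   norm; V = 0 wherever λ₂ > 0 or λ₃ > 0 (bright-tube convention).
   Scales are max-combined after γ-normalisation (×scale²).

   A note on anisotropy: the package can rescale z-derivatives by the
   voxel aspect ratio dz/dx (`anisotropy = TRUE`), which is the
   geometrically faithful Hessian. It is **off** by default. With
   0.7 µm sections and a sub-half-micrometre axial PSF, a filopodium is
   physically plate-like — its axial extent is smaller than one section
   — and the corrected eigenvalue ratios (r_a ≈ 0.07) zero out the
   vesselness of exactly the structures we want. Filtering in index
   space lets the filter's own z-smoothing restore tube-like ratios; it
   also matches the convention of stating distances in pixels.
4. **Vesselness-output segmentation** (`segment_vesselness`). The same
   superpixel clustering (compactness 10) per plane of the vesselness
   field; labels are foreground when their mean exceeds both the
   contrast cut and an absolute floor (0.05). The floor makes frames
   without any tubular structure yield an empty mask instead of
   promoting their noise ceiling. A 3D binary closing (ball radius 1)
   heals broken lines.
5. **Small-region removal** (`remove_small_objects`). 26-connected 3D
   regions under 200 voxels are discarded — the step operates on the
   whole z-stack of a frame, hence the high threshold.
6. **Skeletonization** (`skeletonize_frame`). Topology-preserving
   directional curve thinning: border voxels are deleted from the six
   face directions in turn when they are simple points (removal changes
   neither the local foreground 26-connectivity nor the background
   6-connectivity) and not curve endpoints. Deletions within one
   sub-iteration are re-checked sequentially, so connected-component
   count and topology are preserved exactly. Skeleton voxels inside the
   cell-body mask are then removed (`mask_skeleton`).
7. **Segment extraction** (`split_segments`). The skeleton is treated
   as a 26-adjacency graph. Redundant diagonal chords (an edge a–c
   bridging a one-voxel step a–b–c) are pruned so digitised corners are
   not mistaken for branches; each connected region is decomposed into
   simple paths meeting only at branch voxels (≥ 3 neighbours), with
   lexicographic (z, y, x) tie-breaks for determinism. In the automated
   pipeline, side branches of ≤ 6 voxels dead-ending off a junction —
   typical thinning artefacts on thick tubes — are pruned so the main
   path runs through uninterrupted (`prune_spurs`).

## Curation

Automatic extraction over-segments by design; the published workflow has
an expert remove spurious segments (noise, neighbouring cells) and join
fragments of one filopodium. filotrack encodes that contract as an edit
script — an ordered tibble of `remove`, `merge` and `accept` commands,
serialisable to JSON — which an interactive tool could emit and which
`auto_accept()` fills in trivially for unattended runs. `apply_edits()`
executes the script: merged segments are chained greedily by nearest
endpoints (refusing gaps beyond `merge_gap = 5` voxels), every surviving
instance is oriented base→tip with the base at the endpoint nearest the
cell-body mask (falling back to the frame's segment centroid when no
body voxel exists), and per-instance path lengths and the mean
non-normalised direction vector d̄ (average of consecutive calibrated
displacement vectors) are computed.

**Length measurement.** Physical path length is the arc length of a
smoothed copy of the voxel path; the raw index-space voxel length is
kept alongside (`length_vox`). On a grid with 0.7 µm sections and
0.08 µm pixels, a digitised centreline that merely jitters between two
neighbouring slices gains ~0.7 µm per spurious crossing — we measured
raw-path inflation of 2–3 µm on 9 µm filopodia. The x/y coordinates
are smoothed with a 5-voxel moving average (endpoints pinned); z with a
15-voxel window, justified by geometry: filopodia run nearly parallel to
the imaging plane, so genuine axial slope varies over micrometres while
thinning jitter alternates voxel to voxel, and a wide mean preserves the
net axial displacement of a real slice transition.

## Linking

Frames are processed in order. For each frame, a candidate pair is any
(instance, track) whose minimum voxel-to-voxel path distance to the
track's most recent instance within the five-frame lookback window is at
most 25 px (distances in raw pixel units, z unscaled, matching the
cutoff's stated unit; a calibrated-distance switch exists). Each
candidate is scored

* M_L = |L_c − L_p| / max{L_c, L_p} — relative length difference;
* M_D = (1 − cos θ)/2 — angle between the mean direction vectors d̄,
  0 for parallel, 1 for antiparallel (the magnitudes of the
  non-normalised vectors cancel in the cosine);
* S = 0.46·M_L + 0.6·M_D, the published weights kept exactly as
  printed (they do not sum to 1 and are not renormalised).

Pairs are sorted by S ascending and linked greedily, one-to-one; ties
break by (M_L, instance id, track id) for reproducibility. Unmatched
instances found new tracks; a track absent for the full lookback window
ends. Candidate generation uses each track's most recent instance
rather than all instances in the window — this avoids one track
dominating the candidate list — but `candidate_mode =
"any-within-window"` implements the wider reading.

## Quantification

`filter_tracks()` keeps tracks with maximum length ≥ 3 µm **and**
presence in ≥ 2 frames (both bounds closed — "at least"). The
lifetime condition counts frames present, so a track bridging a linking
gap still qualifies; `strict_consecutive = TRUE` demands an actual
consecutive pair. `count_filopodia()` reports per-frame counts over a
15-minute window plus two summaries — the mean per-frame count and the
number of distinct tracks — because "number of filopodia in a window"
is ambiguous between the two; both are emitted. `ecdf_max_length()`
builds the empirical cumulative distribution of per-track maximum
lengths (after the 3 µm cut-off). `exponential_diagnostic()` fits a
shifted exponential to the maximum lengths by maximum likelihood
(rate = 1/mean excess over the 3 µm offset) and reports a
Kolmogorov–Smirnov distance — maximum lengths are approximately
exponential, consistent with stochastic actin incorporation rather than
a set preferred length. `compare_groups()` is a two-sided Mann–Whitney
test (exact for small untied samples, normal approximation with tie
correction otherwise, no continuity correction so identical samples give
p = 1).

## The synthetic generator

`simulate_movie()` renders a bright ellipsoidal cell body (in-plane
radii 55 × 45 px, 2.2 sections axially, intensity 150, soft edge) with
thin dynamic protrusions on a noisy background, and records the truth:
per frame and filopodium, the centreline voxel path, analytic arc
length and direction, plus the body mask and the drawn maximum lengths.

Default conditions mirror the acquisitions the pipeline targets: 60
frames at 15 s (a 15-min window), 6 sections at 0.7 µm, 256×256 px.
The in-plane pixel size is not something a TIFF can be trusted to know
and is not fixed by the protocol; the generator uses 0.08 µm/px,
typical Nyquist-ish sampling for a 63×/1.4 NA confocal. Eight
filopodia with maximum lengths drawn uniformly on 3–10 µm (an
offset-exponential mode exists) grow at 0.5 µm/frame from anchors
stratified around the tip (a fan over ±70°, with jitter), dwell four
frames, and retract; the per-frame direction jitter is bounded so tips
drift ≤ `drift_px` px/frame. Tubes are rendered as Gaussian profiles
with σ = 2 px laterally and 0.8 sections axially — the latter emulates
the axial PSF of live-imaging confocals (pinhole opened for speed), and
is what makes a filopodium visible in 2–3 sections. Intensities: tube
peak 190 over background 10 with Gaussian noise σ = 19, i.e. SNR ≈ 10;
optional Poisson noise. Everything is deterministic given `seed`.

What the generator does *not* emulate: optical PSF convolution of the
body (only tubes get the Gaussian profile), photobleaching, camera-
specific noise, sample drift, neighbouring cells, and filopodia from
out-of-view structures. Passing the recovery tests therefore shows the
pipeline handles the geometry, anisotropy, crowding and noise level of
these recordings — not that it is robust to every real-world artefact;
on real data the curation step exists precisely to absorb what the
generator leaves out.

## Validation and measured behaviour

The test suite checks each stage against independent oracles
(brute-force component labelling, exhaustive candidate search, an
independent greedy matcher, permutation tests) and the end-to-end
pipeline against generator truth. On the default scene the full
automated pipeline (with `auto_accept`, no manual curation) reaches
per-frame recall and precision at or near 1.0 with a per-filopodium
maximum-length RMSE well under one voxel diagonal (~0.71 µm); identity
accuracy for well-separated filopodia (≥ 3× the 25 px cutoff) is exact
across seeds. Crowded fans do produce occasional identity switches
(accuracy ~0.9 on the dense default scene), which is why length
recovery is scored per filopodium by coverage attribution rather than
through track identity. `scripts/acceptance.R` recomputes all of these
from scratch; problem sizes (one 60-frame default scene, five 20-frame
identity scenes, 100 random linking scenes, n = 500 rate recovery) were
chosen to exercise the study conditions at desk scale.

## Degenerate inputs and edge rules

Constant frames segment to all-background with a warning. A zero
direction vector scores M_D = 0.5 (uninformative) with a warning.
Merges whose nearest endpoints exceed `merge_gap` fail naming the ids.
A 2D frame is accepted by the per-plane steps; the 3D Hessian requires
Z ≥ 3 and says so. Region removal uses a strict `< 200` rule, so a
200-voxel region survives. Serialized artifacts store only integer
voxel paths and ids; derived lengths are recomputed on read, making
round trips exact. TIFF axis metadata is never guessed: multi-page
files require explicit frame/slice counts.

## Known limitations

* The vesselness "modification" used by the original workflow is not
  characterised beyond empirically chosen weights; we use the standard
  three-factor Frangi form with all weights exposed.
* The direction measure's published form is not recoverable; the
  (1 − cos θ)/2 reconstruction is bounded like M_L and uses exactly the
  stated ingredients, but other choices would interact differently with
  the 0.46/0.6 weights.
* Densely crossing filopodia can merge into one skeleton component; the
  automated path does not split them (the edit script can).
* Greedy linking is the published procedure and is kept; it is not an
  optimal assignment and can cascade one bad early link.
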