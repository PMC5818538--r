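---
title: "Fuzzy feature fusion for glioma GTV auto-segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy feature fusion for glioma GTV auto-segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliofuse)
```

## The problem

Delineating the gross tumour volume (GTV) of a glioma for radiotherapy
planning from structural MRI alone is unreliable: infiltrating tumour
extends beyond the contrast-enhancing rim on T1C and the hyperintensity on
T2. Diffusion and perfusion MRI carry complementary functional signal —
apparent diffusion coefficient (ADC) rises in tumour and oedema,
fractional anisotropy (FA) falls where tumour disrupts white-matter
tracts, and relative cerebral blood volume (rCBV) rises with tumour
vascularity — but none of the three admits a crisp diagnostic threshold.
gliofuse treats the three descriptions as fuzzy evidence: each modality
votes a *possibility* of tumour per voxel, the votes are fused, and the
fused possibility map is segmented.

## Membership models

A membership model maps a parametric value to a tumour possibility in
[0, 1]. Two parametric forms are supported:

* **gaussian2**, a sum of two Gaussians
  $a_1 e^{-((v-c_1)/s_1)^2} + a_2 e^{-((v-c_2)/s_2)^2}$ — used for ADC
  (coefficients 0.5, 1.5, 0.33, 0.5, 1.57, 0.66; ADC carried in units of
  $10^{-3}\,\mathrm{mm^2/s}$ throughout, so the centres 1.5 and 1.57 are
  physiological tumour/oedema values) and for the rCBV ratio
  (0.65, 1.1, 0.8, 0.5, 2.68, 2.37);
* **sigmoid_diff**, a scaled difference of two logistic sigmoids
  $\mathrm{scale}\,\bigl(\sigma(k_1(v-x_1)) - \sigma(k_2(v-x_2))\bigr)$ —
  used for FA (1.1, 60, 0.06, 15.76, 0.27): memberships rise sharply above
  FA ≈ 0.06 (excluding CSF-like free water) and fall past FA ≈ 0.27
  (organised white matter).

All evaluations are clamped to [0, 1]. For the canonical coefficients the
clamp never activates (the FA model peaks at ≈ 0.977), but the scale
factors make values above 1 mathematically possible for refitted
coefficients, and a membership must remain a valid possibility.

```{r, fig.width = 5, fig.height = 3}
autoplot(canonical_membership("ADC"))
```

### Estimating models from samples

`build_histogram()` implements a fuzzy-statistics estimate of the
membership frequency: each sample — a mean ± SD summary of tumour-region
values from a clinical ROI or a published table — votes for every
histogram bin its interval overlaps. Three choices here were genuinely
open and are fixed as follows:

* **Binary overlap counting.** A sample either covers a bin (any
  positive-length intersection) or it does not; no partial-area
  weighting. This is the simplest defensible counting rule and is
  isolated behind the one operation, so a weighted variant could be
  swapped in without touching anything else. Interval endpoints that
  merely touch a bin edge do not count (zero-measure overlap), guarded
  with a small epsilon against floating-point jitter.
* **Max-to-1 normalisation.** Frequencies are divided by the maximum bin
  count, not by the area. Memberships are possibilities, not
  probabilities: the most-supported parametric value should have
  membership 1.
* **Default bin widths** of 0.05 ($10^{-3}\,\mathrm{mm^2/s}$) for ADC,
  0.01 for FA and 0.25 for the rCBV ratio resolve each canonical curve
  with at least 30 bins across its support.

`fit_membership()` fits either parametric form to a histogram by bounded
Levenberg–Marquardt least squares (via minpack.lm) on the bin centres,
with widths and slopes bounded below by $10^{-6}$, an iteration cap of
1000 and tolerance $10^{-10}$. The fit is deterministic given its
initialisation. Fits are flagged *degenerate* when the histogram is flat
(zero variance — a flat histogram is perfectly representable by two very
broad Gaussians, so the residual alone cannot detect it) or when the RMS
residual per bin stays above 0.05. On noise-free model-generated
histograms the fit recovers the generating coefficients to well under 1%
relative error, which the test suite asserts for both gaussian2 models.

The shipped sample table (`synthetic_membership_samples()`) is a
synthetic stand-in: it reproduces the documented sample *counts* (32 ADC,
21 FA, 32 rCBV-ratio records) and plausible per-modality ranges, not any
measured values, and is labelled synthetic in its filename and
documentation.

## The functional branch

1. `compute_rcbv_ratio()` divides the raw CBV map by the mean over a
   25-pixel (5×5) ROI in contralateral normal-appearing white matter,
   converting scanner units to the ratio scale of the membership model.
2. `eval_membership_volume()` maps each volume through its model inside
   the brain mask.
3. `fuse()` combines the three feature spaces by the voxel-wise geometric
   mean $\sqrt[3]{FS_{ADC}\,FS_{FA}\,FS_{CBV}}$ — a compromise operator:
   idempotent, symmetric, monotone, bounded by the componentwise min and
   max, and zero whenever any modality vetoes the voxel.
4. `segment_functional()` thresholds the fused volume at 0.6 (inclusive,
   and exposed as a parameter) inside an operator-supplied limit mask,
   then cleans each axial slice in a fixed order: fill holes against a
   4-connected background; erode twice with a flat disk of radius 3
   pixels; dilate twice with the same disk; keep the largest 8-connected
   region.

Numerical choices pinned for reproducibility:

* The radius-3 disk is the exact Euclidean-ball discretisation
  $\{(i,j): i^2+j^2 \le 9\}$ — a 29-pixel footprint on a 7×7 grid. Other
  discretisations (e.g. a 37-pixel quasi-disk) would change results at
  the pixel level, so the set is pinned and tested.
* Outside the slice is background for all morphological operators.
* The largest-component step runs per axial slice by default, matching a
  slice-wise reading of the cleanup sequence; whether it should instead
  be applied to the stacked volume is not decidable from the method's
  description, so `largest_component = "volume"` (26-connectivity)
  provides the other reading.
* Ties for the largest component are broken by the lowest label id, with
  components numbered in column-major raster order.
* The interactive step of an operator limiting the thresholding area
  becomes an explicit `limit` mask input, defaulting to the brain mask —
  an interactive step must become a data input in a library.

## The anatomical branch

`fcm_cluster()` is a standard fuzzy c-means on scalar intensities:
memberships $u_{ij} \propto d_{ij}^{-2/(m-1)}$, centroids the
$u^m$-weighted means, objective $\sum_{ij} u_{ij}^m d_{ij}^2$. Defaults
are the conventional fuzzifier $m = 2$, tolerance $10^{-5}$ on centroid
movement, and at most 300 iterations. Initial centroids are spread evenly
between the 1st and 99th intensity percentiles with a small seeded
jitter; placing them at distribution quantiles directly would collapse
several onto the background mode (most voxels of a head image are air),
while the percentile-anchored spread is deterministic under the recorded
seed and robust to the intensity scale. Voxels at zero distance to a
centroid get full membership there. The per-iteration objective trace is
stored and tested to be non-increasing.

Clustering runs over the full field of view with $k = 3$, so non-brain
voxels form their own cluster alongside normal brain and tumour;
`select_tumor_cluster()` takes the cluster with the highest centroid
(tumour is hyperintense on both T1C and T2) but restricts its mask to the
brain. `cleanup_and_grow()` fills holes per slice, opens once with the
radius-3 disk to cut tenuous bridges to normal tissue — the specific
operator pair behind the anatomical cleanup was not prescribed, so this
minimal fill + opening stand-in is isolated behind one function — and
then grows the region from a user seed. Region growing on a binary
cluster mask reduces exactly to connected-component extraction, here
26-connected in 3-D (tumours are 3-D objects even when the morphology is
slice-wise; `growth = "slice"` gives the per-slice variant). The
anatomical GTV is the union of the T1C and T2 results.

## Combination and evaluation

`combine_masks()` unions the functional and anatomical masks into the
final GTV. `reference_delineation()` codifies threshold-based reference
masks on the functional maps with strict, grade-specific comparisons —
ADC > 1.24 (high grade) / 1.11 (low grade) $\times 10^{-3}\,\mathrm{mm^2/s}$,
FA < 0.286 / 0.17, rCBV ratio > 5.18 / 2.32 — intersected with the brain
and minus an exclusion mask (CSF, necrosis, vessels). How a clinician
would "integrate" the three per-modality regions is not reproducible from
a description; the codified rule here is their union.

`compute_metrics()` reports, per case: volume difference
$\Delta V(\%) = |V_{auto}-V_{manual}|/V_{manual} \times 100$, Dice
$2|A\cap M|/(|A|+|M|)$, sensitivity $|A\cap M|/|M|$, and specificity
$TN/(TN+FP)$ over an **explicit universe** mask. The true-negative domain
is a required parameter because it is otherwise arbitrary — enlarging the
field of view inflates specificity without bound; the brain mask is the
default and the voxel count of the universe is echoed in every report.
Volumes are voxel counts × voxel volume in cm³. `aggregate_metrics()`
summarises cohorts as mean and sample SD (n − 1 denominator), which
reproduces the shipped nine-case cohort's printed summaries exactly.

## The synthetic phantom

`generate_phantom()` builds a seeded, fully synthetic co-registered study:
an ellipsoidal brain with a white-matter interior, a grey-matter shell and
a ventricular CSF pocket, plus an ellipsoidal tumour core with an oedema
margin. Default grid 128×128×20 at 1.875×1.875×6 mm — a typical
perfusion-resolution matrix, and a size at which the full pipeline runs in
seconds. Per zone and modality the tissue table fixes a mean and SD; a
voxel's value is `mean + noise_level * SD * N(0,1)`, so `noise_level = 0`
yields exactly zone-constant volumes, and the raw CBV volume is the ratio
times an arbitrary white-matter scale so that ROI normalisation recovers
the ratios in expectation. The contralateral white-matter ROI is placed by
mirroring the tumour centre through the midline and snapping to the
nearest position whose full 5×5 footprint is white matter.

Zone means are fixture constants chosen from the membership models'
high-response ranges and ordered to respect the qualitative contrasts
(core ADC 1.50 vs WM 0.75; core FA 0.12 vs WM 0.45; core rCBV ratio 2.5
vs WM 1.0 for the high-grade spec). One property of the defaults is worth
stating plainly: the rCBV membership model peaks near a ratio of 1.1 and
is small (≈ 0.16) at the high-grade reference threshold 5.18, so no
core mean can simultaneously sit in the model's high-response range and
clear that reference threshold. The defaults follow the membership range
— the high-grade core ratio clears the low-grade threshold (2.32) but not
5.18, and the high-grade phantom's rCBV reference mask is therefore empty
by construction. Reference-delineation correctness is asserted as exact
voxel-wise threshold comparisons instead.

What the phantom does **not** emulate: partial-volume mixing at zone
boundaries, Rician noise statistics (noise is Gaussian, as a spec'd
simplification), bias fields, registration error, anatomical variability,
or infiltrative (non-ellipsoidal) tumour margins. Passing the end-to-end
recovery test (DSC ≥ 0.90, sensitivity ≥ 0.85, specificity ≥ 0.95 against
the core ∪ oedema truth over the brain universe) therefore demonstrates
internal consistency of the pipeline under known geometry and noise — not
clinical accuracy on patient data.

## Problem sizes and determinism

The test suite exercises morphology against an independent brute-force
sweep on 100 random slices up to 64×64, fusion properties on $10^5$
random voxel triples, FCM on three-plateau volumes of ~2000 voxels, and
the full pipeline on the default 128×128×20 phantom; the whole suite runs
in well under a minute. Every stochastic step — phantom noise, FCM
initialisation — is governed by an explicit integer seed, and
`run_pipeline()` echoes all resolved parameters into a YAML run log so a
run is reproducible from its log alone.

## Known limitations

* The membership coefficients are fixed population-level curves; no
  per-patient adaptation or per-grade models are provided (mixed-grade
  models are a deliberate design position, not an omission).
* Inputs must be co-registered on one grid; no registration, bias-field
  correction or skull stripping is performed.
* rCBV is consumed as a map; its computation from dynamic susceptibility
  time series (including AIF selection) is out of scope.
* The evaluation layer compares masks; it performs no statistical testing
  between methods and no inter-observer analysis.
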