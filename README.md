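# gliofuse

Automatic gross-tumour-volume (GTV) delineation for gliomas from
co-registered multi-parametric MRI, aimed at radiotherapy planning
workflows and at methodologists studying multi-modal segmentation.

Structural MRI under-represents infiltrating glioma, while the functional
maps — apparent diffusion coefficient (ADC), fractional anisotropy (FA)
and relative cerebral blood volume (rCBV) — carry complementary but
threshold-less evidence. gliofuse turns each functional map into a
voxel-wise *tumour membership* volume through a parametric fuzzy model
(`MF`), fuses the three feature spaces by the voxel-wise geometric mean

```
FS_fusion(v) = ( FS_ADC(v) · FS_FA(v) · FS_CBV(v) )^(1/3)
```

and extracts the functional tumour mask by thresholding the fused volume
at 0.6 followed by a fixed morphological cleanup (hole filling, double
erosion and dilation with a radius-3 disk, largest 8-connected region per
slice). A parallel anatomical branch segments T1C and T2 by fuzzy c-means
into three clusters with seeded region growing, and the final GTV is the
union:

```
GTV_auto = Anatomy_auto ∪ Function_auto
```

Evaluation utilities compute volume difference
ΔV(%) = |V_auto − V_manual| / V_manual × 100, Dice similarity, sensitivity
and specificity over an explicit brain universe, with tidy per-case and
mean ± SD cohort reports. A seeded synthetic multi-parametric brain
phantom exercises every stage without patient data.

## Worked example

Generate the default high-grade phantom and run the full pipeline:

```r
library(gliofuse)

mf <- canonical_membership("ADC")
mf
#> <membership_model> ADC (gaussian2) on [0, 4]
#>   a1   c1   s1   a2   c2   s2
#> 0.50 1.50 0.33 0.50 1.57 0.66
eval_membership(mf, c(0.7, 1.5, 3.0))
#> [1] 0.089372446 0.994407090 0.004572974
```

Low memberships at 0.7 (normal white-matter ADC) and 3.0 (CSF), near 1 at
the tumour-typical 1.5 × 10⁻³ mm²/s.

```r
ph <- generate_phantom(default_phantom_specs()$high_grade)
res <- run_pipeline(
  adc = ph$volumes$adc, fa = ph$volumes$fa, t1c = ph$volumes$t1c,
  t2 = ph$volumes$t2, brain = ph$brain, cbv = ph$volumes$cbv,
  wm_roi = ph$wm_roi, seed_t1c = ph$seed_t1c, seed_t2 = ph$seed_t2,
  manual = ph$truth, fcm_seed = 1L, case = "phantom")
res$metrics
#> # A tibble: 1 × 8
#>   case    v_manual_cm3 v_auto_cm3 delta_v_pct   dsc sensitivity specificity
#>   <chr>          <dbl>      <dbl>       <dbl> <dbl>       <dbl>       <dbl>
#> 1 phantom         133.       133.       0.159 0.999       0.998           1
```

The automatic GTV recovers the phantom's core ∪ oedema truth mask almost
exactly: 0.16% volume error, Dice 0.999, and no false positives over the
brain universe (specificity 1).

The shipped nine-case clinical evaluation tables reproduce their printed
cohort summary:

```r
tab <- clinical_gtv_volumes()
dv <- volume_difference_pct(tab$v_auto_cm3, tab$v_manual_cm3)
round(dv, 2)
#> [1] 19.59 10.85  8.72  7.08 14.42  2.76  6.70  6.45  1.66
aggregate_metrics(tibble::tibble(delta_v_pct = dv))
#> # A tibble: 1 × 4
#>   metric       mean    sd     n
#>   <chr>       <dbl> <dbl> <int>
#> 1 delta_v_pct  8.69  5.62     9
```

A command-line interface (`inst/cli/gliofuse`) wraps the same functions
as `run`, `segment-functional`, `segment-anatomical`, `combine`,
`evaluate`, `phantom` and `fit-mf` subcommands over NIfTI files.

See `vignettes/fuzzy-fusion-segmentation.Rmd` for the model, the
morphological conventions, the design decisions and the phantom's
limitations.

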