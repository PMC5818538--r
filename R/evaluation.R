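#' Combine anatomical and functional segmentations
#'
#' The final auto-segmented gross tumour volume is the voxel-wise union of
#' the anatomical and functional masks.
#'
#' @param anatomy,functional [binary_mask()]s on one grid.
#' @return A [binary_mask()] — `GTV_auto`.
#' @export
combine_masks <- function(anatomy, functional) {
  check_same_grid(anatomy, functional, "anatomy", "functional")
  binary_mask(vol_data(anatomy) | vol_data(functional), vol_spacing(anatomy))
}

#' Grade-specific reference thresholds
#'
#' Threshold triple used to delineate the reference tumour extent on the
#' functional maps: tumour-infiltrated tissue shows ADC *higher than*
#' `adc_min` (1e-3 mm^2/s), FA *lower than* `fa_max`, and rCBV ratio
#' *higher than* `cbv_ratio_min`. Defaults: high grade (1.24, 0.286, 5.18),
#' low grade (1.11, 0.17, 2.32).
#'
#' @param grade `"high"` or `"low"`.
#' @param adc_min,fa_max,cbv_ratio_min Optional overrides (all positive).
#' @return A `grade_thresholds` object.
#' @export
grade_thresholds <- function(grade = c("high", "low"), adc_min = NULL,
                             fa_max = NULL, cbv_ratio_min = NULL) {
  grade <- match.arg(grade)
  def <- switch(grade,
                high = c(adc_min = 1.24, fa_max = 0.286, cbv_ratio_min = 5.18),
                low = c(adc_min = 1.11, fa_max = 0.17, cbv_ratio_min = 2.32))
  out <- list(grade = grade,
              adc_min = if (is.null(adc_min)) def[["adc_min"]] else adc_min,
              fa_max = if (is.null(fa_max)) def[["fa_max"]] else fa_max,
              cbv_ratio_min = if (is.null(cbv_ratio_min)) def[["cbv_ratio_min"]]
                              else cbv_ratio_min)
  if (any(unlist(out[-1]) <= 0)) abort("Thresholds must be positive.")
  structure(out, class = "grade_thresholds")
}

#' @export
print.grade_thresholds <- function(x, ...) {
  cat(sprintf(
    "<grade_thresholds> %s grade: ADC > %g (1e-3 mm^2/s), FA < %g, rCBV ratio > %g\n",
    x$grade, x$adc_min, x$fa_max, x$cbv_ratio_min))
  invisible(x)
}

#' Threshold-based reference delineation
#'
#' Codified stand-in for manual reference delineation on the functional
#' maps: strict comparisons of each map against the grade-specific
#' thresholds, intersected with the brain mask and with an optional
#' exclusion mask removed (CSF, necrosis, vessels). The combined reference
#' is the union of the three per-modality masks.
#'
#' @param adc,fa,cbv_ratio [parametric_volume()]s on one grid (`cbv_ratio`
#'   must already be normalised, modality `"CBV_RATIO"`).
#' @param thresholds A [grade_thresholds()].
#' @param brain A [binary_mask()].
#' @param exclusion Optional [binary_mask()] of voxels to remove.
#' @return A list of [binary_mask()]s: `adc`, `fa`, `cbv`, `combined`.
#' @export
reference_delineation <- function(adc, fa, cbv_ratio, thresholds, brain,
                                  exclusion = NULL) {
  stopifnot(inherits(thresholds, "grade_thresholds"))
  check_same_grid(adc, fa, "ADC", "FA")
  check_same_grid(adc, cbv_ratio, "ADC", "CBV ratio")
  check_same_grid(adc, brain, "ADC", "brain mask")
  keep <- vol_data(brain)
  if (!is.null(exclusion)) {
    check_same_grid(adc, exclusion, "ADC", "exclusion mask")
    keep <- keep & !vol_data(exclusion)
  }
  sp <- vol_spacing(adc)
  m_adc <- (vol_data(adc) > thresholds$adc_min) & keep
  m_fa <- (vol_data(fa) < thresholds$fa_max) & keep
  m_cbv <- (vol_data(cbv_ratio) > thresholds$cbv_ratio_min) & keep
  list(adc = binary_mask(m_adc, sp),
       fa = binary_mask(m_fa, sp),
       cbv = binary_mask(m_cbv, sp),
       combined = binary_mask(m_adc | m_fa | m_cbv, sp))
}

#' Segmentation agreement metrics for one case
#'
#' Confusion-matrix metrics of an automatic mask against a manual
#' (reference) mask over an explicit evaluation universe (normally the
#' brain mask — the true-negative domain must be stated for specificity to
#' be meaningful):
#' volume difference `dV(%) = |V_auto - V_manual| / V_manual * 100`,
#' Dice `2|A n M| / (|A| + |M|)`, sensitivity `|A n M| / |M|`, and
#' specificity `TN / (TN + FP)` with `TN = |U \\ (A u M)|`,
#' `FP = |A \\ M|`. Volumes are voxel counts times voxel volume, in cm^3.
#'
#' @param auto,manual [binary_mask()]s on one grid; `manual` non-empty.
#' @param universe A [binary_mask()] containing `auto` and `manual`.
#' @param spacing Optional spacing override in mm.
#' @param case Case identifier for the report row.
#' @return A one-row tibble: `case`, `v_manual_cm3`, `v_auto_cm3`,
#'   `delta_v_pct`, `dsc`, `sensitivity`, `specificity`, `universe_voxels`.
#' @export
compute_metrics <- function(auto, manual, universe, spacing = NULL,
                            case = "case") {
  check_same_grid(auto, manual, "auto", "manual")
  check_same_grid(auto, universe, "auto", "universe")
  a <- vol_data(auto); m <- vol_data(manual); u <- vol_data(universe)
  if (!any(m)) abort("Manual mask is empty; volume difference is undefined.")
  if (any((a | m) & !u)) {
    abort("Universe must contain both masks (auto u manual).")
  }
  spacing <- if (is.null(spacing)) vol_spacing(auto) else as.numeric(spacing)
  vox_cm3 <- prod(spacing) / 1000
  tp <- sum(a & m); fp <- sum(a & !m); fn <- sum(!a & m)
  tn <- sum(u & !a & !m)
  v_auto <- sum(a) * vox_cm3
  v_manual <- sum(m) * vox_cm3
  tibble::tibble(
    case = as.character(case),
    v_manual_cm3 = v_manual,
    v_auto_cm3 = v_auto,
    delta_v_pct = abs(v_auto - v_manual) / v_manual * 100,
    dsc = 2 * tp / (2 * tp + fp + fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    universe_voxels = sum(u))
}

#' Volume difference in percent
#'
#' `dV(%) = |v_auto - v_manual| / v_manual * 100`, vectorised over cases.
#'
#' @param v_auto,v_manual Volumes (any common unit); `v_manual > 0`.
#' @return Numeric vector of percentages.
#' @export
volume_difference_pct <- function(v_auto, v_manual) {
  if (any(v_manual <= 0)) abort("`v_manual` must be positive.")
  abs(v_auto - v_manual) / v_manual * 100
}

#' Aggregate per-case metrics
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' each numeric metric across cases, mirroring a per-cohort
#' "mean +/- SD" summary row.
#'
#' @param reports A data frame of per-case rows (e.g. stacked
#'   [compute_metrics()] output); all numeric columns are summarised.
#' @return A tibble with one row per metric: `metric`, `mean`, `sd`, `n`.
#'   With a single case, `sd` is `NA` and a warning is raised.
#' @export
aggregate_metrics <- function(reports) {
  reports <- as.data.frame(reports)
  if (nrow(reports) < 1L) abort("No reports to aggregate.")
  if (nrow(reports) < 2L) {
    warn("Fewer than 2 cases: SD is undefined and reported as NA.")
  }
  num <- vapply(reports, is.numeric, logical(1))
  cols <- names(reports)[num]
  tibble::tibble(
    metric = cols,
    mean = unname(vapply(cols, function(cn) mean(reports[[cn]]),
                         numeric(1))),
    sd = unname(vapply(cols, function(cn)
      if (nrow(reports) >= 2L) stats::sd(reports[[cn]]) else NA_real_,
      numeric(1))),
    n = nrow(reports))
}

#' Shipped clinical evaluation tables
#'
#' Per-case reference/auto GTV volumes (cm^3) and per-case overlap scores
#' (Dice, sensitivity, specificity) from a published nine-patient glioma
#' evaluation cohort, shipped as plain-text fixtures so the aggregate
#' statistics can be recomputed.
#'
#' @return A tibble.
#' @export
clinical_gtv_volumes <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "clinical_gtv_volumes.csv", package = "gliofuse")))
}

#' @rdname clinical_gtv_volumes
#' @export
clinical_overlap_scores <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "clinical_overlap_scores.csv",
                package = "gliofuse")))
}
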