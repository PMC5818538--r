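#' Normalise a CBV volume to contralateral white matter
#'
#' Divides every voxel by the mean CBV over a small square ROI placed in
#' contralateral normal-appearing white matter, turning arbitrary scanner
#' units into the rCBV ratio used by the membership model and the reference
#' thresholds.
#'
#' @param cbv A [parametric_volume()] with modality `"CBV"`.
#' @param wm_roi A [roi_spec()] (default size 25 = 5x5 pixels).
#' @return A [parametric_volume()] with modality `"CBV_RATIO"`.
#' @export
compute_rcbv_ratio <- function(cbv, wm_roi) {
  stopifnot(inherits(cbv, "parametric_volume"), inherits(wm_roi, "roi_spec"))
  if (cbv$modality != "CBV") {
    abort(sprintf("Expected a CBV volume; got %s.", cbv$modality))
  }
  ix <- roi_indices(wm_roi, dim(cbv$data))
  m <- mean(cbv$data[ix$rows, ix$cols, ix$slice])
  if (!is.finite(m) || m <= 0) {
    abort(sprintf("Degenerate white-matter normaliser: ROI mean = %g.", m))
  }
  parametric_volume(cbv$data / m, "CBV_RATIO", cbv$spacing)
}

#' Fuse three fuzzy feature spaces by geometric mean
#'
#' The fused membership of each voxel is the cube root of the product of
#' its ADC, FA and rCBV memberships — a compromise operator that is zero
#' whenever any one modality rules the voxel out, and bounded between the
#' componentwise minimum and maximum.
#'
#' @param fs_adc,fs_fa,fs_cbv [fuzzy_volume()]s on one grid.
#' @return A [fuzzy_volume()] with source `"FS_FUSION"`.
#' @export
fuse <- function(fs_adc, fs_fa, fs_cbv) {
  stopifnot(inherits(fs_adc, "fuzzy_volume"), inherits(fs_fa, "fuzzy_volume"),
            inherits(fs_cbv, "fuzzy_volume"))
  check_same_grid(fs_adc, fs_fa, "ADC feature", "FA feature")
  check_same_grid(fs_adc, fs_cbv, "ADC feature", "CBV feature")
  fused <- (fs_adc$data * fs_fa$data * fs_cbv$data)^(1 / 3)
  fuzzy_volume(pmin(pmax(fused, 0), 1), "FS_FUSION", vol_spacing(fs_adc))
}

#' Segment the fused fuzzy feature volume
#'
#' Voxels with fused membership at or above `threshold` inside the operator
#' limit mask are extracted, then each axial slice is cleaned in a fixed
#' order: (1) fill holes against a 4-connected background, (2) erode twice
#' with the flat radius-3 disk, (3) dilate twice with the same disk,
#' (4) keep the largest 8-connected region. With
#' `largest_component = "volume"` step (4) instead keeps the single largest
#' 26-connected component of the stacked volume.
#'
#' @param fusion A [fuzzy_volume()] with source `"FS_FUSION"`.
#' @param limit A [binary_mask()] restricting the thresholding (stands in
#'   for the operator's manually limited area; default the brain mask).
#' @param threshold Membership threshold in (0, 1); the comparison is
#'   inclusive (`>= threshold`). Default 0.6.
#' @param largest_component `"slice"` (default) or `"volume"`.
#' @return A [binary_mask()] — the functional tumour segmentation.
#' @export
segment_functional <- function(fusion, limit, threshold = 0.6,
                               largest_component = c("slice", "volume")) {
  stopifnot(inherits(fusion, "fuzzy_volume"))
  largest_component <- match.arg(largest_component)
  check_same_grid(fusion, limit, "fusion", "limit mask")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie in (0, 1).")
  }
  lim <- vol_data(limit)
  if (!any(lim)) {
    warn("Limit mask is empty; returning an empty segmentation.")
    return(binary_mask(array(FALSE, dim(fusion$data)), vol_spacing(fusion)))
  }
  bin <- fusion$data >= threshold & lim
  kern <- disk_kernel(3)
  per_slice_largest <- largest_component == "slice"
  out <- array(FALSE, dim(bin))
  for (s in seq_len(dim(bin)[3])) {
    sl <- bin[, , s]
    if (!any(sl)) next
    out[, , s] <- cleanup_slice_functional(sl, kern,
                                           keep_largest = per_slice_largest)
  }
  if (!per_slice_largest && any(out)) {
    out <- largest_component3d(out)
  }
  binary_mask(out, vol_spacing(fusion))
}

largest_component3d <- function(x) largest_component(x, 26)
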