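#' @importFrom rlang abort warn inform
NULL

MODALITIES <- c("ADC", "FA", "CBV", "CBV_RATIO", "T1C", "T2")

#' Parametric MR volume
#'
#' Container for one modality's 3-D scalar field on the shared voxel grid.
#' Axial slices lie along the third array axis; voxel indices are 1-based in
#' R code (the CLI accepts 0-based indices and converts). ADC values are
#' carried in units of 1e-3 mm^2/s throughout, FA is dimensionless in
#' \[0, 1\], and CBV is either in arbitrary scanner units (`"CBV"`) or
#' normalised to contralateral white matter (`"CBV_RATIO"`).
#'
#' @param data Numeric 3-D array.
#' @param modality One of `"ADC"`, `"FA"`, `"CBV"`, `"CBV_RATIO"`, `"T1C"`,
#'   `"T2"`.
#' @param spacing Numeric length-3 voxel spacing `(dx, dy, dz)` in mm.
#' @return A `parametric_volume` object.
#' @export
parametric_volume <- function(data, modality, spacing = c(1, 1, 1)) {
  modality <- match.arg(modality, MODALITIES)
  data <- as_volume_array(data)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive finite numbers (mm).")
  }
  structure(
    list(data = data, modality = modality, spacing = spacing),
    class = "parametric_volume"
  )
}

#' Binary segmentation mask
#'
#' A region on the shared voxel grid, stored as a logical 3-D array.
#'
#' @param data Logical (or 0/1 numeric) 3-D array.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1)) {
  data <- as_volume_array(data)
  if (is.numeric(data)) {
    bad <- !(data %in% c(0, 1))
    if (any(bad)) abort("Mask values must be 0/1 or logical.")
  }
  arr <- array(as.logical(data), dim = dim(data))
  spacing <- as.numeric(spacing)
  structure(list(data = arr, spacing = spacing), class = "binary_mask")
}

#' Fuzzy feature volume
#'
#' Voxel-wise tumour memberships in \[0, 1\] derived from one parametric
#' volume (or from fusion of several).
#'
#' @param data Numeric 3-D array with values in \[0, 1\].
#' @param source One of `"FS_ADC"`, `"FS_FA"`, `"FS_CBV"`, `"FS_FUSION"`.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return A `fuzzy_volume` object.
#' @export
fuzzy_volume <- function(data, source = c("FS_ADC", "FS_FA", "FS_CBV", "FS_FUSION"),
                         spacing = c(1, 1, 1)) {
  source <- match.arg(source)
  data <- as_volume_array(data)
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 1) {
    abort(sprintf("Membership values must lie in [0, 1]; got range [%g, %g].",
                  rng[1], rng[2]))
  }
  structure(list(data = data, source = source, spacing = as.numeric(spacing)),
            class = "fuzzy_volume")
}

#' Square ROI specification on one axial slice
#'
#' Describes the small region used to sample contralateral normal white
#' matter, realised as an odd-sided square centred on a voxel (the default
#' 25 pixels is a 5x5 square).
#'
#' @param slice 1-based axial slice index.
#' @param center Length-2 integer `(row, col)` voxel index of the ROI centre.
#' @param size Pixel count; must be an odd perfect square (1, 9, 25, ...).
#' @return A `roi_spec` object.
#' @export
roi_spec <- function(slice, center, size = 25) {
  side <- sqrt(size)
  if (size < 1 || side != floor(side) || side %% 2 != 1) {
    abort("`size` must be an odd-sided square pixel count (1, 9, 25, ...).")
  }
  structure(list(slice = as.integer(slice),
                 center = as.integer(center),
                 size = as.integer(size)),
            class = "roi_spec")
}

roi_indices <- function(roi, dims) {
  half <- (sqrt(roi$size) - 1) / 2
  rows <- (roi$center[1] - half):(roi$center[1] + half)
  cols <- (roi$center[2] - half):(roi$center[2] + half)
  if (min(rows) < 1 || max(rows) > dims[1] ||
      min(cols) < 1 || max(cols) > dims[2] ||
      roi$slice < 1 || roi$slice > dims[3]) {
    abort(sprintf(
      "ROI (slice %d, rows %d:%d, cols %d:%d) exceeds volume bounds %s.",
      roi$slice, min(rows), max(rows), min(cols), max(cols),
      paste(dims, collapse = "x")))
  }
  list(rows = rows, cols = cols, slice = roi$slice)
}

as_volume_array <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort("Volume data must be a 3-D array (or a matrix, taken as one slice).")
  }
  x
}

vol_data <- function(x) {
  if (inherits(x, c("parametric_volume", "binary_mask", "fuzzy_volume"))) {
    x$data
  } else {
    as_volume_array(x)
  }
}

vol_spacing <- function(x, default = c(1, 1, 1)) {
  if (is.list(x) && !is.null(x$spacing)) x$spacing else default
}

#' @export
print.parametric_volume <- function(x, ...) {
  cat(sprintf("<parametric_volume> %s  %s voxels  spacing %s mm\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' @export
print.fuzzy_volume <- function(x, ...) {
  cat(sprintf("<fuzzy_volume> %s  %s voxels  range [%.3f, %.3f]\n",
              x$source, paste(dim(x$data), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

# Grid compatibility: identical shape, spacing within 1e-3 mm.
check_same_grid <- function(a, b, what_a = "first", what_b = "second") {
  da <- dim(vol_data(a)); db <- dim(vol_data(b))
  if (!identical(da, db)) {
    abort(sprintf("Grid mismatch: %s volume is %s but %s volume is %s.",
                  what_a, paste(da, collapse = "x"),
                  what_b, paste(db, collapse = "x")))
  }
  sa <- vol_spacing(a); sb <- vol_spacing(b)
  if (max(abs(sa - sb)) > 1e-3) {
    abort(sprintf("Spacing mismatch: %s vs %s mm.",
                  paste(sa, collapse = "x"), paste(sb, collapse = "x")))
  }
  invisible(TRUE)
}

#' Volume of a mask in cubic centimetres
#'
#' @param mask A [binary_mask()].
#' @param spacing Optional spacing override in mm.
#' @return Volume in cm^3.
#' @export
mask_volume_cm3 <- function(mask, spacing = NULL) {
  spacing <- if (is.null(spacing)) vol_spacing(mask) else as.numeric(spacing)
  sum(vol_data(mask)) * prod(spacing) / 1000
}
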