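PHANTOM_ZONES <- c("background", "white_matter", "grey_matter", "csf",
                   "oedema", "core")
PHANTOM_MODALITIES <- c("adc", "fa", "cbv_ratio", "t1c", "t2")

#' Synthetic multi-parametric brain phantom specification
#'
#' Describes a seeded, fully synthetic co-registered multi-parametric
#' study: an ellipsoidal brain with a white-matter interior, a grey-matter
#' shell and a small ventricular CSF pocket, plus an ellipsoidal tumour
#' core surrounded by an oedema margin. Each zone carries a mean and SD for
#' each of ADC (1e-3 mm^2/s), FA, rCBV ratio, T1C and T2 intensity; voxel
#' values are `zone mean + noise_level * zone SD * N(0, 1)` so
#' `noise_level = 0` yields exactly zone-constant volumes. The rCBV volume
#' is produced in arbitrary units (`ratio * wm_scale`) so that dividing by
#' the white-matter ROI mean recovers the specified ratios in expectation.
#'
#' Zone means are fixture constants chosen from the membership models'
#' high-response ranges and ordered to respect the qualitative contrasts of
#' glioma imaging (tumour ADC above white matter, tumour FA below white
#' matter, tumour rCBV ratio above white matter); they are synthetic, not
#' measurements.
#'
#' @param shape Grid dimensions `(rows, cols, slices)`.
#' @param spacing Voxel spacing in mm.
#' @param core_center,core_radii Tumour-core ellipsoid centre and radii in
#'   voxels (1-based centre; radii >= 2).
#' @param oedema_margin Oedema margin added to the core radii, in voxels
#'   per axis (scalar or length 3).
#' @param tissue Data frame of zone parameters: columns `zone`, then
#'   `<modality>_mean` and `<modality>_sd` for each of `adc`, `fa`,
#'   `cbv_ratio`, `t1c`, `t2`. Defaults come with the grade-specific specs.
#' @param noise_level Non-negative scalar multiplying every zone SD.
#' @param wm_scale Arbitrary-unit scale of the raw CBV volume.
#' @param seed Integer seed making generation deterministic.
#' @param grade `"high"` or `"low"`, recorded for threshold selection.
#' @return A `phantom_spec` object.
#' @seealso [generate_phantom()], [default_phantom_specs()]
#' @export
phantom_spec <- function(shape = c(128, 128, 20),
                         spacing = c(1.875, 1.875, 6),
                         core_center = c(44, 64, 10),
                         core_radii = c(14, 11, 3),
                         oedema_margin = c(5, 5, 2),
                         tissue = NULL,
                         noise_level = 1,
                         wm_scale = 120,
                         seed = 1L,
                         grade = c("high", "low")) {
  grade <- match.arg(grade)
  shape <- as.integer(shape)
  if (length(oedema_margin) == 1L) oedema_margin <- rep(oedema_margin, 3L)
  if (is.null(tissue)) tissue <- default_tissue_table(grade)
  stopifnot(length(shape) == 3L, all(shape >= 8L))
  if (any(core_radii < 2)) abort("Core radii must be >= 2 voxels.")
  outer_radii <- core_radii + oedema_margin
  if (any(core_center - outer_radii < 1) ||
      any(core_center + outer_radii > shape)) {
    abort("Tumour (core + oedema) exceeds the grid.")
  }
  tissue <- validate_tissue_table(tissue)
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 core_center = as.numeric(core_center),
                 core_radii = as.numeric(core_radii),
                 oedema_margin = as.numeric(oedema_margin),
                 tissue = tissue, noise_level = noise_level,
                 wm_scale = wm_scale, seed = as.integer(seed),
                 grade = grade),
            class = "phantom_spec")
}

default_tissue_table <- function(grade) {
  t_high <- tibble::tribble(
    ~zone,          ~adc_mean, ~adc_sd, ~fa_mean, ~fa_sd, ~cbv_ratio_mean,
    ~cbv_ratio_sd, ~t1c_mean, ~t1c_sd, ~t2_mean, ~t2_sd,
    "background",   0,    0,    0,    0,    0,    0,    0,   0,  0,   0,
    "white_matter", 0.75, 0.05, 0.45, 0.04, 1.0,  0.10, 300, 20, 300, 20,
    "grey_matter",  0.85, 0.05, 0.25, 0.04, 1.6,  0.15, 350, 20, 350, 20,
    "csf",          3.00, 0.10, 0.05, 0.02, 0.30, 0.05, 100, 15, 850, 30,
    "oedema",       1.35, 0.06, 0.20, 0.03, 1.8,  0.15, 320, 20, 780, 30,
    "core",         1.50, 0.06, 0.12, 0.03, 2.5,  0.20, 800, 40, 750, 30)
  if (grade == "high") return(t_high)
  t_low <- t_high
  t_low[t_low$zone == "core",
        c("adc_mean", "fa_mean", "cbv_ratio_mean", "t1c_mean")] <-
    list(1.30, 0.15, 2.4, 650)
  t_low[t_low$zone == "oedema", c("adc_mean", "fa_mean", "cbv_ratio_mean")] <-
    list(1.20, 0.16, 1.6)
  t_low
}

validate_tissue_table <- function(tissue) {
  tissue <- tibble::as_tibble(tissue)
  need <- c("zone", paste0(rep(PHANTOM_MODALITIES, each = 2),
                           c("_mean", "_sd")))
  if (!all(need %in% names(tissue))) {
    abort(sprintf("Tissue table must have columns: %s.",
                  paste(need, collapse = ", ")))
  }
  if (!setequal(tissue$zone, PHANTOM_ZONES)) {
    abort(sprintf("Tissue table zones must be exactly: %s.",
                  paste(PHANTOM_ZONES, collapse = ", ")))
  }
  row <- function(z) tissue[tissue$zone == z, ]
  # qualitative glioma contrasts: bright in ADC and rCBV, dark in FA
  if (!(row("core")$adc_mean > row("white_matter")$adc_mean &&
        row("core")$fa_mean < row("white_matter")$fa_mean &&
        row("core")$cbv_ratio_mean > row("white_matter")$cbv_ratio_mean)) {
    abort(paste("Zone means must respect tumour contrasts: core ADC and",
                "rCBV ratio above white matter, core FA below white matter."))
  }
  if (any(tissue[paste0(PHANTOM_MODALITIES, "_sd")] < 0)) {
    abort("Zone SDs must be >= 0.")
  }
  tissue
}

#' Grade-specific default phantom specifications
#'
#' @return A list with elements `high_grade` and `low_grade`, each a
#'   [phantom_spec()].
#' @export
default_phantom_specs <- function() {
  list(high_grade = phantom_spec(grade = "high"),
       low_grade = phantom_spec(grade = "low"))
}

# Closest in-slice centre whose (2*half+1)^2 footprint is all white matter.
find_wm_roi_center <- function(zones, slice, target, half = 2L) {
  dims <- dim(zones)
  wm <- zones[, , slice] == 1L
  ok <- wm
  for (dr in -half:half) for (dc in -half:half) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(FALSE, dims[1], dims[2])
    rs <- seq_len(dims[1]) - dr; cs <- seq_len(dims[2]) - dc
    okr <- rs >= 1 & rs <= dims[1]; okc <- cs >= 1 & cs <= dims[2]
    sh[which(okr), which(okc)] <- wm[rs[okr], cs[okc]]
    ok <- ok & sh
  }
  cand <- which(ok, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    abort("No white-matter position can host the 5x5 normalisation ROI.")
  }
  d2 <- (cand[, 1] - target[1])^2 + (cand[, 2] - target[2])^2
  as.integer(cand[which.min(d2), ])
}

ellipsoid_mask <- function(shape, center, radii) {
  r <- seq_len(shape[1]); c <- seq_len(shape[2]); s <- seq_len(shape[3])
  dr <- ((r - center[1]) / radii[1])^2
  dc <- ((c - center[2]) / radii[2])^2
  ds <- ((s - center[3]) / radii[3])^2
  outer(outer(dr, dc, `+`), ds, `+`) <= 1
}

#' Generate a synthetic multi-parametric study
#'
#' Deterministically (per `spec$seed`) realises the phantom: zone geometry,
#' per-voxel Gaussian variation, the five co-registered volumes, the brain
#' mask, ground-truth masks and the bookkeeping needed to run the full
#' pipeline (contralateral white-matter ROI, region-growing seeds).
#'
#' @param spec A [phantom_spec()].
#' @return A list: `volumes` (named [parametric_volume()]s `adc`, `fa`,
#'   `cbv` (arbitrary units), `cbv_ratio` (noise-free expectation is the
#'   tissue-table ratio), `t1c`, `t2`), `brain` mask, `truth_core`,
#'   `truth` (core + oedema), `zones` (integer zone label array),
#'   `wm_roi` ([roi_spec()]), `seed_t1c`/`seed_t2` (voxel triples), and the
#'   echoed `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  brain_center <- c(shape[1] / 2, shape[2] / 2, (shape[3] + 1) / 2)
  brain_radii <- c(0.81 * shape[1] / 2, 0.69 * shape[2] / 2,
                   max(2, shape[3] / 2 - 2))
  brain <- ellipsoid_mask(shape, brain_center, brain_radii)
  wm_inner <- ellipsoid_mask(shape, brain_center,
                             brain_radii - c(5, 5, 1))
  csf_center <- c(brain_center[1] + 6, brain_center[2], brain_center[3])
  csf <- ellipsoid_mask(shape, csf_center, c(6, 5, 2)) & wm_inner
  core <- ellipsoid_mask(shape, spec$core_center, spec$core_radii)
  outer_t <- ellipsoid_mask(shape, spec$core_center,
                            spec$core_radii + spec$oedema_margin)
  core <- core & brain
  oedema <- outer_t & brain & !core
  # zone priority: core > oedema > csf > grey shell > white matter
  zones <- array(0L, shape)
  zones[brain] <- 2L                    # grey-matter shell by default
  zones[wm_inner] <- 1L                 # white matter interior
  zones[csf] <- 3L
  zones[oedema] <- 4L
  zones[core] <- 5L
  set.seed(spec$seed)
  # tissue rows ordered so row i+1 corresponds to zone code i
  tissue <- spec$tissue[match(PHANTOM_ZONES, spec$tissue$zone), ]
  make_vol <- function(modality) {
    mu <- tissue[[paste0(modality, "_mean")]][zones + 1L]
    sdv <- tissue[[paste0(modality, "_sd")]][zones + 1L]
    v <- mu + spec$noise_level * sdv * stats::rnorm(length(mu))
    array(v, shape)
  }
  adc <- pmax(make_vol("adc"), 0)
  fa <- pmin(pmax(make_vol("fa"), 0), 1)
  ratio <- pmax(make_vol("cbv_ratio"), 0)
  t1c <- pmax(make_vol("t1c"), 0)
  t2 <- pmax(make_vol("t2"), 0)

  # Contralateral white-matter ROI: mirror the tumour centre through the
  # midline, then snap to the nearest position whose full 5x5 footprint is
  # white matter (the mirrored point can fall in CSF on small grids).
  target <- c(round(2 * brain_center[1] - spec$core_center[1]),
              round(brain_center[2]))
  roi_slice <- round(spec$core_center[3])
  wm_center <- find_wm_roi_center(zones, roi_slice, target, half = 2L)
  wm_roi <- roi_spec(slice = roi_slice, center = wm_center, size = 25)
  seedv <- round(spec$core_center)

  sp <- spec$spacing
  list(
    volumes = list(
      adc = parametric_volume(adc, "ADC", sp),
      fa = parametric_volume(fa, "FA", sp),
      cbv = parametric_volume(ratio * spec$wm_scale, "CBV", sp),
      cbv_ratio = parametric_volume(ratio, "CBV_RATIO", sp),
      t1c = parametric_volume(t1c, "T1C", sp),
      t2 = parametric_volume(t2, "T2", sp)),
    brain = binary_mask(brain, sp),
    truth_core = binary_mask(core, sp),
    truth = binary_mask(core | oedema, sp),
    zones = zones,
    wm_roi = wm_roi,
    seed_t1c = seedv,
    seed_t2 = seedv,
    spec = spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %s grade, grid %s, core radii (%s) + margin (%s) voxels, noise %g, seed %d\n",
    x$grade, paste(x$shape, collapse = "x"),
    paste(x$core_radii, collapse = ","),
    paste(x$oedema_margin, collapse = ","), x$noise_level, x$seed))
  invisible(x)
}
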