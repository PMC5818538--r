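#' Read and write volumes and masks as NIfTI
#'
#' Thin wrappers over RNifti. Spacing is taken from (and written to) the
#' NIfTI header's pixdim; masks are stored as 0/1 and read back exactly,
#' while floating-point volumes round-trip within single-precision
#' tolerance when `datatype = "float"`.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param modality Modality recorded on the returned [parametric_volume()].
#' @param reference Optional volume/mask whose grid the file must match
#'   (shape identical, spacing within 1e-3 mm).
#' @return `read_volume()` a [parametric_volume()]; `read_mask()` a
#'   [binary_mask()]; the writers return `path` invisibly.
#' @export
read_volume <- function(path, modality, reference = NULL) {
  if (!file.exists(path)) abort(sprintf("No such volume file: %s", path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  sp <- RNifti::pixdim(img)[1:3]
  vol <- parametric_volume(arr, modality, sp)
  if (!is.null(reference)) check_same_grid(vol, reference, path, "reference")
  vol
}

#' @rdname read_volume
#' @param vol A [parametric_volume()].
#' @param datatype NIfTI storage type for volumes (default `"float"`).
#' @export
write_volume <- function(vol, path, datatype = "float") {
  stopifnot(inherits(vol, "parametric_volume"))
  img <- RNifti::asNifti(vol$data, internal = FALSE)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path, reference = NULL) {
  if (!file.exists(path)) abort(sprintf("No such mask file: %s", path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (!all(arr %in% c(0, 1))) {
    abort(sprintf("Mask file %s contains values other than 0/1.", path))
  }
  m <- binary_mask(arr, RNifti::pixdim(img)[1:3])
  if (!is.null(reference)) check_same_grid(m, reference, path, "reference")
  m
}

#' @rdname read_volume
#' @param mask A [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)),
                         internal = FALSE)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a pipeline configuration
#'
#' YAML document holding input paths, thresholds, FCM settings,
#' connectivity switches, grade, white-matter ROI, seeds and the output
#' directory; defaults are filled for absent fields and the fully resolved
#' configuration is echoed into the run log so no default is ambiguous.
#'
#' @param path YAML file.
#' @return A named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such config file: %s", path))
  cfg <- yaml::read_yaml(path)
  defaults <- list(threshold = 0.6, largest_component = "slice",
                   growth = "volume", grade = "high",
                   fcm = list(k = 3, fuzzifier = 2, tol = 1e-5,
                              max_iter = 300),
                   seed = 1L, log_level = "info")
  utils::modifyList(defaults, cfg)
}

#' Run the full segmentation pipeline
#'
#' Executes both branches on in-memory inputs and combines them: the
#' functional branch (membership transform of ADC/FA/rCBV-ratio, geometric
#' mean fusion, thresholding and morphological cleanup) and the anatomical
#' branch (fuzzy c-means on T1C and T2 with seeded region growing), with
#' the final GTV their union. When a manual reference mask is supplied the
#' agreement metrics are computed over the brain universe.
#'
#' @param adc,fa,t1c,t2 [parametric_volume()]s on one grid.
#' @param cbv A `"CBV"` volume in arbitrary units (normalised internally
#'   with `wm_roi`), or `NULL` if `cbv_ratio` is given directly.
#' @param cbv_ratio Optional pre-normalised `"CBV_RATIO"` volume.
#' @param brain Brain [binary_mask()].
#' @param wm_roi [roi_spec()] for rCBV normalisation (required with `cbv`).
#' @param seed_t1c,seed_t2 Region-growing seeds `(row, col, slice)`.
#' @param limit Optional operator limit mask for the functional
#'   thresholding; defaults to the brain mask.
#' @param manual Optional reference [binary_mask()] for evaluation.
#' @param models Named list of membership models (`adc`, `fa`, `cbv`);
#'   defaults to the canonical models.
#' @param threshold Fusion threshold (default 0.6).
#' @param largest_component Functional cleanup largest-component mode.
#' @param growth Anatomical region-growing connectivity.
#' @param fcm_seed,fcm_k,fcm_fuzzifier,fcm_tol,fcm_max_iter FCM settings.
#' @param case Case label used in the metrics row.
#' @return A list: masks `functional`, `anatomical`, `gtv`; fuzzy volumes
#'   `features` and `fusion`; `metrics` (tibble or `NULL`); `parameters`
#'   (fully resolved settings for the run log).
#' @export
run_pipeline <- function(adc, fa, t1c, t2, brain,
                         cbv = NULL, cbv_ratio = NULL, wm_roi = NULL,
                         seed_t1c, seed_t2, limit = NULL, manual = NULL,
                         models = NULL, threshold = 0.6,
                         largest_component = c("slice", "volume"),
                         growth = c("volume", "slice"),
                         fcm_seed = 1L, fcm_k = 3, fcm_fuzzifier = 2.0,
                         fcm_tol = 1e-5, fcm_max_iter = 300,
                         case = "case") {
  largest_component <- match.arg(largest_component)
  growth <- match.arg(growth)
  if (is.null(cbv_ratio)) {
    if (is.null(cbv) || is.null(wm_roi)) {
      abort("Provide either `cbv_ratio`, or `cbv` together with `wm_roi`.")
    }
    cbv_ratio <- compute_rcbv_ratio(cbv, wm_roi)
  }
  if (is.null(limit)) limit <- brain
  if (is.null(models)) {
    models <- list(adc = canonical_membership("ADC"),
                   fa = canonical_membership("FA"),
                   cbv = canonical_membership("CBV_RATIO"))
  }
  fs_adc <- eval_membership_volume(models$adc, adc, brain)
  fs_fa <- eval_membership_volume(models$fa, fa, brain)
  fs_cbv <- eval_membership_volume(models$cbv, cbv_ratio, brain)
  fusion <- fuse(fs_adc, fs_fa, fs_cbv)
  functional <- segment_functional(fusion, limit, threshold,
                                   largest_component)
  anatomical <- segment_anatomical(t1c, t2, brain, seed_t1c, seed_t2,
                                   k = fcm_k, fuzzifier = fcm_fuzzifier,
                                   tol = fcm_tol, max_iter = fcm_max_iter,
                                   seed = fcm_seed, growth = growth)
  gtv <- combine_masks(anatomical, functional)
  metrics <- if (!is.null(manual)) {
    compute_metrics(gtv, manual, brain, case = case)
  }
  list(functional = functional, anatomical = anatomical, gtv = gtv,
       features = list(adc = fs_adc, fa = fs_fa, cbv = fs_cbv),
       fusion = fusion, metrics = metrics,
       parameters = list(threshold = threshold,
                         largest_component = largest_component,
                         growth = growth, fcm_seed = fcm_seed, fcm_k = fcm_k,
                         fcm_fuzzifier = fcm_fuzzifier, fcm_tol = fcm_tol,
                         fcm_max_iter = fcm_max_iter,
                         models = lapply(models, function(m)
                           unname(m$coefficients))))
}

#' Write a machine-readable run log
#'
#' Serialises the fully resolved parameter set of a [run_pipeline()] result
#' to YAML so every run is reproducible from its log.
#'
#' @param result A [run_pipeline()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(result, path) {
  yaml::write_yaml(c(result$parameters,
                     list(package_version =
                            as.character(utils::packageVersion("gliofuse")))),
                   path)
  invisible(path)
}
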