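#' Tumour membership model for one functional modality
#'
#' A membership model maps a parametric value (ADC in 1e-3 mm^2/s, FA, or
#' rCBV ratio) to the possibility, in \[0, 1\], that the voxel belongs to
#' tumour. Two functional forms are supported:
#'
#' * `gaussian2` — a sum of two Gaussians,
#'   `a1*exp(-((v-c1)/s1)^2) + a2*exp(-((v-c2)/s2)^2)`,
#'   with coefficients `(a1, c1, s1, a2, c2, s2)`;
#' * `sigmoid_diff` — a scaled difference of two logistic sigmoids,
#'   `scale*(1/(1+exp(-k1*(v-x1))) - 1/(1+exp(-k2*(v-x2))))`,
#'   with coefficients `(scale, k1, x1, k2, x2)`.
#'
#' Evaluations are clamped to \[0, 1\]: the scale factors of the canonical
#' FA and rCBV models could exceed 1 for non-canonical coefficients, and a
#' membership must be a valid possibility.
#'
#' @param modality One of `"ADC"`, `"FA"`, `"CBV_RATIO"`.
#' @param form `"gaussian2"` or `"sigmoid_diff"`.
#' @param coefficients Named or ordered numeric vector; length 6 for
#'   `gaussian2`, 5 for `sigmoid_diff`. Widths (`s1`, `s2`) and slopes
#'   (`k1`, `k2`) must be positive.
#' @param domain Closed interval of valid parametric values; evaluation
#'   outside it is permitted (the formulas are defined everywhere) but noted.
#' @return A `membership_model` object.
#' @seealso [eval_membership()], [canonical_membership()], [fit_membership()]
#' @export
membership_model <- function(modality = c("ADC", "FA", "CBV_RATIO"),
                             form = c("gaussian2", "sigmoid_diff"),
                             coefficients, domain) {
  modality <- match.arg(modality)
  form <- match.arg(form)
  nm <- coef_names(form)
  if (length(coefficients) != length(nm)) {
    abort(sprintf("`%s` form needs %d coefficients (%s); got %d.",
                  form, length(nm), paste(nm, collapse = ", "),
                  length(coefficients)))
  }
  coefficients <- stats::setNames(as.numeric(coefficients), nm)
  if (form == "gaussian2" &&
      (coefficients["s1"] <= 0 || coefficients["s2"] <= 0)) {
    abort("Gaussian widths s1, s2 must be positive.")
  }
  if (form == "sigmoid_diff" &&
      (coefficients["k1"] <= 0 || coefficients["k2"] <= 0)) {
    abort("Sigmoid slopes k1, k2 must be positive.")
  }
  domain <- as.numeric(domain)
  if (length(domain) != 2L || !all(is.finite(domain)) || domain[1] >= domain[2]) {
    abort("`domain` must be a finite interval c(lo, hi) with lo < hi.")
  }
  structure(list(modality = modality, form = form,
                 coefficients = coefficients, domain = domain),
            class = "membership_model")
}

coef_names <- function(form) {
  switch(form,
         gaussian2 = c("a1", "c1", "s1", "a2", "c2", "s2"),
         sigmoid_diff = c("scale", "k1", "x1", "k2", "x2"))
}

# Raw (unclamped) closed-form evaluation.
mf_raw <- function(model, v) {
  co <- model$coefficients
  switch(model$form,
    gaussian2 =
      co[["a1"]] * exp(-((v - co[["c1"]]) / co[["s1"]])^2) +
      co[["a2"]] * exp(-((v - co[["c2"]]) / co[["s2"]])^2),
    sigmoid_diff =
      co[["scale"]] * (1 / (1 + exp(-co[["k1"]] * (v - co[["x1"]]))) -
                       1 / (1 + exp(-co[["k2"]] * (v - co[["x2"]])))))
}

#' Evaluate a membership model
#'
#' Closed-form evaluation of the model at one or more parametric values,
#' clamped to \[0, 1\]. Values outside the model's stated domain are still
#' evaluated (the forms are defined on the whole real line) but a note is
#' emitted, since the model was not calibrated there.
#'
#' @param model A [membership_model()].
#' @param value Finite numeric vector of parametric values.
#' @return Numeric vector of memberships in \[0, 1\].
#' @examples
#' mf <- canonical_membership("ADC")
#' eval_membership(mf, 1.5)
#' @export
eval_membership <- function(model, value) {
  stopifnot(inherits(model, "membership_model"))
  if (!is.numeric(value) || any(!is.finite(value))) {
    abort("`value` must be finite numeric (no NA/NaN/Inf).")
  }
  n_out <- sum(value < model$domain[1] | value > model$domain[2])
  if (n_out > 0) {
    inform(sprintf(
      "%d value(s) outside the %s model domain [%g, %g]; evaluated anyway.",
      n_out, model$modality, model$domain[1], model$domain[2]))
  }
  pmin(pmax(mf_raw(model, value), 0), 1)
}

#' Canonical membership models
#'
#' The three shipped tumour-membership models for ADC (sum of two Gaussians
#' centred at 1.5 and 1.57 x 1e-3 mm^2/s), FA (scaled sigmoid difference
#' rising near 0.06 and falling near 0.27) and rCBV ratio (two Gaussians
#' centred at 1.1 and 2.68). These are read from the package's plain-text
#' fixtures.
#'
#' @param modality `"ADC"`, `"FA"`, or `"CBV_RATIO"`.
#' @return A [membership_model()].
#' @export
canonical_membership <- function(modality = c("ADC", "FA", "CBV_RATIO")) {
  modality <- match.arg(modality)
  file <- system.file("extdata",
                      paste0("mf_", tolower(modality), ".txt"),
                      package = "gliofuse")
  if (!nzchar(file)) abort("Canonical model fixture not found.")
  read_membership_model(file)
}

#' Transform a parametric volume into a fuzzy feature space
#'
#' Applies [eval_membership()] voxel-wise inside a mask; voxels outside the
#' mask get membership 0.
#'
#' @param model A [membership_model()] matching the volume's modality.
#' @param vol A [parametric_volume()].
#' @param mask A [binary_mask()] on the same grid.
#' @return A [fuzzy_volume()] whose `source` matches the modality.
#' @export
eval_membership_volume <- function(model, vol, mask) {
  stopifnot(inherits(model, "membership_model"),
            inherits(vol, "parametric_volume"))
  check_same_grid(vol, mask, "parametric", "mask")
  out <- array(0, dim = dim(vol$data))
  inside <- vol_data(mask)
  if (any(inside)) {
    out[inside] <- eval_membership(model, vol$data[inside])
  }
  src <- switch(model$modality, ADC = "FS_ADC", FA = "FS_FA",
                CBV_RATIO = "FS_CBV")
  fuzzy_volume(out, source = src, spacing = vol$spacing)
}

#' Write / read a membership model as plain text
#'
#' Key-value serialization (`modality`, `form`, `coefficients`, `domain`).
#' Coefficients are written with 17 significant digits so the round trip is
#' bit-identical for doubles.
#'
#' @param model A [membership_model()].
#' @param path File path.
#' @return `write_membership_model()` returns `path` invisibly;
#'   `read_membership_model()` returns a [membership_model()].
#' @export
write_membership_model <- function(model, path) {
  stopifnot(inherits(model, "membership_model"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c(
    paste0("modality: ", model$modality),
    paste0("form: ", model$form),
    paste0("coefficients: ", num(model$coefficients)),
    paste0("domain: ", num(model$domain)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_membership_model
#' @export
read_membership_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such model file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":\\s*")
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ":"), "")
  field <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) abort(sprintf("Model file missing field '%s'.", k))
    vals[i]
  }
  nums <- function(k) as.numeric(strsplit(trimws(field(k)), "\\s+")[[1]])
  membership_model(modality = trimws(field("modality")),
                   form = trimws(field("form")),
                   coefficients = nums("coefficients"),
                   domain = nums("domain"))
}

#' @export
print.membership_model <- function(x, ...) {
  cat(sprintf("<membership_model> %s (%s) on [%g, %g]\n",
              x$modality, x$form, x$domain[1], x$domain[2]))
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' Plot a membership model curve
#'
#' @param object A [membership_model()].
#' @param n Number of evaluation points across the domain.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot membership_model
#' @export
autoplot.membership_model <- function(object, n = 512, ...) {
  v <- seq(object$domain[1], object$domain[2], length.out = n)
  df <- tibble::tibble(value = v,
                       membership = suppressMessages(eval_membership(object, v)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$membership)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = sprintf("%s value", object$modality),
                  y = "tumour membership",
                  title = sprintf("%s membership model (%s)",
                                  object$modality, object$form))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
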