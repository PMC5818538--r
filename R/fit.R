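#' Read a membership sample table
#'
#' Samples are literature- or clinically-derived summaries of tumour
#' parametric values, one row per ROI or published value, with columns
#' `modality`, `mean`, `sd`, `source`. Each sample contributes the interval
#' `mean +/- sd` to the fuzzy-statistics histogram.
#'
#' @param path Delimited text file (comma- or tab-separated).
#' @return A tibble with validated columns.
#' @export
read_membership_samples <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such sample table: %s", path))
  df <- utils::read.csv(path, sep = if (grepl("\\.tsv$", path)) "\t" else ",",
                        stringsAsFactors = FALSE)
  need <- c("modality", "mean", "sd", "source")
  if (!all(need %in% names(df))) {
    abort(sprintf("Sample table must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  df$modality <- toupper(df$modality)
  validate_samples(df)
  tibble::as_tibble(df[need])
}

# Plausibility ranges per modality (ADC in 1e-3 mm^2/s).
SAMPLE_RANGES <- list(ADC = c(0, 4), FA = c(0, 1), CBV_RATIO = c(0, 20))

validate_samples <- function(df) {
  if (!all(df$modality %in% names(SAMPLE_RANGES))) {
    abort("Sample modality must be one of ADC, FA, CBV_RATIO.")
  }
  if (any(df$sd < 0)) abort("Sample sd must be >= 0.")
  for (m in unique(df$modality)) {
    r <- SAMPLE_RANGES[[m]]
    v <- df$mean[df$modality == m]
    if (any(v <= r[1] | v > r[2])) {
      abort(sprintf("%s sample means must lie in (%g, %g].", m, r[1], r[2]))
    }
  }
  invisible(df)
}

#' Shipped synthetic membership sample table
#'
#' A synthetic stand-in for the sample collection behind the canonical
#' models: it reproduces the sample counts (32 ADC, 21 FA, 32 rCBV-ratio
#' values) and plausible per-modality ranges, not any measured values.
#'
#' @return A tibble of sample records.
#' @export
synthetic_membership_samples <- function() {
  read_membership_samples(system.file("extdata",
                                      "membership_samples_synthetic.csv",
                                      package = "gliofuse"))
}

#' Build a tumour-membership-frequency histogram from samples
#'
#' The fuzzy-statistics rule: each sample votes for every bin its interval
#' `[mean - sd, mean + sd]` overlaps (binary overlap; a zero-sd sample votes
#' for the single bin containing its mean). Raw counts are normalised by the
#' maximum count, so the histogram peaks at frequency 1 — memberships are
#' possibilities, not probabilities.
#'
#' @param samples Data frame with columns `modality`, `mean`, `sd` (all rows
#'   one modality).
#' @param bin_width Positive bin width in modality units. Defaults per
#'   modality: ADC 0.05 (1e-3 mm^2/s), FA 0.01, rCBV ratio 0.25.
#' @return A `membership_histogram` object with `bin_edges`, `mids`,
#'   `frequency`, `counts`, `modality`.
#' @export
build_histogram <- function(samples, bin_width = NULL) {
  samples <- as.data.frame(samples)
  if (nrow(samples) < 2L) abort("Need at least 2 samples.")
  mods <- unique(samples$modality)
  if (length(mods) != 1L) {
    abort(sprintf("All samples must share one modality; got %s.",
                  paste(mods, collapse = ", ")))
  }
  validate_samples(samples)
  if (is.null(bin_width)) {
    bin_width <- switch(mods, ADC = 0.05, FA = 0.01, CBV_RATIO = 0.25)
  }
  if (!is.numeric(bin_width) || bin_width <= 0) {
    abort("`bin_width` must be positive.")
  }
  lo <- samples$mean - samples$sd
  hi <- samples$mean + samples$sd
  # Edges aligned to multiples of bin_width covering all intervals.
  first <- floor(min(lo) / bin_width)
  last <- ceiling(max(hi) / bin_width)
  if (last <= first) last <- first + 1L
  edges <- (first:last) * bin_width
  nb <- length(edges) - 1L
  counts <- integer(nb)
  eps <- bin_width * 1e-9  # guard against float jitter at shared edges
  for (i in seq_len(nb)) {
    el <- edges[i]; eh <- edges[i + 1L]
    overlap <- (lo < eh - eps & hi > el + eps) |
      (samples$sd == 0 & samples$mean >= el & samples$mean < eh)
    counts[i] <- sum(overlap)
  }
  structure(list(bin_edges = edges,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts,
                 frequency = counts / max(counts),
                 modality = mods),
            class = "membership_histogram")
}

#' @export
print.membership_histogram <- function(x, ...) {
  cat(sprintf("<membership_histogram> %s, %d bins on [%g, %g], peak count %d\n",
              x$modality, length(x$counts), min(x$bin_edges),
              max(x$bin_edges), max(x$counts)))
  invisible(x)
}

#' Plot a membership histogram
#'
#' @param object A `membership_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot membership_histogram
#' @export
autoplot.membership_histogram <- function(object, ...) {
  df <- tibble::tibble(mid = object$mids, frequency = object$frequency)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$frequency)) +
    ggplot2::geom_col(width = diff(object$bin_edges)[1], fill = "grey40") +
    ggplot2::labs(x = sprintf("%s value", object$modality),
                  y = "tumour membership frequency")
}

#' Fit a membership model to a histogram
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) minimising the sum
#' of squared residuals between the model evaluated at bin centres and the
#' histogram frequencies. Widths and slopes are bounded below by a small
#' positive value so fits cannot degenerate; the iteration cap is 1000 and
#' the convergence tolerance 1e-10. The fit is deterministic given `init`.
#'
#' A fit is flagged `degenerate` when the residual RMS per bin stays above
#' `degenerate_rms` (default 0.05), as happens for flat or uninformative
#' histograms.
#'
#' @param hist A `membership_histogram` from [build_histogram()].
#' @param form `"gaussian2"` or `"sigmoid_diff"`.
#' @param init Numeric initial coefficients (length 6 / 5).
#' @param modality Modality recorded on the fitted model; defaults to the
#'   histogram's.
#' @param degenerate_rms RMS residual threshold above which the fit is
#'   flagged degenerate.
#' @return A `membership_fit` object: the fitted [membership_model()] plus
#'   `residual_norm`, `rms`, `iterations`, `converged`, `degenerate`.
#' @export
fit_membership <- function(hist, form = c("gaussian2", "sigmoid_diff"), init,
                           modality = NULL, degenerate_rms = 0.05) {
  stopifnot(inherits(hist, "membership_histogram"))
  form <- match.arg(form)
  nm <- coef_names(form)
  if (length(init) != length(nm)) {
    abort(sprintf("`init` must have %d coefficients for form '%s'.",
                  length(nm), form))
  }
  if (stats::sd(hist$frequency) == 0) {
    warn("Histogram is flat; fit is degenerate.")
  }
  modality <- if (is.null(modality)) hist$modality else modality
  init <- stats::setNames(as.numeric(init), nm)
  lower <- rep(-Inf, length(nm))
  names(lower) <- nm
  pos <- intersect(c("s1", "s2", "k1", "k2"), nm)
  lower[pos] <- 1e-6
  x <- hist$mids
  y <- hist$frequency
  resid_fun <- function(p) {
    m <- list(form = form, coefficients = as.list(p))
    mf_raw(m, x) - y
  }
  fit <- minpack.lm::nls.lm(
    par = init, lower = lower, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-10,
                                         ptol = 1e-10))
  co <- stats::setNames(as.numeric(fit$par), nm)
  rss <- sum(fit$fvec^2)
  rms <- sqrt(rss / length(x))
  converged <- fit$info %in% 1:4
  if (!converged && fit$info != 9) {
    # info 9: iteration cap reached; still return best-so-far below
    warn(sprintf("Curve fit did not converge cleanly (nls.lm info %d: %s).",
                 fit$info, fit$message))
  }
  if (fit$info == 9) {
    abort(sprintf(
      "Curve fit hit the iteration cap; best residual norm %.4g with coefficients %s.",
      sqrt(rss), paste(signif(co, 6), collapse = ", ")))
  }
  model <- membership_model(modality = modality, form = form,
                            coefficients = co,
                            domain = range(hist$bin_edges))
  structure(list(model = model,
                 residual_norm = sqrt(rss),
                 rms = rms,
                 iterations = fit$niter,
                 converged = converged,
                 degenerate = stats::sd(y) < 1e-8 || rms > degenerate_rms,
                 histogram = hist),
            class = "membership_fit")
}

#' @export
print.membership_fit <- function(x, ...) {
  cat(sprintf(
    "<membership_fit> %s (%s): residual norm %.3g in %d iterations%s\n",
    x$model$modality, x$model$form, x$residual_norm, x$iterations,
    if (x$degenerate) " [degenerate]" else ""))
  print(signif(x$model$coefficients, 6))
  invisible(x)
}

#' Tidy a fitted membership model
#'
#' @param x A `membership_fit`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`.
#' @method tidy membership_fit
#' @export
tidy.membership_fit <- function(x, ...) {
  tibble::tibble(term = names(x$model$coefficients),
                 estimate = as.numeric(x$model$coefficients))
}

#' One-row fit summary
#'
#' @param x A `membership_fit`.
#' @param ... Unused.
#' @return A one-row tibble: modality, form, residual norm, RMS, iterations,
#'   convergence and degeneracy flags.
#' @method glance membership_fit
#' @export
glance.membership_fit <- function(x, ...) {
  tibble::tibble(modality = x$model$modality, form = x$model$form,
                 residual_norm = x$residual_norm, rms = x$rms,
                 iterations = x$iterations, converged = x$converged,
                 degenerate = x$degenerate)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
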