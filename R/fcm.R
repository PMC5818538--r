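#' Fuzzy c-means clustering of voxel intensities
#'
#' Standard fuzzy c-means on the scalar intensities of the voxels inside
#' `mask` (by default the full field of view, so air/background can form
#' its own cluster). Memberships follow
#' `u_ij = 1 / sum_l (d_ij / d_il)^(2/(m-1))` and centroids are the
#' `u^m`-weighted intensity means; iteration stops when the largest
#' centroid movement falls below `tol` or after `max_iter` sweeps.
#' Initial centroids are placed at seeded random quantiles of the masked
#' intensity distribution, making the run deterministic given `seed`.
#'
#' Voxels at zero distance to a centroid receive full membership in that
#' centroid (split evenly among coincident centroids).
#'
#' @param vol A [parametric_volume()] (typically T1C or T2).
#' @param mask Optional [binary_mask()] limiting the voxels clustered;
#'   `NULL` means every voxel.
#' @param k Number of clusters (>= 2); the anatomical branch uses 3
#'   (tumour, normal brain, non-brain).
#' @param fuzzifier Fuzziness exponent m > 1 (default 2).
#' @param tol Convergence tolerance on centroid movement (default 1e-5).
#' @param max_iter Iteration cap (default 300).
#' @param seed Integer seed for centroid initialisation.
#' @return An `fcm_result`: `membership` (n x k matrix over masked voxels),
#'   `centroids` (sorted ascending), `labels` (3-D integer array, 0 outside
#'   mask), `iterations`, `objective`, `objective_trace`, `voxel_index`.
#' @export
fcm_cluster <- function(vol, mask = NULL, k = 3, fuzzifier = 2.0,
                        tol = 1e-5, max_iter = 300, seed = 1L) {
  stopifnot(inherits(vol, "parametric_volume"))
  if (k < 2) abort("`k` must be >= 2.")
  if (fuzzifier <= 1) abort("`fuzzifier` must be > 1.")
  dims <- dim(vol$data)
  inside <- if (is.null(mask)) {
    array(TRUE, dims)
  } else {
    check_same_grid(vol, mask, "volume", "mask")
    vol_data(mask)
  }
  if (!any(inside)) abort("Mask is empty; nothing to cluster.")
  x <- as.numeric(vol$data[inside])
  # Seeded quantile-spread initialisation: centroids evenly spread between
  # the 1st and 99th intensity percentiles with a small seeded jitter.
  # (Placing centroids at distribution quantiles directly collapses them
  # onto the background mode when most voxels are air.)
  set.seed(seed)
  q <- as.numeric(stats::quantile(x, c(0.01, 0.99), names = FALSE))
  if (q[2] <= q[1]) q <- range(x)
  if (q[2] <= q[1]) q <- q + c(-0.5, 0.5)
  centroids <- seq(q[1], q[2], length.out = k + 2L)[2:(k + 1L)]
  centroids <- centroids + stats::runif(k, -1, 1) * 1e-3 * (q[2] - q[1])
  obj_trace <- numeric(0)
  iterations <- 0L
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(x, centroids, function(a, b) (a - b)^2)
    zero <- d2 < .Machine$double.eps
    inv <- d2^(-1 / (fuzzifier - 1))
    u <- inv / rowSums(inv)
    zr <- rowSums(zero) > 0
    if (any(zr)) {
      u[zr, ] <- 0
      u[zr, ] <- zero[zr, , drop = FALSE] / rowSums(zero[zr, , drop = FALSE])
    }
    um <- u^fuzzifier
    new_centroids <- colSums(um * x) / colSums(um)
    obj_trace <- c(obj_trace, sum(um * outer(x, new_centroids,
                                             function(a, b) (a - b)^2)))
    moved <- max(abs(new_centroids - centroids))
    centroids <- new_centroids
    iterations <- it
    if (moved < tol) break
  }
  ord <- order(centroids)
  centroids <- centroids[ord]
  u <- u[, ord, drop = FALSE]
  labels <- array(0L, dims)
  labels[inside] <- max.col(u, ties.method = "first")
  structure(list(membership = u, centroids = centroids, labels = labels,
                 iterations = iterations,
                 objective = obj_trace[length(obj_trace)],
                 objective_trace = obj_trace,
                 voxel_index = which(inside), dims = dims,
                 spacing = vol$spacing, k = as.integer(k)),
            class = "fcm_result")
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf("<fcm_result> k=%d, %d voxels, %d iterations, objective %.4g\n",
              x$k, nrow(x$membership), x$iterations, x$objective))
  cat("centroids:", paste(signif(x$centroids, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy FCM centroids
#'
#' @param x An `fcm_result`.
#' @param ... Unused.
#' @return One row per cluster: `cluster`, `centroid`, `size` (hard-label
#'   voxel count).
#' @method tidy fcm_result
#' @export
tidy.fcm_result <- function(x, ...) {
  hard <- max.col(x$membership, ties.method = "first")
  tibble::tibble(cluster = seq_len(x$k),
                 centroid = x$centroids,
                 size = tabulate(hard, nbins = x$k))
}

#' One-row FCM summary
#'
#' @param x An `fcm_result`.
#' @param ... Unused.
#' @return A one-row tibble: k, iterations, final objective, voxel count.
#' @method glance fcm_result
#' @export
glance.fcm_result <- function(x, ...) {
  tibble::tibble(k = x$k, iterations = x$iterations,
                 objective = x$objective, n_voxels = nrow(x$membership))
}

#' Pick the tumour cluster
#'
#' Tumour is hyperintense on both T1C (contrast enhancement) and T2
#' (oedema), so the cluster with the highest centroid intensity is taken;
#' ties go to the lowest cluster id. When `within` is supplied, the
#' returned hard-label mask is additionally restricted to that (brain)
#' mask, so non-brain voxels that happen to share the cluster are dropped.
#'
#' @param res An `fcm_result`.
#' @param within Optional [binary_mask()] restricting the cluster mask.
#' @return A list: `cluster` (id) and `mask` (a [binary_mask()] of its
#'   hard-labelled voxels).
#' @export
select_tumor_cluster <- function(res, within = NULL) {
  stopifnot(inherits(res, "fcm_result"))
  id <- which(res$centroids == max(res$centroids))[1]
  m <- res$labels == id
  if (!is.null(within)) m <- m & vol_data(within)
  list(cluster = id, mask = binary_mask(m, res$spacing))
}

#' Morphological cleanup and seeded region growing
#'
#' Per axial slice the tumour-cluster mask is hole-filled (4-connected
#' background) and opened once with the flat radius-3 disk, separating
#' tenuous bridges to normal tissue; region growing then keeps the
#' 26-connected component of the cleaned volume that contains the seed
#' (`growth = "slice"` restricts growth to 8-connectivity within the seed's
#' slice).
#'
#' @param labelmask A [binary_mask()] of the tumour cluster.
#' @param seed A length-3 integer `(row, col, slice)` voxel index (1-based).
#' @param growth `"volume"` (default, 26-connected 3-D) or `"slice"`.
#' @return A [binary_mask()]; empty (with a warning) if the seed falls
#'   outside the cleaned mask.
#' @export
cleanup_and_grow <- function(labelmask, seed, growth = c("volume", "slice")) {
  growth <- match.arg(growth)
  m <- vol_data(labelmask)
  dims <- dim(m)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > dims)) {
    abort(sprintf("Seed (%s) is outside the %s volume.",
                  paste(seed, collapse = ","), paste(dims, collapse = "x")))
  }
  kern <- disk_kernel(3)
  cleaned <- array(FALSE, dims)
  for (s in seq_len(dims[3])) {
    sl <- m[, , s]
    if (!any(sl)) next
    sl <- fill_holes_slice(sl)
    sl <- dilate_slice(erode_slice(sl, kern), kern)  # opening
    cleaned[, , s] <- sl
  }
  if (!cleaned[seed[1], seed[2], seed[3]]) {
    warn("Seed lies outside the cleaned tumour-cluster mask; empty result.")
    return(binary_mask(array(FALSE, dims), vol_spacing(labelmask)))
  }
  if (growth == "volume") {
    lab <- label_components(cleaned, 26)
    keep <- lab == lab[seed[1], seed[2], seed[3]]
  } else {
    keep <- array(FALSE, dims)
    lab2 <- label_components(cleaned[, , seed[3]], 8)
    keep[, , seed[3]] <- lab2 == lab2[seed[1], seed[2]]
  }
  binary_mask(keep, vol_spacing(labelmask))
}

#' Anatomical tumour segmentation (T1C union T2)
#'
#' Runs the anatomical branch on each structural volume: fuzzy c-means into
#' `k = 3` clusters over the full field of view (tumour, normal brain,
#' non-brain), selection of the hyperintense cluster restricted to the
#' brain, per-slice cleanup and seeded region growing; the final anatomical
#' tumour extent is the voxel-wise union of the T1C and T2 results.
#'
#' @param t1c,t2 [parametric_volume()]s on the shared grid.
#' @param brain A [binary_mask()] of the brain.
#' @param seed_t1c,seed_t2 Length-3 `(row, col, slice)` seeds near each
#'   tumour centre (1-based).
#' @param k,fuzzifier,tol,max_iter,seed FCM settings; see [fcm_cluster()].
#' @param growth Region-growing connectivity; see [cleanup_and_grow()].
#' @return A [binary_mask()] — `Anatomy_auto`.
#' @export
segment_anatomical <- function(t1c, t2, brain, seed_t1c, seed_t2,
                               k = 3, fuzzifier = 2.0, tol = 1e-5,
                               max_iter = 300, seed = 1L,
                               growth = c("volume", "slice")) {
  growth <- match.arg(growth)
  check_same_grid(t1c, t2, "T1C", "T2")
  check_same_grid(t1c, brain, "T1C", "brain mask")
  one <- function(vol, sd_pt) {
    res <- fcm_cluster(vol, mask = NULL, k = k, fuzzifier = fuzzifier,
                       tol = tol, max_iter = max_iter, seed = seed)
    sel <- select_tumor_cluster(res, within = brain)
    cleanup_and_grow(sel$mask, sd_pt, growth = growth)
  }
  a <- one(t1c, seed_t1c)
  b <- one(t2, seed_t2)
  binary_mask((vol_data(a) | vol_data(b)) & vol_data(brain),
              vol_spacing(t1c))
}
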