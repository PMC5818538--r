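#' Discrete flat disk structuring element
#'
#' The Euclidean-ball discretization `{(i, j): i^2 + j^2 <= r^2}` as a 0/1
#' matrix with a `(2r+1)` square footprint. For the default radius 3 this is
#' the 29-pixel disk used throughout the morphological cleanup; the exact
#' pixel set is pinned so results are bit-stable.
#'
#' @param radius Integer radius in pixels.
#' @return A 0/1 integer matrix.
#' @export
disk_kernel <- function(radius = 3) {
  r <- as.integer(radius)
  stopifnot(r >= 1)
  off <- -r:r
  k <- outer(off, off, function(i, j) as.integer(i^2 + j^2 <= r^2))
  storage.mode(k) <- "integer"
  k
}

# Neighbourhood offset table for a given 2-D/3-D connectivity.
conn_offsets <- function(connectivity) {
  switch(as.character(connectivity),
    "4" = cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1)),
    "8" = {
      g <- expand.grid(dr = -1:1, dc = -1:1)
      as.matrix(g[!(g$dr == 0 & g$dc == 0), ])
    },
    "6" = cbind(dr = c(-1, 1, 0, 0, 0, 0), dc = c(0, 0, -1, 1, 0, 0),
                ds = c(0, 0, 0, 0, -1, 1)),
    "26" = {
      g <- expand.grid(dr = -1:1, dc = -1:1, ds = -1:1)
      as.matrix(g[!(g$dr == 0 & g$dc == 0 & g$ds == 0), ])
    },
    abort("connectivity must be one of 4, 8 (2-D) or 6, 26 (3-D)."))
}

#' Connected-component labelling
#'
#' Labels the `TRUE` voxels of a 2-D or 3-D logical array under the given
#' connectivity. Components are numbered by the first voxel of each
#' component in R's native (column-major) raster order, so label 1 is the
#' component encountered first; ties elsewhere in the pipeline are broken by
#' lowest label id.
#'
#' @param x Logical matrix or 3-D array.
#' @param connectivity 4 or 8 for a matrix, 6 or 26 for a 3-D array.
#' @return Integer array of the same shape; 0 is background.
#' @export
label_components <- function(x, connectivity) {
  dims <- dim(x)
  is3d <- length(dims) == 3L
  offs <- conn_offsets(connectivity)
  if ((is3d && ncol(offs) != 3L) || (!is3d && ncol(offs) != 2L)) {
    abort("Connectivity does not match array dimensionality.")
  }
  idx <- which(x)
  lab <- array(0L, dim = dims)
  if (length(idx) == 0L) return(lab)
  pos <- arrayInd(idx, dims)
  # map from flat index to 1..n for graph vertices
  vmap <- integer(prod(dims))
  vmap[idx] <- seq_along(idx)
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    npos <- pos
    npos[, 1] <- pos[, 1] + offs[k, 1]
    npos[, 2] <- pos[, 2] + offs[k, 2]
    if (is3d) npos[, 3] <- pos[, 3] + offs[k, 3]
    ok <- npos[, 1] >= 1 & npos[, 1] <= dims[1] &
          npos[, 2] >= 1 & npos[, 2] <= dims[2]
    if (is3d) ok <- ok & npos[, 3] >= 1 & npos[, 3] <= dims[3]
    if (!any(ok)) next
    nflat <- npos[ok, 1] + (npos[ok, 2] - 1L) * dims[1]
    if (is3d) nflat <- nflat + (npos[ok, 3] - 1L) * dims[1] * dims[2]
    nb <- vmap[nflat]
    src <- which(ok)[nb > 0L]
    if (length(src)) {
      edges <- rbind(edges, cbind(src, nb[nb > 0L]))
    }
  }
  if (is.null(edges)) {
    comp <- seq_along(idx)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_along(idx)]
  }
  # renumber by first occurrence in column-major order
  first <- match(unique(comp), comp)
  ord <- order(idx[first])
  relabel <- integer(max(comp))
  relabel[unique(comp)[ord]] <- seq_along(ord)
  lab[idx] <- relabel[comp]
  lab
}

#' Fill holes in a binary slice
#'
#' A hole is a 4-connected background component that does not touch the
#' slice border; all holes are set to foreground.
#'
#' @param m Logical matrix (one axial slice).
#' @return Logical matrix with holes filled.
#' @export
fill_holes_slice <- function(m) {
  stopifnot(is.matrix(m))
  bg <- !m
  if (!any(bg)) return(m)
  lab <- label_components(bg, 4)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                            lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0L]
  hole <- lab > 0L & !(lab %in% border_labels)
  m | hole
}

# EBImage-backed binary erosion / dilation with an arbitrary 0/1 kernel.
# Everything outside the slice is background, so slices are zero-padded by
# the kernel radius before the EBImage call (EBImage itself treats the
# outside as foreground when eroding).
pad_op <- function(m, kern, op) {
  r <- (nrow(kern) - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L * r, nc + 2L * r)
  p[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- as.numeric(m)
  out <- op(p, kern)
  matrix(out[(r + 1L):(r + nr), (r + 1L):(r + nc)] > 0.5, nr, nc)
}

erode_slice <- function(m, kern) pad_op(m, kern, EBImage::erode)

dilate_slice <- function(m, kern) pad_op(m, kern, EBImage::dilate)

#' Keep the largest connected component
#'
#' Ties on size are broken by lowest label id (components are numbered in
#' raster order, see [label_components()]).
#'
#' @param x Logical matrix or 3-D array.
#' @param connectivity Connectivity passed to [label_components()].
#' @return Logical array retaining only the largest component (all-`FALSE`
#'   if the input is empty).
#' @export
largest_component <- function(x, connectivity) {
  lab <- label_components(x, connectivity)
  if (max(lab) == 0L) return(array(FALSE, dim = dim(x)))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes == max(sizes))[1]
  array(lab == keep, dim = dim(x))
}

# The functional-branch per-slice cleanup: fill holes (4-connected
# background), erode twice with the radius-3 disk, dilate twice with the
# same disk, then keep the largest 8-connected region on the slice.
cleanup_slice_functional <- function(m, kern = disk_kernel(3),
                                     keep_largest = TRUE) {
  m <- fill_holes_slice(m)
  m <- erode_slice(m, kern)
  m <- erode_slice(m, kern)
  m <- dilate_slice(m, kern)
  m <- dilate_slice(m, kern)
  if (keep_largest && any(m)) {
    m <- largest_component(m, 8)
  }
  m
}
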