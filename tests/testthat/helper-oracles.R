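# Independent oracles used across the suite. These deliberately avoid the
# package's code paths (no EBImage, no igraph): scalar arithmetic for the
# membership forms, shift-and-combine sweeps for morphology, and iterative
# flood fills for connectivity.

oracle_mf_adc <- function(v) {
  0.5 * exp(-((v - 1.5) / 0.33)^2) + 0.5 * exp(-((v - 1.57) / 0.66)^2)
}

oracle_mf_fa <- function(v) {
  1.1 * (1 / (1 + exp(-60 * (v - 0.06))) - 1 / (1 + exp(-15.76 * (v - 0.27))))
}

oracle_mf_cbv <- function(v) {
  0.65 * exp(-((v - 1.1) / 0.8)^2) + 0.5 * exp(-((v - 2.68) / 2.37)^2)
}

oracle_mf <- function(modality, v) {
  switch(modality, ADC = oracle_mf_adc(v), FA = oracle_mf_fa(v),
         CBV_RATIO = oracle_mf_cbv(v))
}

# Shift a logical matrix by (dr, dc), padding with `fill`.
oracle_shift <- function(m, dr, dc, fill = FALSE) {
  out <- matrix(fill, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
  rsrc <- rs - dr; csrc <- cs - dc
  okr <- rsrc >= 1 & rsrc <= nrow(m); okc <- csrc >= 1 & csrc <= ncol(m)
  out[rs[okr], cs[okc]] <- m[rsrc[okr], csrc[okc]]
  out
}

kernel_offsets <- function(kern) {
  r <- (nrow(kern) - 1) / 2
  w <- which(kern > 0, arr.ind = TRUE)
  cbind(w[, 1] - r - 1, w[, 2] - r - 1)
}

# Erosion: pixel survives iff every kernel offset lands on foreground
# (border treated as background).
oracle_erode <- function(m, kern) {
  off <- kernel_offsets(kern)
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) {
    out <- out & oracle_shift(m, off[i, 1], off[i, 2], fill = FALSE)
  }
  out
}

oracle_dilate <- function(m, kern) {
  off <- kernel_offsets(kern)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) {
    out <- out | oracle_shift(m, -off[i, 1], -off[i, 2], fill = FALSE)
  }
  out
}

# Background reachable from the border under 4-connectivity, by iterative
# propagation; holes are the unreachable background.
oracle_fill_holes <- function(m) {
  bg <- !m
  reach <- matrix(FALSE, nrow(m), ncol(m))
  reach[1, ] <- bg[1, ]; reach[nrow(m), ] <- bg[nrow(m), ]
  reach[, 1] <- bg[, 1]; reach[, ncol(m)] <- bg[, ncol(m)]
  repeat {
    grown <- reach
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      grown <- grown | (bg & oracle_shift(reach, d[1], d[2]))
    }
    if (identical(grown, reach)) break
    reach <- grown
  }
  m | (bg & !reach)
}

# All connected components of a logical matrix by repeated flood fill.
# Returns an integer matrix; components numbered by first TRUE pixel in
# column-major order.
oracle_label <- function(m, connectivity = 8) {
  dirs <- if (connectivity == 4) {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  } else {
    ds <- expand.grid(dr = -1:1, dc = -1:1)
    ds <- ds[!(ds$dr == 0 & ds$dc == 0), ]
    lapply(seq_len(nrow(ds)), function(i) c(ds$dr[i], ds$dc[i]))
  }
  lab <- matrix(0L, nrow(m), ncol(m))
  nextlab <- 0L
  remaining <- m
  while (any(remaining)) {
    nextlab <- nextlab + 1L
    seedix <- which(remaining)[1]
    comp <- matrix(FALSE, nrow(m), ncol(m))
    comp[seedix] <- TRUE
    repeat {
      grown <- comp
      for (d in dirs) {
        grown <- grown | (m & oracle_shift(comp, d[1], d[2]))
      }
      if (identical(grown, comp)) break
      comp <- grown
    }
    lab[comp] <- nextlab
    remaining <- remaining & !comp
  }
  lab
}

oracle_largest8 <- function(m) {
  lab <- oracle_label(m, 8)
  if (max(lab) == 0L) return(m & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which(sizes == max(sizes))[1]
}

# Full functional per-slice cleanup sequence, independent of the package.
oracle_cleanup_slice <- function(m, kern) {
  m <- oracle_fill_holes(m)
  m <- oracle_erode(m, kern)
  m <- oracle_erode(m, kern)
  m <- oracle_dilate(m, kern)
  m <- oracle_dilate(m, kern)
  if (any(m)) m <- oracle_largest8(m) else m
}

# Random smooth-ish membership slice in [0, 1] for morphology sweeps.
random_fusion_slice <- function(nr, nc) {
  base <- matrix(0.15, nr, nc)
  for (b in seq_len(sample(2:4, 1))) {
    cr <- runif(1, 5, nr - 5); cc <- runif(1, 5, nc - 5)
    rad <- runif(1, 4, min(nr, nc) / 3)
    d2 <- outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, `+`)
    base <- pmax(base, 0.85 * exp(-d2 / (2 * rad^2)) + 0.1)
  }
  pmin(pmax(base + matrix(runif(nr * nc, -0.15, 0.15), nr, nc), 0), 1)
}

# Small helpers shared by tests.
mk_vol <- function(arr, modality = "ADC", spacing = c(1, 1, 1)) {
  parametric_volume(arr, modality, spacing)
}

mk_mask <- function(arr, spacing = c(1, 1, 1)) binary_mask(arr, spacing)

full_mask <- function(dims, spacing = c(1, 1, 1)) {
  binary_mask(array(TRUE, dims), spacing)
}
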