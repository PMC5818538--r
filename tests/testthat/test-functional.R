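test_that("rCBV normalisation divides by the white-matter ROI mean", {
  arr <- array(2, c(11, 11, 3))
  arr[6, 6, 2] <- 5
  cbv <- mk_vol(arr, "CBV")
  roi <- roi_spec(slice = 3, center = c(6, 6), size = 25)
  ratio <- compute_rcbv_ratio(cbv, roi)  # ROI mean is 2
  expect_equal(ratio$modality, "CBV_RATIO")
  expect_equal(ratio$data[6, 6, 2], 2.5)

  # volume identical to its ROI mean everywhere -> all ones
  ones <- compute_rcbv_ratio(mk_vol(array(3.7, c(8, 8, 2)), "CBV"),
                             roi_spec(1, c(4, 4), 9))
  expect_true(all(ones$data == 1))

  # random volume vs independent mean-then-divide
  set.seed(3)
  rnd <- array(runif(10 * 10 * 2, 1, 8), c(10, 10, 2))
  roi2 <- roi_spec(2, c(5, 5), 25)
  r <- compute_rcbv_ratio(mk_vol(rnd, "CBV"), roi2)
  mu <- mean(rnd[3:7, 3:7, 2])
  expect_equal(r$data, rnd / mu)

  expect_error(compute_rcbv_ratio(mk_vol(array(0, c(8, 8, 2)), "CBV"),
                                  roi_spec(1, c(4, 4), 25)), "Degenerate")
  expect_error(compute_rcbv_ratio(mk_vol(rnd, "CBV"),
                                  roi_spec(1, c(1, 1), 25)), "bounds")
  expect_error(compute_rcbv_ratio(mk_vol(rnd, "ADC"), roi2), "CBV")
})

test_that("geometric-mean fusion has the algebraic properties", {
  dims <- c(6, 6, 2)
  fv <- function(x, src) fuzzy_volume(array(x, dims), src)
  # idempotence on equal memberships
  m <- runif(prod(dims))
  expect_equal(fuse(fv(m, "FS_ADC"), fv(m, "FS_FA"), fv(m, "FS_CBV"))$data,
               array(m, dims))
  # annihilator zero and the derived scalar example
  z <- m; z[1] <- 0
  fused <- fuse(fv(z, "FS_ADC"), fv(m, "FS_FA"), fv(m, "FS_CBV"))
  expect_equal(fused$data[1], 0)
  one <- fuse(fv(0.8, "FS_ADC"), fv(0.9, "FS_FA"), fv(0.6, "FS_CBV"))
  expect_equal(one$data[1], 0.432^(1 / 3), tolerance = 1e-12)

  set.seed(5)
  a <- runif(prod(dims)); b <- runif(prod(dims)); c <- runif(prod(dims))
  f <- fuse(fv(a, "FS_ADC"), fv(b, "FS_FA"), fv(c, "FS_CBV"))$data
  # bounded by componentwise min and max
  expect_true(all(f >= pmin(a, b, c) - 1e-12 & f <= pmax(a, b, c) + 1e-12))
  # symmetric under permutation
  expect_equal(fuse(fv(c, "FS_ADC"), fv(a, "FS_FA"), fv(b, "FS_CBV"))$data, f)
  # monotone in each argument
  a2 <- pmin(a + 0.1, 1)
  f2 <- fuse(fv(a2, "FS_ADC"), fv(b, "FS_FA"), fv(c, "FS_CBV"))$data
  expect_true(all(f2 >= f - 1e-12))

  expect_error(fuse(fv(a, "FS_ADC"), fv(b, "FS_FA"),
                    fuzzy_volume(array(0.5, c(5, 5, 2)), "FS_CBV")),
               "mismatch")
})

test_that("functional segmentation thresholds then cleans each slice", {
  dims <- c(64, 64, 2)
  limit <- full_mask(dims)
  # a 31x31 plateau at 0.7 survives the erode/dilate pair as one component
  f <- array(0, dims)
  f[17:47, 17:47, 1] <- 0.7
  seg <- segment_functional(fuzzy_volume(f, "FS_FUSION"), limit)
  expect_identical(seg$data[, , 1],
                   oracle_cleanup_slice(f[, , 1] >= 0.6, disk_kernel(3)))
  expect_gt(sum(seg$data[, , 1]), 0)
  expect_equal(max(label_components(seg$data[, , 1], 8)), 1L)

  # everything below threshold -> empty
  seg0 <- segment_functional(fuzzy_volume(array(0.5, dims), "FS_FUSION"),
                             limit)
  expect_equal(sum(seg0$data), 0)

  # of two surviving blobs only the larger is kept per slice
  g <- array(0, dims)
  g[5:24, 5:24, 1] <- 0.9    # 400 px
  g[40:49, 40:44, 1] <- 0.9  # 50 px, both survive erosion
  segg <- segment_functional(fuzzy_volume(g, "FS_FUSION"), limit)
  expect_true(any(segg$data[5:24, 5:24, 1]))
  expect_false(any(segg$data[40:49, 40:44, 1]))
  lab <- oracle_label(g[, , 1] >= 0.6, 8)
  expect_equal(max(lab), 2L)  # the two blobs really are separate components
})

test_that("functional segmentation respects limit mask and threshold", {
  dims <- c(40, 40, 1)
  set.seed(9)
  f <- array(random_fusion_slice(40, 40), dims)
  lim <- array(FALSE, dims); lim[5:30, 5:30, 1] <- TRUE
  seg <- segment_functional(fuzzy_volume(f, "FS_FUSION"), mk_mask(lim))
  expect_true(all(!seg$data | lim))  # output within limit

  # raising the threshold never grows the pre-morphology region
  pre_06 <- f >= 0.6 & lim
  pre_07 <- f >= 0.7 & lim
  expect_true(all(!pre_07 | pre_06))
  # threshold is inclusive
  fx <- array(0, dims); fx[10:25, 10:25, 1] <- 0.6
  seg_eq <- segment_functional(fuzzy_volume(fx, "FS_FUSION"),
                               full_mask(dims), threshold = 0.6)
  expect_gt(sum(seg_eq$data), 0)

  expect_warning(
    empty <- segment_functional(fuzzy_volume(f, "FS_FUSION"),
                                mk_mask(array(FALSE, dims))),
    "empty")
  expect_equal(sum(empty$data), 0)
})

test_that("volume-wise largest component mode keeps one 3-D component", {
  dims <- c(40, 40, 3)
  f <- array(0, dims)
  f[5:20, 5:20, 1:2] <- 0.9   # big blob across slices 1-2
  f[25:38, 25:38, 3] <- 0.9   # separate blob on slice 3
  seg <- segment_functional(fuzzy_volume(f, "FS_FUSION"), full_mask(dims),
                            largest_component = "volume")
  expect_true(any(seg$data[, , 1]) && any(seg$data[, , 2]))
  expect_false(any(seg$data[, , 3]))
  expect_equal(max(label_components(seg$data, 26)), 1L)
})
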