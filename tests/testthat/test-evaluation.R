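test_that("mask combination is a voxel-wise union with the usual algebra", {
  dims <- c(10, 10, 2)
  a <- array(FALSE, dims); a[1:10, 1:10, 1] <- TRUE   # 100 voxels
  b <- array(FALSE, dims); b[1:5, 1:10, 2] <- TRUE    # 50 voxels, disjoint
  u <- combine_masks(mk_mask(a), mk_mask(b))
  expect_equal(sum(u$data), 150)
  expect_equal(combine_masks(mk_mask(a), mk_mask(a))$data, a)  # idempotent

  set.seed(21)
  x <- array(runif(prod(dims)) < 0.4, dims)
  y <- array(runif(prod(dims)) < 0.4, dims)
  z <- array(runif(prod(dims)) < 0.4, dims)
  expect_equal(combine_masks(mk_mask(x), mk_mask(y))$data, x | y)
  expect_equal(combine_masks(mk_mask(x), mk_mask(y))$data,
               combine_masks(mk_mask(y), mk_mask(x))$data)  # commutative
  expect_equal(
    combine_masks(combine_masks(mk_mask(x), mk_mask(y)), mk_mask(z))$data,
    combine_masks(mk_mask(x), combine_masks(mk_mask(y), mk_mask(z)))$data)
  expect_error(combine_masks(mk_mask(x), full_mask(c(9, 10, 2))), "mismatch")
})

test_that("reference delineation applies strict grade-specific thresholds", {
  dims <- c(8, 8, 2)
  brain <- full_mask(dims)
  th <- grade_thresholds("high")
  uni <- function(x, mod) mk_vol(array(x, dims), mod)

  # uniform ADC 1.30 > 1.24: full-brain ADC mask
  del <- reference_delineation(uni(1.30, "ADC"), uni(0.30, "FA"),
                               uni(1.0, "CBV_RATIO"), th, brain)
  expect_true(all(del$adc$data))
  # uniform FA 0.30 fails "lower than 0.286": empty FA mask
  expect_equal(sum(del$fa$data), 0)
  expect_equal(sum(del$cbv$data), 0)
  expect_equal(del$combined$data, del$adc$data)

  # boundary values are excluded (strict inequalities)
  at <- reference_delineation(uni(1.24, "ADC"), uni(0.286, "FA"),
                              uni(5.18, "CBV_RATIO"), th, brain)
  expect_equal(sum(at$combined$data), 0)
})

test_that("phantom reference masks equal an independent voxel sweep", {
  spec <- default_phantom_specs()$low_grade
  spec$noise_level <- 0
  ph <- generate_phantom(spec)
  th <- grade_thresholds("low")
  del <- reference_delineation(ph$volumes$adc, ph$volumes$fa,
                               ph$volumes$cbv_ratio, th, ph$brain)
  b <- ph$brain$data
  expect_equal(del$adc$data, ph$volumes$adc$data > 1.11 & b)
  expect_equal(del$fa$data, ph$volumes$fa$data < 0.17 & b)
  expect_equal(del$cbv$data, ph$volumes$cbv_ratio$data > 2.32 & b)
  # white matter (FA 0.45) is correctly outside the FA reference mask
  wm <- ph$zones == 1L
  expect_equal(sum(del$fa$data & wm), 0)

  # monotone in the threshold: raising adc_min never grows the ADC mask
  th2 <- grade_thresholds("low", adc_min = 1.4)
  del2 <- reference_delineation(ph$volumes$adc, ph$volumes$fa,
                                ph$volumes$cbv_ratio, th2, ph$brain)
  expect_true(all(!del2$adc$data | del$adc$data))

  # exclusion mask removes its voxels from every reference mask
  excl <- binary_mask(ph$zones == 3L, ph$brain$spacing)  # CSF
  del3 <- reference_delineation(ph$volumes$adc, ph$volumes$fa,
                                ph$volumes$cbv_ratio, th, ph$brain,
                                exclusion = excl)
  expect_equal(sum(del3$combined$data & excl$data), 0)
})

test_that("agreement metrics reproduce hand-counted confusion matrices", {
  dims <- c(10, 1, 1)
  A <- array(FALSE, dims); A[1:2, 1, 1] <- TRUE
  M <- array(FALSE, dims); M[2:3, 1, 1] <- TRUE
  U <- full_mask(dims)
  met <- compute_metrics(mk_mask(A), mk_mask(M), U, case = "toy")
  expect_equal(met$dsc, 0.5)
  expect_equal(met$sensitivity, 0.5)
  expect_equal(met$specificity, 7 / 8)
  expect_equal(met$universe_voxels, 10)
  # confusion-matrix identity TP+FP+FN+TN = |U|
  tp <- sum(A & M); fp <- sum(A & !M); fn <- sum(!A & M)
  tn <- met$specificity / (1 - met$specificity) * fp
  expect_equal(tp + fp + fn + tn, 10)

  # identity case
  met_id <- compute_metrics(mk_mask(M), mk_mask(M), U)
  expect_equal(met_id$delta_v_pct, 0)
  expect_equal(met_id$dsc, 1)
  expect_equal(met_id$sensitivity, 1)
  expect_equal(met_id$specificity, 1)

  # volumes scale with voxel size (cm^3)
  met_sp <- compute_metrics(mk_mask(A), mk_mask(M), U,
                            spacing = c(10, 10, 10))
  expect_equal(met_sp$v_manual_cm3, 2)

  # empty automatic mask is legal (total miss), empty manual mask is not
  miss <- compute_metrics(mk_mask(array(FALSE, dims)), mk_mask(M), U)
  expect_equal(miss$dsc, 0)
  expect_equal(miss$sensitivity, 0)
  expect_error(compute_metrics(mk_mask(M), mk_mask(array(FALSE, dims)), U),
               "empty")
  small_u <- array(FALSE, dims); small_u[1, 1, 1] <- TRUE
  expect_error(compute_metrics(mk_mask(A), mk_mask(M), mk_mask(small_u)),
               "Universe")
})

test_that("Dice is symmetric with the expected extremes", {
  dims <- c(6, 6, 1)
  set.seed(31)
  A <- array(runif(36) < 0.5, dims); A[1] <- TRUE
  B <- array(runif(36) < 0.5, dims); B[2] <- TRUE
  U <- full_mask(dims)
  expect_equal(compute_metrics(mk_mask(A), mk_mask(B), U)$dsc,
               compute_metrics(mk_mask(B), mk_mask(A), U)$dsc)
  disj <- array(FALSE, dims); disj[10] <- TRUE
  other <- array(FALSE, dims); other[20] <- TRUE
  expect_equal(compute_metrics(mk_mask(disj), mk_mask(other), U)$dsc, 0)
  # A containing M gives sensitivity 1; A inside M gives specificity 1
  inner <- array(FALSE, dims); inner[1:6] <- TRUE
  outer_m <- array(FALSE, dims); outer_m[1:12] <- TRUE
  expect_equal(compute_metrics(mk_mask(outer_m), mk_mask(inner), U)$sensitivity, 1)
  expect_equal(compute_metrics(mk_mask(inner), mk_mask(outer_m), U)$specificity, 1)
})

test_that("aggregation reports mean and sample SD per metric", {
  reports <- rbind(
    compute_metrics(mk_mask(array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))),
                    mk_mask(array(c(TRUE, FALSE, TRUE, FALSE), c(4, 1, 1))),
                    full_mask(c(4, 1, 1)), case = "a"),
    compute_metrics(mk_mask(array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))),
                    mk_mask(array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))),
                    full_mask(c(4, 1, 1)), case = "b"))
  agg <- aggregate_metrics(reports)
  expect_true(all(c("metric", "mean", "sd", "n") %in% names(agg)))
  row <- agg[agg$metric == "dsc", ]
  expect_equal(row$mean, mean(reports$dsc))
  expect_equal(row$sd, stats::sd(reports$dsc))

  # identical reports -> SD 0
  same <- rbind(reports[2, ], reports[2, ], reports[2, ])
  expect_true(all(aggregate_metrics(same)$sd == 0))
  # single report -> SD undefined, flagged
  expect_warning(one <- aggregate_metrics(reports[1, ]), "SD")
  expect_true(all(is.na(one$sd)))
})

test_that("volume difference follows the absolute-percentage definition", {
  expect_equal(round(volume_difference_pct(234.63, 196.20), 2), 19.59)
  expect_equal(volume_difference_pct(100, 100), 0)
  expect_equal(volume_difference_pct(c(110, 90), c(100, 100)), c(10, 10))
  expect_error(volume_difference_pct(1, 0), "positive")
})
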