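samples_df <- function(mean, sd, modality = "ADC") {
  data.frame(modality = modality, mean = mean, sd = sd, source = "test")
}

test_that("fuzzy-statistics histogram counts interval overlaps", {
  # two identical samples: one plateau at frequency 1 over [1.4, 1.6]
  h <- build_histogram(samples_df(c(1.5, 1.5), c(0.1, 0.1)), bin_width = 0.1)
  covered <- h$mids > 1.4 & h$mids < 1.6
  expect_true(all(h$frequency[covered] == 1))
  expect_true(all(h$frequency[!covered] == 0))

  # two disjoint intervals: two plateaus at frequency 1
  h2 <- build_histogram(samples_df(c(1.0, 2.0), c(0.2, 0.2)), bin_width = 0.1)
  expect_equal(sort(unique(h2$frequency)), c(0, 1))
  expect_equal(sum(h2$frequency == 1), 8)  # 4 bins per interval
})

test_that("staggered samples match brute-force overlap counting", {
  m <- c(1.0, 1.2, 1.3, 1.55, 1.8); s <- c(0.15, 0.1, 0.25, 0.05, 0.2)
  bw <- 0.1
  h <- build_histogram(samples_df(m, s), bin_width = bw)
  # brute force: count intervals with positive-length overlap with each bin
  # (touching at an edge is zero measure and does not count)
  brute <- vapply(seq_along(h$mids), function(i) {
    lo <- h$bin_edges[i]; hi <- h$bin_edges[i + 1]
    sum(pmin(m + s, hi) - pmax(m - s, lo) > 1e-9 * bw)
  }, numeric(1))
  expect_equal(h$counts, as.integer(brute))
  expect_equal(h$frequency, brute / max(brute))
  expect_equal(max(h$frequency), 1)
})

test_that("histogram input validation", {
  expect_error(build_histogram(samples_df(1.5, 0.1)), "at least 2")
  mixed <- rbind(samples_df(1.5, 0.1), samples_df(0.2, 0.05, "FA"))
  expect_error(build_histogram(mixed), "one modality")
  expect_error(build_histogram(samples_df(c(1, 2), c(0.1, -0.1))), ">= 0")
  expect_error(build_histogram(samples_df(c(1, 2), c(0.1, 0.1)),
                               bin_width = 0), "positive")
})

test_that("fitting a model-generated histogram is a fixed point", {
  mf <- canonical_membership("ADC")
  edges <- seq(0.2, 3.2, by = 0.05)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  h <- structure(list(bin_edges = edges, mids = mids,
                      counts = rep(1L, length(mids)),
                      frequency = oracle_mf_adc(mids), modality = "ADC"),
                 class = "membership_histogram")
  fit <- fit_membership(h, "gaussian2", init = mf$coefficients)
  expect_lt(max(abs(fit$model$coefficients - mf$coefficients)), 1e-6)
  expect_lt(fit$residual_norm, 1e-8)
  expect_false(fit$degenerate)
})

test_that("perturbed initialisation still recovers generating coefficients", {
  mf <- canonical_membership("CBV_RATIO")
  edges <- seq(0, 10, by = 0.25)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  h <- structure(list(bin_edges = edges, mids = mids,
                      counts = rep(1L, length(mids)),
                      frequency = oracle_mf_cbv(mids), modality = "CBV_RATIO"),
                 class = "membership_histogram")
  set.seed(11)
  init <- mf$coefficients * runif(6, 0.9, 1.1)
  fit <- fit_membership(h, "gaussian2", init = init)
  rel <- abs(fit$model$coefficients - mf$coefficients) /
    abs(mf$coefficients)
  expect_lt(max(rel), 0.01)
  expect_lt(fit$residual_norm, 1e-4)

  td <- tidy(fit)
  expect_equal(td$term, c("a1", "c1", "s1", "a2", "c2", "s2"))
  gl <- glance(fit)
  expect_true(gl$converged)
})

test_that("flat histograms are flagged degenerate", {
  edges <- seq(0, 2, by = 0.1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  h <- structure(list(bin_edges = edges, mids = mids,
                      counts = rep(1L, length(mids)),
                      frequency = rep(1, length(mids)), modality = "ADC"),
                 class = "membership_histogram")
  expect_warning(fit <- fit_membership(h, "gaussian2",
                                       init = c(0.5, 0.8, 0.3, 0.5, 1.2, 0.5)),
                 "flat|degenerate")
  expect_true(fit$degenerate)
})

test_that("shipped synthetic sample table has the documented structure", {
  s <- synthetic_membership_samples()
  expect_equal(unname(table(s$modality)[c("ADC", "FA", "CBV_RATIO")]),
               c(32L, 21L, 32L), ignore_attr = TRUE)
  expect_true(all(s$sd >= 0))
  # end to end: histogram + fit run on the synthetic ADC samples
  h <- build_histogram(s[s$modality == "ADC", ])
  fit <- fit_membership(h, "gaussian2",
                        init = canonical_membership("ADC")$coefficients)
  expect_s3_class(fit$model, "membership_model")
  v <- seq(fit$model$domain[1], fit$model$domain[2], length.out = 101)
  expect_true(all(eval_membership(fit$model, v) >= 0 &
                    eval_membership(fit$model, v) <= 1))
})
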