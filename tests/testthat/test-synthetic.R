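test_that("simulated chromatograms match their closed forms", {
  g <- seq(0, 20, by = 0.01)
  pk <- data.frame(rt = 10, height = 100, sigma = 0.1)
  ch <- simulate_chromatogram(pk, g)
  # noiseless apex at the grid point nearest the peak centre
  expect_equal(ch$time[which.max(ch$intensity)], 10)
  expect_equal(max(ch$intensity), 100, tolerance = 1e-6)
  # Gaussian integral: h * sigma * sqrt(2 pi)
  area <- sum((ch$intensity[-1] + ch$intensity[-length(g)]) / 2 * diff(g))
  expect_equal(area, 100 * 0.1 * sqrt(2 * pi), tolerance = 1e-3)
  # no peaks, no baseline, no noise -> flat zero
  flat <- simulate_chromatogram(data.frame(rt = numeric(0), height = numeric(0),
                                           sigma = numeric(0)), g)
  expect_true(all(flat$intensity == 0))
  expect_error(simulate_chromatogram(pk, numeric(0)), "empty")
  expect_error(simulate_chromatogram(pk, c(1, 1, 2)), "increasing")
})

test_that("chromatogram noise is seed-reproducible", {
  g <- seq(0, 5, by = 0.05)
  a <- simulate_chromatogram(data.frame(rt = 2, height = 10, sigma = 0.1), g,
                             noise_sd = 1, seed = 11)
  b <- simulate_chromatogram(data.frame(rt = 2, height = 10, sigma = 0.1), g,
                             noise_sd = 1, seed = 11)
  c <- simulate_chromatogram(data.frame(rt = 2, height = 10, sigma = 0.1), g,
                             noise_sd = 1, seed = 12)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("cohorts carry the designed common/extra peak structure", {
  lib <- spaced_library(28)
  co <- simulate_cohort(c(YJH = 2, JH = 2), lib, common_count = 16,
                        class_extra_peaks = c(YJH = 10, JH = 2), seed = 5)
  areas <- co$peak_table$areas
  cls <- co$truth$class_labels
  # common peaks present in every sample
  expect_true(all(!is.na(areas[, co$truth$common_peak_indices])))
  # per-class observed peak counts: 16 + extras
  expect_equal(unname(rowSums(!is.na(areas))[cls == "YJH"]), rep(26, 2))
  expect_equal(unname(rowSums(!is.na(areas))[cls == "JH"]), rep(18, 2))
  # class-specific peaks never leak into the other class
  extra_cols <- setdiff(seq_len(ncol(areas)), co$truth$common_peak_indices)
  for (j in extra_cols) {
    present <- !is.na(areas[, j])
    expect_length(unique(cls[present]), 1L)
  }
  expect_true(all(co$truth$causal_peak_indices %in% co$truth$common_peak_indices))
  # determinism
  co2 <- simulate_cohort(c(YJH = 2, JH = 2), lib, common_count = 16,
                         class_extra_peaks = c(YJH = 10, JH = 2), seed = 5)
  expect_identical(co$peak_table$areas, co2$peak_table$areas)
  expect_error(simulate_cohort(c(YJH = 0, JH = 2), lib, 16), ">= 1")
  expect_error(simulate_cohort(c(YJH = 2, JH = 2), lib, 40), "exceeds")
})

test_that("bioactivity is an exact linear map when noiseless", {
  lib <- spaced_library(16)
  co <- simulate_cohort(c(YJH = 4, JH = 4), lib, common_count = 16,
                        noise_sd = 0, seed = 9)
  Y <- simulate_bioactivity(co$peak_table, co$truth)
  Xc <- co$peak_table$areas[, co$truth$causal_peak_indices]
  expect_equal(unname(Y[, 1]), unname(drop(Xc %*% co$truth$causal_weights)),
               tolerance = 1e-12)
  # all-zero weights -> constant (zero) response
  co$truth$causal_weights <- rep(0, 3)
  Y0 <- simulate_bioactivity(co$peak_table, co$truth)
  expect_true(all(Y0 == 0))
})

test_that("noisy bioactivity stays strongly correlated with its signal", {
  cors <- vapply(1:50, function(s) {
    lib <- make_peak_library(16, seed = s)
    co <- simulate_cohort(c(YJH = 4, JH = 4), lib, common_count = 16,
                          noise_sd = 0.1, seed = s)
    Y <- simulate_bioactivity(co$peak_table, co$truth)
    Xc <- co$peak_table$areas[, co$truth$causal_peak_indices]
    stats::cor(Y[, 1], drop(Xc %*% co$truth$causal_weights))
  }, numeric(1))
  expect_gt(mean(cors), 0.95)
})

test_that("dose-response generator matches the 4PL closed form", {
  d <- simulate_dose_response(ec50 = 2, hill = 1, floor = 0, ceiling = 100,
                              doses = c(2, 6))
  expect_equal(d$response[1], 50)                       # midpoint
  expect_equal(d$response[2], 100 / (1 + 2 / 6))        # = 75
  big <- simulate_dose_response(2, 1, 0, 100, doses = 1e9)
  expect_equal(big$response, 100, tolerance = 1e-6)     # ceiling limit
  expect_error(simulate_dose_response(2, doses = c(-1, 2)), "positive")
  expect_error(simulate_dose_response(-1, doses = 2), "positive")
})

test_that("metabolome generator plants its differential features", {
  sim <- simulate_metabolome(n_per_group = 20, n_features = 100,
                             n_differential = 10, fold_change = 2,
                             missing_rate = 0, cv = 0.1, seed = 21)
  expect_length(sim$truth$differential_indices, 10)
  expect_false(any(sim$table$intensities == 0))
  g <- sim$table$groups
  ratios <- vapply(sim$truth$differential_indices, function(j) {
    mean(sim$table$intensities[g == "treated", j]) /
      mean(sim$table$intensities[g == "control", j])
  }, numeric(1))
  expect_true(all(ratios > 1.8 & ratios < 2.2))
  expect_true(all(sim$table$id_score >= 0 & sim$table$id_score <= 60))
  # missingness injected at the requested rate
  sim2 <- simulate_metabolome(10, 200, 5, missing_rate = 0.2, seed = 3)
  expect_lt(abs(mean(sim2$table$intensities == 0) - 0.2), 0.02)
  expect_error(simulate_metabolome(5, 10, 20, seed = 1), "n_differential")
  expect_error(simulate_metabolome(5, 10, 2, fold_change = -1, seed = 1), "positive")
})
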