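test_that("detect_peaks finds noiseless Gaussians at their apices", {
  g <- seq(0, 20, by = 0.01)
  ch <- simulate_chromatogram(data.frame(rt = 10, height = 100, sigma = 0.1), g)
  pk <- detect_peaks(ch, min_height = 10, min_prominence = 10)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$rt, 10, tolerance = 0.011)
  # flat trace -> nothing
  expect_equal(nrow(detect_peaks(chromatogram("z", g, rep(0, length(g))))), 0L)
  # two resolved Gaussians recovered within one grid step
  ch2 <- simulate_chromatogram(data.frame(rt = c(9, 10), height = c(50, 80),
                                          sigma = c(0.1, 0.1)), g)
  pk2 <- detect_peaks(ch2, 5, 5)
  expect_equal(pk2$rt, c(9, 10), tolerance = 0.011)
  expect_error(detect_peaks(chromatogram("s", 1:2, c(0, 1))), "3 points")
})

test_that("match_peaks clusters by retention time within tolerance", {
  p1 <- data.frame(rt = 10.00, height = 5, area = 1, left = 9, right = 11)
  p2 <- data.frame(rt = 10.02, height = 5, area = 2, left = 9, right = 11)
  tab <- match_peaks(list(a = p1, b = p2), rt_tolerance = 0.1)
  expect_equal(ncol(tab$areas), 1L)
  expect_equal(unname(tab$areas[, 1]), c(1, 2))
  # beyond tolerance: two columns, one missing entry each
  p3 <- data.frame(rt = 10.5, height = 5, area = 2, left = 10, right = 11)
  tab2 <- match_peaks(list(a = p1, b = p3), rt_tolerance = 0.1)
  expect_equal(ncol(tab2$areas), 2L)
  expect_equal(sum(is.na(tab2$areas)), 2L)
  expect_error(match_peaks(list(), 0.1), "no peak lists")
})

test_that("detection + matching recover a designed cohort", {
  lib <- spaced_library(16)
  co <- simulate_cohort(c(YJH = 4, JH = 4), lib, common_count = 16,
                        jitter_sd = 0.05, chrom_noise_sd = 0.1, seed = 31)
  detected <- lapply(co$chromatograms, detect_peaks,
                     min_height = 5, min_prominence = 5)
  names(detected) <- vapply(co$chromatograms, `[[`, "", "sample_id")
  tab <- match_peaks(detected, rt_tolerance = 0.2)
  expect_equal(ncol(tab$areas), 16L)
  expect_equal(length(common_peaks(tab)), 16L)
  # column count is monotone non-increasing in the tolerance
  cols <- vapply(c(0.05, 0.1, 0.2, 0.4), function(tol) {
    ncol(match_peaks(detected, rt_tolerance = tol)$areas)
  }, integer(1))
  expect_true(all(diff(cols) <= 0))
})

test_that("median reference follows the stated median conventions", {
  g <- 1:4
  mk <- function(v, id) chromatogram(id, g, rep(v, 4))
  ref3 <- median_reference(list(mk(1, "a"), mk(5, "b"), mk(9, "c")))
  expect_equal(ref3$intensity, rep(5, 4))
  # even count: mean of the two middle values
  ref2 <- median_reference(list(mk(2, "a"), mk(4, "b")))
  expect_equal(ref2$intensity, rep(3, 4))
  # idempotent on replicated identical traces
  x <- chromatogram("x", g, c(1, 3, 2, 5))
  expect_equal(median_reference(list(x, x, x))$intensity, x$intensity)
  bad <- chromatogram("y", g + 0.5, c(1, 3, 2, 5))
  expect_error(median_reference(list(x, bad)), "different grids")
})

test_that("similarity index is the congruence coefficient", {
  g <- 1:3
  mk <- function(v) chromatogram("s", g, v)
  expect_equal(similarity_index(mk(c(1, 2, 3)), mk(c(1, 2, 3)))$similarity, 1)
  expect_equal(similarity_index(mk(c(1, 0, 0)), mk(c(0, 1, 0)))$similarity, 0)
  expect_equal(similarity_index(mk(c(1, 1, 0)), mk(c(1, 0, 0)))$similarity,
               0.7071068, tolerance = 1e-7)
  # invariant to positive rescaling
  expect_equal(similarity_index(mk(c(1, 4, 2)), mk(7 * c(2, 3, 1)))$similarity,
               similarity_index(mk(c(1, 4, 2)), mk(c(2, 3, 1)))$similarity)
  expect_error(similarity_index(mk(c(0, 0, 0)), mk(c(1, 2, 3))), "zero-norm")
})

test_that("common peaks are the fully observed columns", {
  areas <- matrix(1, 3, 4, dimnames = list(NULL, sprintf("C%d", 1:4)))
  tab <- peak_table(areas, consensus_rt = 1:4)
  expect_equal(common_peaks(tab), c(C1 = 1L, C2 = 2L, C3 = 3L, C4 = 4L),
               ignore_attr = TRUE)
  areas[2, 3] <- NA
  tab2 <- peak_table(areas, consensus_rt = 1:4)
  expect_equal(unname(common_peaks(tab2)), c(1L, 2L, 4L))
  # designed cohort: exactly the built-in common set
  lib <- spaced_library(20)
  co <- simulate_cohort(c(YJH = 3, JH = 3), lib, common_count = 16,
                        class_extra_peaks = c(YJH = 2, JH = 2), seed = 8)
  expect_equal(unname(common_peaks(co$peak_table)),
               co$truth$common_peak_indices)
})

test_that("resampling puts mixed grids onto the overlapping union grid", {
  a <- chromatogram("a", seq(0, 10, 0.5), sin(seq(0, 10, 0.5)))
  b <- chromatogram("b", seq(1, 11, 0.4), cos(seq(1, 11, 0.4)))
  rs <- resample_chromatograms(list(a, b))
  expect_identical(rs[[1]]$time, rs[[2]]$time)
  expect_gte(min(rs[[1]]$time), 1)
  expect_lte(max(rs[[1]]$time), 10)
  ref <- median_reference(rs)
  expect_s3_class(ref, "chromatogram")
})

test_that("chromatogram round-trips through long CSV", {
  dir <- withr::local_tempdir()
  g <- seq(0, 2, by = 0.1)
  chroms <- list(chromatogram("s1", g, g^2), chromatogram("s2", g, 2 * g))
  path <- file.path(dir, "chroms.csv")
  write_chromatograms(chroms, path)
  back <- read_chromatograms(path)
  expect_equal(back$s1$intensity, g^2)
  expect_equal(back$s2$intensity, 2 * g)
})
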