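make_table <- function(vals, groups, scores = NULL, ion = NULL) {
  feature_table(vals, groups = groups, id_score = scores, ion_mode = ion)
}

test_that("missingness filter applies the strict per-group rule", {
  g <- rep(c("a", "b"), each = 4)
  x <- matrix(1, 8, 3, dimnames = list(NULL, c("keep", "boundary", "drop")))
  # 'boundary': exactly 50% zeros in each group -> retained (strict rule)
  x[c(1, 2, 5, 6), 2] <- 0
  # 'drop': 75% zeros in both groups -> removed
  x[c(1, 2, 3, 5, 6, 7), 3] <- 0
  tab <- make_table(x, g)
  out <- filter_missing(tab)
  expect_equal(out$table$feature_ids, c("keep", "boundary"))
  expect_equal(out$log$features_in, 3)
  expect_equal(out$log$removed, 1)
  expect_equal(out$log$retained + out$log$removed, out$log$features_in)
})

test_that("the every/any group quantifier changes which features survive", {
  g <- rep(c("a", "b"), each = 4)
  x <- matrix(1, 8, 2, dimnames = list(NULL, c("one_group", "both_groups")))
  x[1:3, 1] <- 0  # 75% missing in group a only
  x[c(1:3, 5:7), 2] <- 0  # 75% missing in both
  tab <- make_table(x, g)
  expect_equal(filter_missing(tab, quantifier = "every")$table$feature_ids,
               "one_group")
  expect_equal(ncol(filter_missing(tab, quantifier = "any")$table$intensities),
               0L)
})

test_that("half-minimum imputation fills zeros with half the positive minimum", {
  g <- rep(c("a", "b"), each = 2)
  x <- matrix(c(0, 4, 8, 6,
                1, 2, 3, 4), 4, 2)
  tab <- make_table(x, g)
  out <- impute_half_min(tab)
  expect_equal(unname(out$intensities[1, 1]), 2)  # half of min positive 4
  expect_equal(unname(out$intensities[, 2]), x[, 2])  # untouched without zeros
  expect_false(any(out$intensities == 0))
  # random round-trip: imputed entries equal half the per-feature minima
  set.seed(5)
  x2 <- matrix(stats::rlnorm(60), 10, 6)
  x2[stats::runif(60) < 0.2] <- 0
  x2[1, ] <- 1  # guarantee a positive value everywhere
  t2 <- impute_half_min(make_table(x2, rep(c("a", "b"), each = 5)))
  for (j in 1:6) {
    zero <- x2[, j] == 0
    if (any(zero)) {
      expect_equal(unname(t2$intensities[zero, j]),
                   rep(min(x2[x2[, j] > 0, j]) / 2, sum(zero)))
    }
  }
  bad <- make_table(cbind(rep(0, 4)), rep(c("a", "b"), each = 2))
  expect_error(impute_half_min(bad), "all-missing")
})

test_that("score filter keeps 36 and above, drops below and unscored", {
  g <- rep(c("a", "b"), each = 2)
  x <- matrix(1, 4, 4)
  tab <- make_table(x, g, scores = c(36, 35.999, 60, NA))
  out <- filter_score(tab)
  expect_equal(unname(out$table$id_score), c(36, 60))
  expect_equal(out$log$removed, 2)
  expect_equal(out$log$parameters$unscored_removed, tab$feature_ids[4])
  # uniform scores: retained fraction approaches (60 - 36) / 60
  sim <- simulate_metabolome(4, 5000, 10, missing_rate = 0, seed = 77)
  frac <- ncol(filter_score(sim$table)$table$intensities) / 5000
  expect_lt(abs(frac - 24 / 60), 0.03)
})

test_that("ion-mode merging aligns samples and uniquifies feature ids", {
  g <- rep(c("a", "b"), each = 2)
  pos <- make_table(matrix(1:8, 4, 2,
                           dimnames = list(sprintf("S%d", 1:4), c("F1", "F2"))),
                    g, scores = c(40, 50))
  neg_mat <- matrix(101:104, 4, 1,
                    dimnames = list(sprintf("S%d", c(3, 4, 1, 2)), "F1"))
  neg <- make_table(neg_mat, g[c(3, 4, 1, 2)], scores = 45)
  merged <- merge_ion_modes(pos, neg)
  expect_equal(ncol(merged$intensities), 3L)
  expect_equal(merged$feature_ids, c("F1_pos", "F2_pos", "F1_neg"))
  # negative block re-ordered onto the positive sample order
  expect_equal(unname(merged$intensities[, "F1_neg"]), c(103, 104, 101, 102))
  neg2 <- make_table(matrix(1, 3, 1, dimnames = list(sprintf("S%d", 1:3), "X")),
                     g[1:3])
  expect_error(merge_ion_modes(pos, neg2), "differ")
})

test_that("the preprocessing chain runs in order and conserves counts", {
  sim <- simulate_metabolome(n_per_group = 10, n_features = 300,
                             n_differential = 10, missing_rate = 0.3,
                             seed = 42)
  out <- preprocess_features(sim$table)
  # manual truth for each rule, recomputed independently
  x <- sim$table$intensities
  g <- sim$table$groups
  frac_a <- colMeans(x[g == levels(g)[1], ] == 0)
  frac_b <- colMeans(x[g == levels(g)[2], ] == 0)
  keep1 <- !(frac_a > 0.5 & frac_b > 0.5)
  expect_equal(out$log[[1]]$retained, sum(keep1))
  keep2 <- keep1 & sim$table$id_score >= 36
  expect_equal(ncol(out$table$intensities), sum(keep2))
  expect_false(any(out$table$intensities == 0))
  for (l in out$log) {
    expect_equal(l$features_in, l$removed + l$retained)
  }
})
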