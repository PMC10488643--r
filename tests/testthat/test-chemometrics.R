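test_that("autoscale implements uv, pareto and none modes", {
  set.seed(3)
  x <- matrix(stats::rnorm(40, sd = 3), 10, 4)
  uv <- autoscale(x, "uv")
  expect_equal(unname(colMeans(uv$values)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(uv$values, 2, stats::sd)), rep(1, 4),
               tolerance = 1e-10)
  expect_equal(autoscale(x, "none", center = FALSE)$values, x)
  # pareto: centred column divided by sqrt(sd)
  x4 <- x[, 1] * 4 / stats::sd(x[, 1])  # sd exactly 4
  pa <- autoscale(cbind(x4, x[, 2]), "pareto")
  expect_equal(unname(pa$values[, 1]), (x4 - mean(x4)) / 2)
  xc <- x
  xc[, 2] <- 5
  expect_error(autoscale(xc, "uv"), "constant")
})

test_that("PCA agrees with an eigen-decomposition oracle", {
  set.seed(11)
  x <- matrix(stats::rnorm(32), 8, 4)
  m <- pca(x, n_components = 4)
  ev <- eigen(stats::cov(x))
  # scores match brute-force projection up to column sign
  xc <- scale(x, center = TRUE, scale = FALSE)
  for (a in 1:4) {
    s_oracle <- drop(xc %*% ev$vectors[, a])
    expect_equal(abs(stats::cor(m$scores[, a], s_oracle)), 1, tolerance = 1e-8)
  }
  expect_equal(sum(m$explained_variance), 1, tolerance = 1e-12)
  expect_true(all(diff(m$explained_variance) <= 1e-12))
  # collinear 2D data: PC1 explains everything
  z <- cbind(1:6, 2 * (1:6))
  expect_equal(pca(z, 1)$explained_variance[1], 1, tolerance = 1e-12)
  expect_error(pca(x, 10), "n_components")
})

test_that("NIPALS PLSR reaches the perfect-fit and OLS limits", {
  set.seed(21)
  X <- matrix(stats::rnorm(50), 10, 5)
  B <- matrix(stats::rnorm(10), 5, 2)
  Y <- X %*% B
  fit <- plsr_fit(scale(X, scale = FALSE), scale(Y, scale = FALSE), 5)
  expect_gt(fit$r2y_cum[fit$n_components], 1 - 1e-8)
  expect_true(all(diff(fit$r2y_cum) >= -1e-12))
  expect_true(all(diff(fit$r2x_cum) >= -1e-12))
  # single y, full components -> ordinary least squares
  y <- X %*% stats::rnorm(5) + stats::rnorm(10, sd = 0.3)
  Xc <- scale(X, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  f1 <- plsr_fit(Xc, yc, 5)
  b_ols <- solve(crossprod(Xc), crossprod(Xc, yc))
  expect_equal(unname(coef(f1)), unname(b_ols), tolerance = 1e-8)
  # first weight vector proportional to X'y (up to the sign convention)
  w1 <- f1$W[, 1]
  xy <- drop(crossprod(Xc, yc))
  xy <- xy / sqrt(sum(xy^2))
  if (xy[1] < 0) xy <- -xy
  expect_equal(unname(w1), unname(xy), tolerance = 1e-10)
  # deflation residuals orthogonal to extracted scores
  Xd <- Xc - tcrossprod(f1$T[, 1], f1$P[, 1])
  expect_lt(max(abs(crossprod(Xd, f1$T[, 1]))), 1e-8)
})

test_that("VIP matches its brute-force formula and normalisation", {
  set.seed(31)
  X <- matrix(stats::rnorm(100), 10, 10)
  Y <- X[, 1:2] %*% matrix(c(1, 2, -1, 0.5), 2, 2) + stats::rnorm(10, sd = 0.1)
  fit <- plsr_fit(autoscale(X), autoscale(Y), 4)
  v <- vip(fit)
  expect_equal(unname(v), vip_oracle(fit), tolerance = 1e-10)
  expect_equal(mean(v^2), 1, tolerance = 1e-10)
  expect_equal(sum(v^2), ncol(X), tolerance = 1e-8)
  # exchangeable predictors share the same VIP
  set.seed(32)
  z <- stats::rnorm(20)
  Xs <- cbind(z, z) + matrix(stats::rnorm(40, sd = 1e-8), 20, 2)
  f2 <- plsr_fit(autoscale(Xs), autoscale(matrix(z)), 1)
  expect_equal(unname(vip(f2)), c(1, 1), tolerance = 1e-3)
})

test_that("Q2 cross-validation behaves on signal, noise, and reruns", {
  set.seed(41)
  X <- matrix(stats::rnorm(20 * 8), 20, 8)
  y <- X %*% stats::rnorm(8)
  q2 <- q2_cross_validation(X, y, n_components = 4, seed = 13)
  expect_gt(q2[4], 0.95)
  expect_identical(q2, q2_cross_validation(X, y, n_components = 4, seed = 13))
  # pure-noise response: mean Q2 non-positive across seeded repeats
  q2_null <- vapply(1:100, function(s) {
    set.seed(s + 500)
    Xn <- matrix(stats::rnorm(16 * 6), 16, 6)
    yn <- stats::rnorm(16)
    q2_cross_validation(Xn, yn, n_components = 2, seed = s)[2]
  }, numeric(1))
  expect_lte(mean(q2_null), 0)
  expect_error(q2_cross_validation(X, y, 2, n_folds = 50), "exceeds")
})

test_that("OPLS-DA separates classes and its S-plot is well formed", {
  set.seed(51)
  n <- 10
  X <- rbind(matrix(stats::rnorm(n * 8, mean = 0), n, 8),
             matrix(stats::rnorm(n * 8, mean = 3), n, 8))
  cl <- rep(c("a", "b"), each = n)
  m <- oplsda_fit(X, cl, n_orthogonal = 1)
  expect_true(all(m$scores[cl == "a"] < 0) && all(m$scores[cl == "b"] > 0))
  expect_gt(m$r2y, 0.8)
  # orthogonal scores uncorrelated with the class vector
  if (m$n_orthogonal > 0) {
    expect_lt(max(abs(crossprod(m$ortho_scores, m$y))), 1e-8)
  }
  expect_true(all(abs(m$s_plot$p_corr) <= 1 + 1e-12))
  expect_equal(mean(m$vip^2), 1, tolerance = 1e-10)
  expect_error(oplsda_fit(X, rep("a", 2 * n)), "2 classes")
})

test_that("permutation p-values respect their add-one bounds", {
  set.seed(61)
  n <- 8
  X <- rbind(matrix(stats::rnorm(n * 6), n, 6),
             matrix(stats::rnorm(n * 6, mean = 4), n, 6))
  cl <- rep(c("a", "b"), each = n)
  pt <- permutation_test(X, cl, n_permutations = 200, seed = 5)
  # strongly separated classes: observed beats every permutation
  expect_equal(pt$p_r2y, 1 / 201)
  expect_equal(pt$p_q2, 1 / 201)
  expect_true(all(c(pt$p_r2y, pt$p_q2) >= 1 / 201))
  expect_true(all(c(pt$p_r2y, pt$p_q2) <= 1))
  # labels carrying no signal: p should be far from the lower bound
  set.seed(62)
  Xn <- matrix(stats::rnorm(16 * 6), 16, 6)
  ptn <- permutation_test(Xn, rep(c("a", "b"), 8), n_permutations = 50, seed = 9)
  expect_gt(ptn$p_q2, 0.05)
  expect_error(permutation_test(X, cl, n_permutations = 0), ">= 1")
})

test_that("volcano computes fold changes, Welch t and BH adjustment", {
  set.seed(71)
  g <- rep(c("a", "b"), each = 10)
  X <- matrix(stats::rlnorm(20 * 30), 20, 30)
  X[g == "b", 1] <- 2 * X[g == "a", 1]   # exact doubling
  X[, 2] <- rep(5, 20)                   # zero variance everywhere
  res <- volcano(X, g)
  expect_equal(res$fold_change[1], 2, tolerance = 1e-12)
  expect_equal(res$log2_fc[1], 1, tolerance = 1e-12)
  expect_true(is.na(res$p_value[2]) && !res$selected[2])
  expect_true(all(res$p_adjusted >= res$p_value, na.rm = TRUE))
  # agreement with stats::t.test Welch p on a random feature
  j <- 5
  expect_equal(res$p_value[j],
               stats::t.test(X[g == "b", j], X[g == "a", j])$p.value,
               tolerance = 1e-10)
  # identical group means -> zero log fold change
  X2 <- X
  X2[, 3] <- rep(c(1, 2), 10)
  res2 <- volcano(X2, g)
  expect_equal(res2$log2_fc[3], 0, tolerance = 1e-12)
})

test_that("volcano recovers planted differential features", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_metabolome(n_per_group = 20, n_features = 120,
                               n_differential = 10, fold_change = 2,
                               missing_rate = 0, cv = 0.25, seed = s)
    res <- volcano(sim$table)
    mean(res$selected[sim$truth$differential_indices])
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("hierarchical clustering merges nearest rows first", {
  x <- matrix(c(0, 1, 10), ncol = 1)
  hc <- hierarchical_clustering(x)
  expect_equal(sort(-hc$tree$merge[1, ]), c(1, 2))  # {0, 1} merge first
  # identical rows merge at height zero
  x2 <- rbind(c(1, 2), c(1, 2), c(9, 9))
  hc2 <- hierarchical_clustering(x2)
  expect_equal(hc2$merge_heights[1], 0)
  # permuting rows relabels but preserves merge heights
  x3 <- matrix(stats::rnorm(20), 5, 4)
  h_a <- hierarchical_clustering(x3)
  h_b <- hierarchical_clustering(x3[5:1, ])
  expect_equal(h_a$merge_heights, h_b$merge_heights)
  expect_error(hierarchical_clustering(matrix(c(1, NA, 2, 3), 2, 2)),
               "non-finite")
})
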