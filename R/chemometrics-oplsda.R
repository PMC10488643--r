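# Discriminant stage for the metabolomics branch: OPLS-DA with S-plot
# statistics, label-permutation testing of R2Y/Q2, per-feature volcano
# statistics (Welch t, fold change, BH adjustment, VIP gating), and
# hierarchical clustering of selected features.

class_vector <- function(class_labels) {
  f <- factor(class_labels)
  if (nlevels(f) != 2L) {
    stop_input("exactly 2 classes are required (got %d: %s)", nlevels(f),
               paste(levels(f), collapse = ", "))
  }
  y <- ifelse(f == levels(f)[2L], 1, -1)
  list(y = y - mean(y), levels = levels(f), raw = y)
}

# core extraction on an already scaled X and centred y
oplsda_core <- function(X, y, n_orthogonal) {
  w <- drop(crossprod(X, y))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-14) stop_input("X carries no class-correlated variation")
  w <- w / nw * sign_fix(w / nw)
  Xc <- X
  Wo <- Po <- NULL
  To <- NULL
  if (n_orthogonal > 0) {
    Wo <- matrix(0, ncol(X), n_orthogonal)
    Po <- matrix(0, ncol(X), n_orthogonal)
    To <- matrix(0, nrow(X), n_orthogonal)
    for (o in seq_len(n_orthogonal)) {
      t <- drop(Xc %*% w)
      p <- drop(crossprod(Xc, t)) / sum(t^2)
      w_o <- p - sum(w * p) * w
      nwo <- sqrt(sum(w_o^2))
      if (nwo < 1e-12) {  # no orthogonal variation left
        Wo <- Wo[, seq_len(o - 1L), drop = FALSE]
        Po <- Po[, seq_len(o - 1L), drop = FALSE]
        To <- To[, seq_len(o - 1L), drop = FALSE]
        break
      }
      w_o <- w_o / nwo * sign_fix(w_o / nwo)
      t_o <- drop(Xc %*% w_o)
      p_o <- drop(crossprod(Xc, t_o)) / sum(t_o^2)
      Wo[, o] <- w_o
      Po[, o] <- p_o
      To[, o] <- t_o
      Xc <- Xc - tcrossprod(t_o, p_o)
    }
  }
  t <- drop(Xc %*% w)
  p <- drop(crossprod(Xc, t)) / sum(t^2)
  b <- sum(t * y) / sum(t^2)
  list(w = w, p = p, t = t, b = b, Wo = Wo, Po = Po, To = To, Xcorr = Xc)
}

#' Fit a two-class OPLS-DA model
#'
#' One predictive component plus `n_orthogonal` components carrying
#' class-orthogonal X-variation (Trygg-Wold algorithm).  Classes are coded
#' -1/+1 (second factor level positive) and centred.
#'
#' @param x Raw feature matrix (samples x variables).
#' @param class_labels Two-level factor/character vector, one per sample.
#' @param n_orthogonal Number of orthogonal components (>= 0).
#' @param scale Column scaling mode (see [autoscale()]); `"uv"` default.
#' @return Object of class `oplsda_model` with predictive scores/loadings,
#'   orthogonal scores/loadings, `r2x`, `r2y`, per-variable `vip`, and S-plot
#'   coordinates `s_plot` (`p_cov`, `p_corr`).
#' @export
oplsda_fit <- function(x, class_labels, n_orthogonal = 1L, scale = "uv") {
  X0 <- check_matrix(x)
  cl <- class_vector(class_labels)
  if (nrow(X0) != length(cl$y)) stop_input("one class label per sample is required")
  xs <- autoscale(X0, mode = scale)
  X <- xs$values
  fit <- oplsda_core(X, cl$y, n_orthogonal)
  yhat <- fit$t * fit$b
  r2y <- 1 - sum((cl$y - yhat)^2) / sum(cl$y^2)
  ssx <- sum(X^2)
  r2x_pred <- sum(fit$t^2) * sum(fit$p^2) / ssx
  r2x_orth <- if (is.null(fit$To) || ncol(fit$To) == 0L) 0 else {
    sum(vapply(seq_len(ncol(fit$To)), function(o) {
      sum(fit$To[, o]^2) * sum(fit$Po[, o]^2)
    }, numeric(1))) / ssx
  }
  p_var <- ncol(X)
  vip <- sqrt(p_var) * abs(fit$w)
  t <- fit$t
  n <- length(t)
  p_cov <- drop(crossprod(X, t)) / (n - 1)
  sds <- apply(X, 2L, stats::sd)
  p_corr <- p_cov / (stats::sd(t) * sds)
  p_corr[sds == 0] <- NA_real_
  ids <- colnames(X0)
  if (is.null(ids)) ids <- sprintf("X%d", seq_len(p_var))
  structure(list(weights = stats::setNames(fit$w, ids),
                 loadings = stats::setNames(fit$p, ids),
                 scores = fit$t, b = fit$b,
                 ortho_weights = fit$Wo, ortho_loadings = fit$Po,
                 ortho_scores = fit$To,
                 r2y = r2y, r2x_pred = r2x_pred, r2x_ortho = r2x_orth,
                 vip = stats::setNames(vip, ids),
                 s_plot = data.frame(feature = ids, p_cov = p_cov,
                                     p_corr = p_corr),
                 class_levels = cl$levels, y = cl$y,
                 x_center = xs$center, x_scale = xs$scale,
                 scale_mode = scale,
                 n_orthogonal = if (is.null(fit$To)) 0L else ncol(fit$To)),
            class = "oplsda_model")
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf("<oplsda_model> 1 predictive + %d orthogonal: R2Y = %.3f (%s vs %s)\n",
              x$n_orthogonal, x$r2y, x$class_levels[1], x$class_levels[2]))
  invisible(x)
}

#' Predict class scores from a fitted OPLS-DA model
#'
#' @param object An `oplsda_model`.
#' @param newdata Raw feature matrix on the training variables.
#' @param ... Unused.
#' @return Numeric vector of predicted class values (negative = first level).
#' @export
predict.oplsda_model <- function(object, newdata, ...) {
  X <- sweep(sweep(check_matrix(newdata), 2L, object$x_center, "-"),
             2L, object$x_scale, "/")
  if (!is.null(object$ortho_weights) && ncol(object$ortho_weights) > 0) {
    for (o in seq_len(ncol(object$ortho_weights))) {
      t_o <- drop(X %*% object$ortho_weights[, o])
      X <- X - tcrossprod(t_o, object$ortho_loadings[, o])
    }
  }
  drop(X %*% object$weights) * object$b
}

oplsda_q2 <- function(x, class_labels, n_orthogonal = 1L, n_folds = 7L,
                      scale = "uv", seed = 1L) {
  X <- check_matrix(x)
  cl <- class_vector(class_labels)
  n <- nrow(X)
  n_folds <- min(n_folds, n)
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  press <- 0
  ss <- 0
  for (f in seq_len(n_folds)) {
    test <- folds == f
    ytr <- cl$raw[!test]
    if (length(unique(ytr)) < 2L) next  # degenerate training fold
    fit <- oplsda_fit(X[!test, , drop = FALSE],
                      factor(cl$raw, levels = c(-1, 1))[!test],
                      n_orthogonal = n_orthogonal, scale = scale)
    pred <- predict(fit, X[test, , drop = FALSE]) + mean(ytr)
    press <- press + sum((cl$raw[test] - pred)^2)
    ss <- ss + sum((cl$raw[test] - mean(ytr))^2)
  }
  1 - press / ss
}

#' Label-permutation test for an OPLS-DA model
#'
#' Refits the model under `n_permutations` seeded random relabelings and
#' reports add-one permutation p-values for both R2Y and cross-validated Q2:
#' `p = (1 + #[permuted >= observed]) / (1 + n_permutations)`, so the
#' smallest attainable p with 200 permutations is 1/201.
#'
#' @param x Raw feature matrix.
#' @param class_labels Two-level class vector.
#' @param n_permutations Number of label permutations (>= 1).
#' @param seed Seed driving the permutations and the CV fold assignment.
#' @param n_orthogonal,n_folds,scale Passed to the model/Q2 computation.
#' @return List with observed `r2y` and `q2`, permuted statistics, and
#'   p-values `p_r2y`, `p_q2`.
#' @export
permutation_test <- function(x, class_labels, n_permutations = 200L, seed = 1L,
                             n_orthogonal = 1L, n_folds = 7L, scale = "uv") {
  if (n_permutations < 1L) stop_input("n_permutations must be >= 1")
  X <- check_matrix(x)
  obs_fit <- oplsda_fit(X, class_labels, n_orthogonal = n_orthogonal, scale = scale)
  obs_q2 <- oplsda_q2(X, class_labels, n_orthogonal = n_orthogonal,
                      n_folds = n_folds, scale = scale, seed = seed)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      lab <- sample(class_labels)
      r2 <- tryCatch(oplsda_fit(X, lab, n_orthogonal = n_orthogonal,
                                scale = scale)$r2y,
                     error = function(e) NA_real_)
      q2 <- tryCatch(oplsda_q2(X, lab, n_orthogonal = n_orthogonal,
                               n_folds = n_folds, scale = scale, seed = seed),
                     error = function(e) NA_real_)
      c(r2, q2)
    }, numeric(2))
  })
  r2_perm <- perm[1L, ]
  q2_perm <- perm[2L, ]
  list(r2y = obs_fit$r2y, q2 = obs_q2,
       r2y_permuted = r2_perm, q2_permuted = q2_perm,
       p_r2y = (1 + sum(r2_perm >= obs_fit$r2y, na.rm = TRUE)) / (1 + n_permutations),
       p_q2 = (1 + sum(q2_perm >= obs_q2, na.rm = TRUE)) / (1 + n_permutations),
       n_permutations = n_permutations)
}

#' Volcano statistics with VIP gating
#'
#' Per-feature Welch t-test between the two groups, group-mean fold change
#' (second level over first), Benjamini-Hochberg adjusted p-values, OPLS-DA
#' VIP, and a selection flag `VIP > vip_threshold AND p < alpha` (raw p, as
#' in common metabolomics practice; the adjusted p is reported alongside).
#'
#' @param table A [feature_table()] (groups taken from it) or a plain matrix.
#' @param groups Two-level group vector; defaults to `table$groups`.
#' @param alpha Raw-p significance threshold.
#' @param vip_threshold VIP threshold.
#' @param scale Scaling for the internal OPLS-DA.  Unit variance by default:
#'   on raw (unlogged) intensity tables pareto scaling lets high-abundance
#'   features swamp the VIP spectrum; pareto remains available.
#' @param n_orthogonal Orthogonal components for the internal OPLS-DA.
#' @return Data frame of class `differential_result`: `feature`,
#'   `fold_change`, `log2_fc`, `t_stat`, `p_value`, `p_adjusted`, `vip`,
#'   `selected`.  Features with zero variance in both groups get `NA`
#'   statistics and are never selected.
#' @export
volcano <- function(table, groups = NULL, alpha = 0.05, vip_threshold = 1.0,
                    scale = "uv", n_orthogonal = 1L) {
  if (inherits(table, "feature_table")) {
    X <- table$intensities
    if (is.null(groups)) groups <- table$groups
  } else {
    X <- check_matrix(table)
  }
  g <- factor(groups)
  if (nlevels(g) != 2L) stop_input("volcano needs exactly 2 groups")
  if (any(tabulate(g) < 2L)) stop_input("both groups need >= 2 samples")
  i1 <- g == levels(g)[1L]
  i2 <- g == levels(g)[2L]
  n1 <- sum(i1)
  n2 <- sum(i2)
  m1 <- colMeans(X[i1, , drop = FALSE])
  m2 <- colMeans(X[i2, , drop = FALSE])
  v1 <- apply(X[i1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(X[i2, , drop = FALSE], 2L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- ifelse(se2 > 0, (m2 - m1) / sqrt(se2), NA_real_)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  fc <- m2 / m1
  # constant features carry no class information: exclude from the model,
  # report NA importance
  informative <- apply(X, 2L, stats::sd) > 0
  v <- rep(NA_real_, ncol(X))
  v[informative] <- oplsda_fit(X[, informative, drop = FALSE], g,
                               n_orthogonal = n_orthogonal,
                               scale = scale)$vip
  ids <- colnames(X)
  if (is.null(ids)) ids <- sprintf("M%d", seq_len(ncol(X)))
  out <- data.frame(feature = ids,
                    fold_change = fc,
                    log2_fc = log2(fc),
                    t_stat = t_stat,
                    p_value = p,
                    p_adjusted = stats::p.adjust(p, method = "BH"),
                    vip = unname(v),
                    row.names = NULL)
  out$selected <- !is.na(out$p_value) & out$p_value < alpha &
    !is.na(out$vip) & out$vip > vip_threshold
  class(out) <- c("differential_result", class(out))
  out
}

#' Hierarchical clustering of a feature matrix
#'
#' Agglomerative clustering (Ward's criterion on Euclidean distances by
#' default) via [stats::hclust()], which merges the lowest-index pair on
#' ties, making the tree and leaf order deterministic.
#'
#' @param x Numeric matrix with finite entries (rows are clustered).
#' @param linkage `"ward"` (mapped to `ward.D2`), or any [stats::hclust()]
#'   method name.
#' @param metric Distance metric for [stats::dist()].
#' @return List with the `tree` (an `hclust` object), `leaf_order` and
#'   `merge_heights`.
#' @export
hierarchical_clustering <- function(x, linkage = "ward", metric = "euclidean") {
  x <- check_matrix(x)
  if (nrow(x) < 2L) stop_input("need at least 2 rows to cluster")
  if (any(!is.finite(x))) stop_input("matrix contains non-finite entries")
  method <- if (identical(linkage, "ward")) "ward.D2" else linkage
  hc <- stats::hclust(stats::dist(x, method = metric), method = method)
  list(tree = hc, leaf_order = hc$order, merge_heights = hc$height)
}
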