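# Multivariate core: column scaling, PCA by SVD, NIPALS partial least-squares
# regression with R2X/R2Y bookkeeping, VIP scores, and cross-validated Q2.
#
# All latent-variable extraction follows a fixed sign convention (first
# element of each weight/loading vector non-negative) so results, and the
# tests, are sign-stable.

#' Centre and scale a data matrix
#'
#' @param x Numeric matrix (>= 2 rows).
#' @param mode `"uv"` (unit variance), `"pareto"` (divide by the square root
#'   of the column standard deviation) or `"none"`.  All modes centre.
#' @param center Centre columns first (default `TRUE`).
#' @return Object of class `scaled_matrix`: `values`, `center`, `scale`,
#'   `mode`.
#' @export
autoscale <- function(x, mode = c("uv", "pareto", "none"), center = TRUE) {
  mode <- match.arg(mode)
  x <- check_matrix(x)
  if (nrow(x) < 2L) stop_input("autoscale needs at least 2 rows")
  ctr <- if (center) colMeans(x) else rep(0, ncol(x))
  sds <- apply(x, 2L, stats::sd)
  scl <- switch(mode,
                uv = sds,
                pareto = sqrt(sds),
                none = rep(1, ncol(x)))
  if (mode != "none" && any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    if (mode == "uv") {
      stop_input("constant column(s) under unit-variance scaling: %s",
                 paste(bad, collapse = ", "))
    }
    scl[sds == 0] <- 1  # pareto: a constant, centred column is all zero anyway
  }
  vals <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
  structure(list(values = vals, center = ctr, scale = scl, mode = mode),
            class = "scaled_matrix")
}

as_values <- function(x) {
  if (inherits(x, "scaled_matrix")) x$values else check_matrix(x)
}

# flip the sign of a component so the first (largest-magnitude tie-safe)
# criterion is deterministic: first element of w non-negative
sign_fix <- function(w) if (w[1L] < 0) -1 else 1

#' Principal component analysis by singular value decomposition
#'
#' @param x Numeric matrix or [autoscale()] result.  Plain matrices are
#'   centred (not scaled) before decomposition.
#' @param n_components Number of components (<= `min(nrow - 1, ncol)`).
#' @return List of class `pca_model`: `scores`, `loadings`,
#'   `explained_variance` (ratios over all possible components), `center`.
#' @export
pca <- function(x, n_components = 2L) {
  scaled_input <- inherits(x, "scaled_matrix")
  v <- as_values(x)
  if (!scaled_input) v <- scale(v, center = TRUE, scale = FALSE)
  n_max <- min(nrow(v) - 1L, ncol(v))
  if (n_components < 1L || n_components > n_max) {
    stop_input("n_components must be in [1, %d]", n_max)
  }
  sv <- svd(v)
  flip <- apply(sv$v, 2L, sign_fix)
  scores <- sweep(sv$u %*% diag(sv$d, length(sv$d)), 2L, flip, "*")
  loadings <- sweep(sv$v, 2L, flip, "*")
  expl <- sv$d^2 / sum(sv$d^2)
  structure(list(scores = scores[, seq_len(n_components), drop = FALSE],
                 loadings = loadings[, seq_len(n_components), drop = FALSE],
                 explained_variance = expl,
                 center = attr(v, "scaled:center")),
            class = "pca_model")
}

#' Fit a PLSR model by NIPALS
#'
#' Nonlinear iterative partial least squares with X- and Y-deflation.
#' Per-component and cumulative fractions of explained X- and Y-variance
#' (R2X, R2Y) are recorded, as is the explained Y sum of squares per
#' component used by [vip()].
#'
#' @param x Predictor matrix or [autoscale()] result (samples x variables).
#' @param y Response matrix/vector or [autoscale()] result.
#' @param n_components Number of latent components (>= 1).
#' @param tol NIPALS convergence tolerance on the score vector.
#' @param max_iter Maximum NIPALS iterations per component.
#' @return Object of class `plsr_model` with weights `W`, loadings `P`,
#'   Y-loadings `C`, scores `T`, `r2x`, `r2y` (per component and cumulative),
#'   `ssy_explained`, and the matrices needed for prediction.
#' @export
plsr_fit <- function(x, y, n_components, tol = 1e-10, max_iter = 2000L) {
  X <- as_values(x)
  Y <- as_values(y)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  if (nrow(X) != nrow(Y)) stop_input("x and y must have the same number of rows")
  if (n_components < 1L) stop_input("n_components must be >= 1")
  n <- nrow(X)
  p <- ncol(X)
  m <- ncol(Y)
  ssx_tot <- sum(X^2)
  ssy_tot <- sum(Y^2)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  C <- matrix(0, m, n_components)
  Tm <- matrix(0, n, n_components)
  r2x <- r2y <- ssy_a <- numeric(n_components)
  conv <- rep(TRUE, n_components)
  Xd <- X
  Yd <- Y
  for (a in seq_len(n_components)) {
    if (sum(Yd^2) < 1e-12 * max(ssy_tot, 1)) {
      # Y residual exhausted: remaining components explain nothing
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      C <- C[, seq_len(a - 1L), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1L), drop = FALSE]
      r2x <- r2x[seq_len(a - 1L)]
      r2y <- r2y[seq_len(a - 1L)]
      ssy_a <- ssy_a[seq_len(a - 1L)]
      conv <- conv[seq_len(a - 1L)]
      n_components <- a - 1L
      break
    }
    u <- Yd[, which.max(colSums(Yd^2)), drop = TRUE]
    t_old <- rep(Inf, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      t <- drop(Xd %*% w)
      c <- crossprod(Yd, t) / sum(t^2)
      if (m == 1L) {  # single y: NIPALS converges in one pass
        converged <- TRUE
        break
      }
      u <- drop(Yd %*% c) / sum(c^2)
      if (sqrt(sum((t - t_old)^2)) < tol * sqrt(sum(t^2))) {
        converged <- TRUE
        break
      }
      t_old <- t
    }
    if (!converged && m > 1L) {
      # near-degenerate eigenvalues slow the power iteration; the extracted
      # component is still usable, so flag rather than fail
      warning(sprintf("NIPALS did not fully converge for component %d after %d iterations",
                      a, max_iter), call. = FALSE)
    }
    conv[a] <- converged || m == 1L
    s <- sign_fix(w)
    w <- w * s
    t <- t * s
    c <- c * s
    pp <- crossprod(Xd, t) / sum(t^2)
    W[, a] <- w
    P[, a] <- pp
    C[, a] <- c
    Tm[, a] <- t
    r2x[a] <- sum(t^2) * sum(pp^2) / ssx_tot
    ssy_a[a] <- sum(t^2) * sum(c^2)
    r2y[a] <- ssy_a[a] / ssy_tot
    Xd <- Xd - tcrossprod(t, pp)
    Yd <- Yd - tcrossprod(t, c)
  }
  rn <- if (!is.null(colnames(X))) colnames(X) else sprintf("X%d", seq_len(p))
  rownames(W) <- rownames(P) <- rn
  structure(list(W = W, P = P, C = C, T = Tm,
                 n_components = n_components,
                 r2x = r2x, r2x_cum = cumsum(r2x),
                 r2y = r2y, r2y_cum = cumsum(r2y),
                 ssy_explained = ssy_a,
                 converged = conv,
                 x_center = if (inherits(x, "scaled_matrix")) x$center else NULL,
                 x_scale = if (inherits(x, "scaled_matrix")) x$scale else NULL,
                 y_center = if (inherits(y, "scaled_matrix")) y$center else NULL,
                 y_scale = if (inherits(y, "scaled_matrix")) y$scale else NULL),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d component(s): R2X(cum) = %.3f, R2Y(cum) = %.3f\n",
              x$n_components,
              x$r2x_cum[x$n_components], x$r2y_cum[x$n_components]))
  invisible(x)
}

#' Regression coefficients of a fitted PLSR model
#'
#' `B = W (P'W)^-1 C'`, mapping the (scaled) X space to the (scaled) Y space.
#'
#' @param object A `plsr_model`.
#' @param ... Unused.
#' @return p x m coefficient matrix.
#' @export
coef.plsr_model <- function(object, ...) {
  object$W %*% solve(crossprod(object$P, object$W), t(object$C))
}

#' Predict from a fitted PLSR model
#'
#' @param object A `plsr_model`.
#' @param newdata Matrix of predictors on the original (unscaled) X scale if
#'   the model was fitted on an [autoscale()] result, otherwise on the scale
#'   used at fit time.
#' @param ... Unused.
#' @return Predicted Y matrix, back-transformed to the original Y scale when
#'   scaling information is available.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  X <- check_matrix(newdata)
  if (!is.null(object$x_center)) {
    X <- sweep(sweep(X, 2L, object$x_center, "-"), 2L, object$x_scale, "/")
  }
  Yhat <- X %*% coef(object)
  if (!is.null(object$y_center)) {
    Yhat <- sweep(sweep(Yhat, 2L, object$y_scale, "*"), 2L, object$y_center, "+")
  }
  Yhat
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt( p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a )` where
#' `SSY_a` is the Y sum of squares explained by component `a`.  The mean of
#' the squared VIPs is 1 by construction, so VIP > 1 flags variables that
#' contribute more than an average share to the explained Y-variance.
#'
#' @param model A fitted `plsr_model`.
#' @return Named numeric vector of VIP scores, one per X variable.
#' @export
vip <- function(model) {
  ssy <- model$ssy_explained
  if (sum(ssy) <= 0) stop_input("model explains no Y-variance; VIP undefined")
  p <- nrow(model$W)
  w2 <- sweep(model$W^2, 2L, colSums(model$W^2), "/")
  out <- sqrt(p * drop(w2 %*% ssy) / sum(ssy))
  stats::setNames(out, rownames(model$W))
}

#' Cross-validated Q2 for a PLSR model
#'
#' Sevenfold (by default) cross-validation: folds are assigned by a seeded
#' random permutation, each held-out fold is predicted from a model fitted on
#' the remainder (centring/scaling re-estimated on the training fold), and
#' `Q2 = 1 - PRESS/SS` is accumulated per cumulative component count.  `SS`
#' is the sum of squares about the training-fold Y means.
#'
#' @param x,y Raw predictor and response matrices (unscaled).
#' @param n_components Maximum number of components to evaluate.
#' @param n_folds Number of folds (<= number of rows).
#' @param scale Scaling mode applied within each training fold.
#' @param seed Seed for the fold assignment.
#' @return Numeric vector `q2[a]` for models with `a = 1..n_components`
#'   components.
#' @export
q2_cross_validation <- function(x, y, n_components, n_folds = 7L,
                                scale = "uv", seed = 1L) {
  X <- check_matrix(x)
  Y <- check_matrix(y)
  if (is.null(dim(y))) Y <- matrix(as.numeric(y), ncol = 1L)
  n <- nrow(X)
  if (n_folds > n) stop_input("n_folds (%d) exceeds sample count (%d)", n_folds, n)
  if (n_folds < 2L) stop_input("need at least 2 folds")
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  press <- rep(0, n_components)
  ss <- 0
  for (f in seq_len(n_folds)) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]
    Ytr <- Y[!test, , drop = FALSE]
    keep <- apply(Xtr, 2L, stats::sd) > 0
    xs <- autoscale(Xtr[, keep, drop = FALSE], mode = scale)
    ys <- autoscale(Ytr, mode = "none")
    a_max <- min(n_components, nrow(Xtr) - 1L, sum(keep))
    fit <- suppressWarnings(plsr_fit(xs, ys, n_components = a_max))
    a_max <- fit$n_components
    Xte <- sweep(sweep(X[test, keep, drop = FALSE], 2L, xs$center, "-"),
                 2L, xs$scale, "/")
    Yte <- Y[test, , drop = FALSE]
    ss <- ss + sum(sweep(Yte, 2L, ys$center, "-")^2)
    for (a in seq_len(n_components)) {
      aa <- min(a, a_max)
      Wa <- fit$W[, seq_len(aa), drop = FALSE]
      Pa <- fit$P[, seq_len(aa), drop = FALSE]
      Ca <- fit$C[, seq_len(aa), drop = FALSE]
      B <- Wa %*% solve(crossprod(Pa, Wa), t(Ca))
      pred <- sweep(Xte %*% B, 2L, ys$center, "+")
      press[a] <- press[a] + sum((Yte - pred)^2)
    }
  }
  1 - press / ss
}
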