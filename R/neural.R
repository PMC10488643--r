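# Single-hidden-layer back-propagation network trained by damped Gauss-Newton
# (Levenberg-Marquardt): weight update
#   x[k+1] = x[k] - (J'J + mu I)^-1 J' e
# with J the Jacobian of the residual vector e with respect to the flattened
# weights, and mu adapted by the classical accept/reject schedule.  Garson's
# weight-partition algorithm turns the trained weights into per-input
# contribution ratios.

unpack_weights <- function(net) {
  ni <- net$n_in; nh <- net$n_hidden; no <- net$n_out
  w <- net$weights
  i <- 0L
  W1 <- matrix(w[i + seq_len(nh * ni)], nh, ni); i <- i + nh * ni
  b1 <- w[i + seq_len(nh)]; i <- i + nh
  W2 <- matrix(w[i + seq_len(no * nh)], no, nh); i <- i + no * nh
  b2 <- w[i + seq_len(no)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

#' Initialise a single-hidden-layer network
#'
#' The flat weight vector stores, in order: hidden weights `W1`
#' (`n_hidden x n_in`, column-major), hidden biases `b1`, output weights
#' `W2` (`n_out x n_hidden`, column-major), output biases `b2` — a total of
#' `(n_in + 1) * n_hidden + (n_hidden + 1) * n_out` entries.
#'
#' @param n_in,n_hidden,n_out Layer sizes (all >= 1).
#' @param seed Integer seed for the small uniform initial weights.
#' @param activation Hidden-layer activation: `"tanh"` (default) or
#'   `"identity"` (useful for testing against linear least squares).
#' @return Object of class `bpann`.
#' @export
init_network <- function(n_in, n_hidden, n_out = 1L, seed = 1L,
                         activation = c("tanh", "identity")) {
  activation <- match.arg(activation)
  if (n_in < 1 || n_hidden < 1 || n_out < 1) {
    stop_input("all layer sizes must be >= 1")
  }
  n_w <- (n_in + 1L) * n_hidden + (n_hidden + 1L) * n_out
  w <- with_seed(seed, stats::runif(n_w, -0.5, 0.5) / sqrt(n_in + 1))
  structure(list(weights = w, n_in = n_in, n_hidden = n_hidden,
                 n_out = n_out, activation = activation),
            class = "bpann")
}

#' @export
print.bpann <- function(x, ...) {
  cat(sprintf("<bpann> %d-%d-%d (%s hidden), %d weights\n",
              x$n_in, x$n_hidden, x$n_out, x$activation, length(x$weights)))
  invisible(x)
}

#' Forward pass of the network
#'
#' @param net A `bpann`.
#' @param x Input matrix (samples x n_in).
#' @return Output matrix (samples x n_out).
#' @export
ann_forward <- function(net, x) {
  x <- check_matrix(x)
  p <- unpack_weights(net)
  A <- sweep(x %*% t(p$W1), 2L, p$b1, "+")
  H <- if (net$activation == "tanh") tanh(A) else A
  sweep(H %*% t(p$W2), 2L, p$b2, "+")
}

# residual vector e = vec(yhat - y) (output-major) and its Jacobian J,
# restricted to the `trainable` weight indices
ann_residual_jacobian <- function(net, x, y, trainable = NULL) {
  x <- check_matrix(x)
  y <- check_matrix(y)
  p <- unpack_weights(net)
  n <- nrow(x)
  ni <- net$n_in; nh <- net$n_hidden; no <- net$n_out
  A <- sweep(x %*% t(p$W1), 2L, p$b1, "+")
  if (net$activation == "tanh") {
    H <- tanh(A)
    D <- 1 - H^2
  } else {
    H <- A
    D <- matrix(1, n, nh)
  }
  yhat <- sweep(H %*% t(p$W2), 2L, p$b2, "+")
  e <- as.vector(yhat - y)
  n_w <- length(net$weights)
  J <- matrix(0, n * no, n_w)
  for (k in seq_len(no)) {
    rows <- (k - 1L) * n + seq_len(n)
    # d yhat_k / d W1[j, m] = W2[k, j] * D[, j] * x[, m]
    G <- sweep(D, 2L, p$W2[k, ], "*")          # n x nh
    for (m in seq_len(ni)) {
      J[rows, (m - 1L) * nh + seq_len(nh)] <- G * x[, m]
    }
    J[rows, nh * ni + seq_len(nh)] <- G        # b1
    off <- nh * ni + nh
    for (j in seq_len(nh)) {                   # W2 column-major: (k, j)
      J[rows, off + (j - 1L) * no + k] <- H[, j]
    }
    J[rows, off + no * nh + k] <- 1            # b2
  }
  if (!is.null(trainable)) J <- J[, trainable, drop = FALSE]
  list(e = e, J = J, sse = sum(e^2))
}

#' One Levenberg-Marquardt weight update
#'
#' Applies `delta = -(J'J + mu I)^-1 J' e` to the (trainable) weights and
#' returns the updated network with the new residual norm.  The damping
#' factor is not adapted here; [ann_train()] owns the accept/reject schedule.
#'
#' @param net A `bpann`.
#' @param x,y Training inputs and targets.
#' @param mu Damping factor (> 0).
#' @param trainable Optional integer indices of weights to update (others are
#'   frozen); default all.
#' @return List with `net` (updated), `sse_old`, `sse_new` and `delta`.
#' @export
lm_step <- function(net, x, y, mu, trainable = NULL) {
  if (mu <= 0) stop_input("mu must be positive")
  rj <- ann_residual_jacobian(net, x, y, trainable)
  A <- crossprod(rj$J)
  diag(A) <- diag(A) + mu
  delta <- tryCatch(-solve(A, crossprod(rj$J, rj$e)),
                    error = function(e) {
                      stop_input("normal equations singular despite damping; increase mu")
                    })
  if (any(!is.finite(delta))) stop_input("non-finite LM step; increase mu")
  new_net <- net
  idx <- if (is.null(trainable)) seq_along(net$weights) else trainable
  new_net$weights[idx] <- net$weights[idx] + drop(delta)
  rj_new <- ann_residual_jacobian(new_net, x, y, trainable)
  list(net = new_net, sse_old = rj$sse, sse_new = rj_new$sse,
       delta = drop(delta))
}

#' Train the network by Levenberg-Marquardt with early stopping
#'
#' Samples are partitioned into training/validation/test sets by a seeded
#' random split.  Inputs and targets are standardised on the training set;
#' reported mean squared errors are on that standardised scale.  A proposed
#' LM step is accepted when it lowers the training SSE (mu is divided by 10),
#' otherwise rejected and retried with mu multiplied by 10; training stops at
#' `max_iter` accepted steps, when mu escalates past `mu_max`, or when the
#' validation MSE has not improved for `patience` accepted steps.  Weights
#' with the best validation MSE are returned.
#'
#' @param net A `bpann` (e.g. from [init_network()]).
#' @param x,y Full data matrices (samples x n_in / n_out).
#' @param split Fractions for train/validation/test; must sum to 1.
#' @param max_iter Maximum accepted iterations.
#' @param patience Early-stopping patience on the validation MSE.
#' @param mu0,mu_max Initial and maximal damping factor.
#' @param seed Seed for the split assignment.
#' @return List of class `bpann_fit`: `net` (best-validation weights),
#'   `mse` (named train/validation/test triple), `trace` (accepted-step
#'   training MSE, non-increasing), `split_index`, and the standardisation
#'   parameters.
#' @export
ann_train <- function(net, x, y, split = c(0.70, 0.15, 0.15),
                      max_iter = 100L, patience = 10L,
                      mu0 = 1e-3, mu_max = 1e10, seed = 1L) {
  x <- check_matrix(x)
  y <- check_matrix(y)
  if (abs(sum(split) - 1) > 1e-8) stop_input("split fractions must sum to 1")
  n <- nrow(x)
  n_tr <- round(split[1] * n)
  n_val <- round(split[2] * n)
  n_te <- n - n_tr - n_val
  if (n_tr < 1 || n_val < 1 || n_te < 1) {
    stop_input("split leaves an empty subset (n = %d -> %d/%d/%d)",
               n, n_tr, n_val, n_te)
  }
  idx <- with_seed(seed, sample.int(n))
  set <- rep("test", n)
  set[idx[seq_len(n_tr)]] <- "train"
  set[idx[n_tr + seq_len(n_val)]] <- "validation"

  xc <- colMeans(x[set == "train", , drop = FALSE])
  xs <- apply(x[set == "train", , drop = FALSE], 2L, stats::sd)
  xs[xs == 0] <- 1
  yc <- colMeans(y[set == "train", , drop = FALSE])
  ys <- apply(y[set == "train", , drop = FALSE], 2L, stats::sd)
  ys[ys == 0] <- 1
  Xs <- sweep(sweep(x, 2L, xc, "-"), 2L, xs, "/")
  Ys <- sweep(sweep(y, 2L, yc, "-"), 2L, ys, "/")
  Xtr <- Xs[set == "train", , drop = FALSE]
  Ytr <- Ys[set == "train", , drop = FALSE]

  mse_of <- function(nt, which) {
    d <- ann_forward(nt, Xs[set == which, , drop = FALSE]) -
      Ys[set == which, , drop = FALSE]
    mean(d^2)
  }
  mu <- mu0
  trace <- mean((ann_forward(net, Xtr) - Ytr)^2)
  best_val <- mse_of(net, "validation")
  best_net <- net
  stall <- 0L
  iter <- 0L
  while (iter < max_iter) {
    step <- tryCatch(lm_step(net, Xtr, Ytr, mu),
                     error = function(e) NULL)
    if (!is.null(step) && step$sse_new < step$sse_old) {
      net <- step$net
      mu <- max(mu / 10, 1e-12)
      iter <- iter + 1L
      trace <- c(trace, step$sse_new / length(Ytr))
      val <- mse_of(net, "validation")
      if (val < best_val - 1e-15) {
        best_val <- val
        best_net <- net
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    } else {
      mu <- mu * 10
      if (mu > mu_max) break
    }
  }
  structure(list(net = best_net,
                 mse = c(train = mse_of(best_net, "train"),
                         validation = best_val,
                         test = mse_of(best_net, "test")),
                 trace = trace,
                 split_index = set,
                 x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
                 iterations = iter, mu_final = mu, seed = seed),
            class = "bpann_fit")
}

#' @export
print.bpann_fit <- function(x, ...) {
  cat(sprintf("<bpann_fit> %d accepted steps; MSE train/val/test = %.4g/%.4g/%.4g\n",
              x$iterations, x$mse["train"], x$mse["validation"], x$mse["test"]))
  invisible(x)
}

#' Predict from a trained network on the original data scale
#'
#' @param object A `bpann_fit`.
#' @param newdata Input matrix on the original scale.
#' @param ... Unused.
#' @return Predictions back-transformed to the original target scale.
#' @export
predict.bpann_fit <- function(object, newdata, ...) {
  Xs <- sweep(sweep(check_matrix(newdata), 2L, object$x_center, "-"),
              2L, object$x_scale, "/")
  sweep(sweep(ann_forward(object$net, Xs), 2L, object$y_scale, "*"),
        2L, object$y_center, "+")
}

#' Per-input contribution ratios of a trained network
#'
#' Garson's algorithm (default): each input's share of the absolute
#' input-hidden x hidden-output weight products, with the input-hidden
#' weights normalised within each hidden neuron, summed over hidden neurons
#' and outputs and expressed as percentages summing to 100.  The
#' connection-weight (Olden) method, which keeps signs and is not normalised
#' to 100, is available behind a flag.
#'
#' @param net A `bpann` or `bpann_fit`.
#' @param method `"garson"` or `"olden"`.
#' @return Numeric vector, one entry per input; percentages for Garson.
#' @export
contribution_ratios <- function(net, method = c("garson", "olden")) {
  method <- match.arg(method)
  if (inherits(net, "bpann_fit")) net <- net$net
  p <- unpack_weights(net)
  if (all(net$weights == 0)) stop_input("all weights are zero; contributions undefined")
  if (method == "olden") {
    return(drop(colSums(p$W2) %*% p$W1))
  }
  aW1 <- abs(p$W1)                      # nh x ni
  row_tot <- rowSums(aW1)
  if (any(row_tot == 0)) row_tot[row_tot == 0] <- 1
  share <- aW1 / row_tot                # input share within each hidden neuron
  out_w <- colSums(abs(p$W2))           # nh, summed over outputs
  contrib <- drop(crossprod(share, out_w))
  if (sum(contrib) == 0) stop_input("degenerate network; contributions undefined")
  100 * contrib / sum(contrib)
}
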