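#' Fit a feedforward neural-network pose model
#'
#' Backpropagation network mapping the standardized 3-D query to the
#' (standardized) 9-D antenna-relative pose: tanh hidden units, identity
#' output, mean-squared-error loss, seeded mini-batch gradient descent.
#' Weights initialize uniformly in `+/- 1/sqrt(fan_in)`. Inputs and targets
#' are z-scored internally; predictions are returned on the physical scale.
#'
#' @param queries,targets as in [lwpr_fit()].
#' @param hidden integer vector of hidden-layer sizes. Default `30` (one
#'   hidden layer of 30 units).
#' @param epochs full passes over the training set. Default 1000.
#' @param lr learning rate. Default 0.05.
#' @param batch mini-batch size. Default 32.
#' @param seed RNG seed for initialization and batch shuffling.
#' @param scaling optional query scaling to reuse across models.
#' @return An object of class `ski_mlp`: layer sizes, weight matrices `W`,
#'   bias vectors `b`, standardization parameters, and `meta` with the
#'   per-epoch training loss.
#' @export
mlp_fit <- function(queries, targets, hidden = 30, epochs = 1000, lr = 0.05,
                    batch = 32, seed = 1L, scaling = NULL) {
  X <- .as_query_matrix(queries)
  Y <- .as_target_matrix(targets)
  n <- nrow(X)
  if (nrow(Y) != n) stop("queries/targets length mismatch")
  if (n < 10L) stop("need at least 10 training samples")
  if (any(!is.finite(X)) || any(!is.finite(Y))) stop("non-finite training data")
  if (is.null(scaling)) scaling <- query_scaling(as.data.frame(X))
  Xs <- sweep(sweep(X, 2, scaling$center), 2, scaling$scale, "/")
  ty_c <- colMeans(Y)
  ty_s <- apply(Y, 2, stats::sd)
  ty_s[ty_s < 1e-12] <- 1
  Ys <- sweep(sweep(Y, 2, ty_c), 2, ty_s, "/")

  sizes <- c(3L, as.integer(hidden), 9L)
  L <- length(sizes) - 1L
  set.seed(seed)
  W <- vector("list", L); b <- vector("list", L)
  for (ell in seq_len(L)) {
    lim <- 1 / sqrt(sizes[ell])
    W[[ell]] <- matrix(stats::runif(sizes[ell] * sizes[ell + 1L], -lim, lim),
                       sizes[ell], sizes[ell + 1L])
    b[[ell]] <- stats::runif(sizes[ell + 1L], -lim, lim)
  }

  loss_hist <- numeric(epochs)
  if (epochs > 0) for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      xb <- Xs[idx, , drop = FALSE]
      yb <- Ys[idx, , drop = FALSE]
      # forward
      act <- vector("list", L + 1L)
      act[[1L]] <- xb
      for (ell in seq_len(L)) {
        zz <- sweep(act[[ell]] %*% W[[ell]], 2, b[[ell]], "+")
        act[[ell + 1L]] <- if (ell < L) tanh(zz) else zz
      }
      err <- act[[L + 1L]] - yb
      tot <- tot + sum(err^2)
      # backward
      delta <- 2 * err / (length(idx) * 9)
      for (ell in L:1L) {
        gW <- crossprod(act[[ell]], delta)
        gb <- colSums(delta)
        if (ell > 1L)
          delta <- (delta %*% t(W[[ell]])) * (1 - act[[ell]]^2)
        W[[ell]] <- W[[ell]] - lr * gW
        b[[ell]] <- b[[ell]] - lr * gb
      }
    }
    loss_hist[ep] <- tot / (n * 9)
    if (!is.finite(loss_hist[ep]))
      stop("training diverged (NaN loss); reduce `lr`")
  }

  structure(list(sizes = sizes, W = W, b = b, scaling = scaling,
                 target_center = ty_c, target_scale = ty_s,
                 meta = list(epochs = epochs, lr = lr, batch = batch,
                             seed = seed, loss = loss_hist)),
            class = "ski_mlp")
}

# forward pass on a standardized input matrix
.mlp_forward <- function(model, Xs) {
  a <- Xs
  L <- length(model$W)
  for (ell in seq_len(L)) {
    zz <- sweep(a %*% model$W[[ell]], 2, model$b[[ell]], "+")
    a <- if (ell < L) tanh(zz) else zz
  }
  a
}

#' Predict the 9-D relative pose with the network
#'
#' Deterministic forward pass; output de-standardized to metres.
#'
#' @param object a fitted `ski_mlp`.
#' @param queries query rows (same forms as in [lwpr_fit()]).
#' @param ... unused.
#' @return n-by-9 matrix of relative-pose predictions.
#' @export
predict.ski_mlp <- function(object, queries, ...) {
  X <- .as_query_matrix(queries)
  Xs <- sweep(sweep(X, 2, object$scaling$center), 2, object$scaling$scale, "/")
  out <- .mlp_forward(object, Xs)
  out <- sweep(sweep(out, 2, object$target_scale, "*"), 2,
               object$target_center, "+")
  colnames(out) <- c("cx", "cy", "cz", "lx", "ly", "lz", "rx", "ry", "rz")
  out
}

#' @export
print.ski_mlp <- function(x, ...) {
  cat(sprintf("Neural-network pose model: layers %s, %d epochs (final loss %.3g)\n",
              paste(x$sizes, collapse = "-"), x$meta$epochs,
              if (x$meta$epochs > 0) x$meta$loss[x$meta$epochs] else NA))
  invisible(x)
}

#' @export
summary.ski_mlp <- function(object, ...) {
  n_par <- sum(vapply(object$W, length, 0L)) + sum(vapply(object$b, length, 0L))
  cat(sprintf("Neural-network pose model\n  architecture: %s (%d parameters)\n",
              paste(object$sizes, collapse = "-"), n_par))
  cat(sprintf("  training: %d epochs, lr %.3g, batch %d, seed %d\n",
              object$meta$epochs, object$meta$lr, object$meta$batch,
              object$meta$seed))
  if (object$meta$epochs > 0)
    cat(sprintf("  loss: %.4g -> %.4g\n", object$meta$loss[1],
                object$meta$loss[object$meta$epochs]))
  invisible(object)
}

#' @export
plot.ski_mlp <- function(x, ...) {
  if (x$meta$epochs == 0) stop("untrained model")
  graphics::plot(seq_len(x$meta$epochs), x$meta$loss, type = "l", log = "y",
                 xlab = "epoch", ylab = "training MSE (standardized)",
                 main = "Training loss", ...)
  invisible(x)
}

# analytic MSE gradient for a weight/bias list on a full batch; used by the
# finite-difference gradient checks
.mlp_gradient <- function(W, b, Xs, Ys) {
  L <- length(W)
  act <- vector("list", L + 1L)
  act[[1L]] <- Xs
  for (ell in seq_len(L)) {
    zz <- sweep(act[[ell]] %*% W[[ell]], 2, b[[ell]], "+")
    act[[ell + 1L]] <- if (ell < L) tanh(zz) else zz
  }
  err <- act[[L + 1L]] - Ys
  delta <- 2 * err / length(err)
  gW <- vector("list", L); gb <- vector("list", L)
  for (ell in L:1L) {
    gW[[ell]] <- crossprod(act[[ell]], delta)
    gb[[ell]] <- colSums(delta)
    if (ell > 1L)
      delta <- (delta %*% t(W[[ell]])) * (1 - act[[ell]]^2)
  }
  list(gW = gW, gb = gb,
       loss = mean(err^2))
}
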