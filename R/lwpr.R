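#' Fit a locally weighted regression pose model
#'
#' Statistical-generalization pose model: the standardized 3-D query space
#' (radial acceleration, speed, skiing angle) is covered incrementally by
#' Gaussian receptive fields, each carrying a local linear map from the query
#' to the 9-D antenna-relative pose. A field centered at `c` activates a
#' query `x` with `w = exp(-0.5 (x-c)' D (x-c))`; training is incremental in
#' temporal order: a new field is created at any point whose best activation
#' falls below `w_gen`, and every field with activation above the cutoff
#' updates its local model by weighted recursive least squares on `(x - c)`
#' (ridge-initialized). After the placement pass, `passes - 1` additional
#' update-only sweeps run so that fields created late in the pass also see
#' the full data. The distance metric `D` is fixed (no metric adaptation).
#'
#' @param queries a `query_series` (see [build_query()]) or data frame with
#'   columns `a_r`, `v`, `alpha`.
#' @param targets a `relative_pose9d` (see [pose_to_relative()]) or n-by-9
#'   matrix, aligned with `queries`.
#' @param D distance metric: a positive semi-definite 3x3 matrix in
#'   standardized query units (queries are z-scored before field placement so
#'   the metric has a consistent meaning across runs and units), or a scalar
#'   `d` for `d * I`. Larger diagonal values shrink the receptive fields and
#'   raise the local-model count. Default `4` (fields of roughly half a
#'   standard deviation radius), a practical size for giant-slalom queries.
#' @param w_gen receptive-field creation threshold in (0, 1). Default 0.2.
#' @param w_cutoff activation below which a field neither updates nor
#'   contributes to prediction. Default 1e-4.
#' @param ridge ridge regularization of the local regressions. Default 1e-6.
#' @param passes total sweeps over the data (1 placement pass plus
#'   `passes - 1` update-only sweeps). Default 2.
#' @param scaling optional query scaling (means/SDs) to reuse across models;
#'   computed from `queries` when NULL.
#' @return An object of class `ski_lwpr`: list with `fields` (each with
#'   center `c`, metric `D`, coefficient matrix `B` (4x9: intercept +
#'   slopes), RLS state), `scaling`, `target_center`, and the tuning
#'   parameters.
#' @export
lwpr_fit <- function(queries, targets, D = 4, w_gen = 0.2,
                     w_cutoff = 1e-4, ridge = 1e-6, passes = 2,
                     scaling = NULL) {
  X <- .as_query_matrix(queries)
  Y <- .as_target_matrix(targets)
  n <- nrow(X)
  if (nrow(Y) != n) stop("queries/targets length mismatch")
  if (n < 10L) stop("need at least 10 training samples")
  if (length(D) == 1L) D <- diag(3) * D
  D <- as.matrix(D)
  if (!isSymmetric(unname(D)) || any(eigen(D, only.values = TRUE)$values < -1e-12))
    stop("`D` must be symmetric positive semi-definite")
  if (any(apply(X, 2, stats::sd) < 1e-10))
    stop("zero-variance query feature; standardize or drop it")
  if (is.null(scaling)) scaling <- query_scaling(as.data.frame(X))
  Xs <- sweep(sweep(X, 2, scaling$center), 2, scaling$scale, "/")

  fields <- list()
  centers <- matrix(numeric(0), 0, 3)
  for (i in seq_len(n)) {
    x <- Xs[i, ]
    w <- .field_activations(centers, fields, x)
    if (length(w) == 0L || max(w) < w_gen) {
      fields[[length(fields) + 1L]] <- .new_field(x, D, Y[i, ], ridge)
      centers <- rbind(centers, x)
      w <- c(w, 1)
    }
    upd <- which(w > w_cutoff)
    for (j in upd)
      fields[[j]] <- .rls_update(fields[[j]], x, Y[i, ], w[j])
  }
  if (passes > 1) for (p in seq_len(passes - 1)) {
    for (i in seq_len(n)) {
      x <- Xs[i, ]
      w <- .field_activations(centers, fields, x)
      for (j in which(w > w_cutoff))
        fields[[j]] <- .rls_update(fields[[j]], x, Y[i, ], w[j])
    }
  }
  structure(list(fields = fields, centers = centers, D = D,
                 w_gen = w_gen, w_cutoff = w_cutoff, ridge = ridge,
                 passes = passes, scaling = scaling, n_train = n),
            class = "ski_lwpr")
}

.as_query_matrix <- function(queries) {
  if (is.matrix(queries)) {
    if (ncol(queries) != 3L) stop("query matrix must have 3 columns")
    colnames(queries) <- c("a_r", "v", "alpha")
    return(queries)
  }
  as.matrix(queries[, c("a_r", "v", "alpha")])
}

.as_target_matrix <- function(targets) {
  if (inherits(targets, "relative_pose9d")) return(relative_as_matrix(targets))
  m <- as.matrix(targets)
  if (ncol(m) != 9L) stop("targets must be 9-dimensional")
  m
}

.field_activations <- function(centers, fields, x) {
  if (nrow(centers) == 0L) return(numeric(0))
  # all fields share the metric; quadratic form row-wise
  dx <- sweep(centers, 2, x)
  qf <- rowSums((dx %*% fields[[1]]$D) * dx)
  exp(-0.5 * qf)
}

.new_field <- function(center, D, y0, ridge) {
  list(c = center, D = D,
       P = diag(4) / ridge,               # RLS inverse-covariance state
       B = rbind(y0, matrix(0, 3, 9)))    # intercept initialized at first target
}

# weighted recursive least squares on z = (1, x - c)
.rls_update <- function(field, x, y, w) {
  z <- c(1, x - field$c)
  Pz <- field$P %*% z
  denom <- 1 / w + sum(z * Pz)
  K <- Pz / denom
  err <- y - drop(crossprod(z, field$B))
  field$B <- field$B + K %*% rbind(err)
  field$P <- field$P - tcrossprod(K, Pz)
  field
}

#' Predict the 9-D relative pose from a query
#'
#' The prediction is the activation-weighted (convex) combination of the
#' local linear models whose activation exceeds the cutoff; if no field
#' activates, the nearest field alone is used and the sample is flagged as
#' extrapolation.
#'
#' @param object a fitted `ski_lwpr`.
#' @param queries query rows (same forms as in [lwpr_fit()]).
#' @param ... unused.
#' @return n-by-9 matrix of relative-pose predictions with logical attribute
#'   `extrapolated` per row.
#' @export
predict.ski_lwpr <- function(object, queries, ...) {
  X <- .as_query_matrix(queries)
  Xs <- sweep(sweep(X, 2, object$scaling$center), 2, object$scaling$scale, "/")
  n <- nrow(Xs)
  out <- matrix(0, n, 9)
  extra <- logical(n)
  for (i in seq_len(n)) {
    x <- Xs[i, ]
    w <- .field_activations(object$centers, object$fields, x)
    use <- which(w > object$w_cutoff)
    if (length(use) == 0L) {
      use <- which.max(w)
      w[use] <- 1
      extra[i] <- TRUE
    }
    pred <- matrix(0, length(use), 9)
    for (jj in seq_along(use)) {
      f <- object$fields[[use[jj]]]
      pred[jj, ] <- drop(crossprod(c(1, x - f$c), f$B))
    }
    out[i, ] <- colSums(pred * w[use]) / sum(w[use])
  }
  colnames(out) <- c("cx", "cy", "cz", "lx", "ly", "lz", "rx", "ry", "rz")
  attr(out, "extrapolated") <- extra
  out
}

#' @export
print.ski_lwpr <- function(x, ...) {
  cat(sprintf("Locally weighted pose model: %d receptive fields (D diag %.3g, w_gen %.2f, %d training samples)\n",
              length(x$fields), x$D[1, 1], x$w_gen, x$n_train))
  invisible(x)
}

#' @export
summary.ski_lwpr <- function(object, ...) {
  cat(sprintf("Locally weighted pose model\n  fields: %d\n  training samples: %d\n",
              length(object$fields), object$n_train))
  cat(sprintf("  metric diag (standardized units): %s\n  w_gen: %.3f, cutoff: %.1e\n",
              paste(sprintf("%.3g", diag(object$D)), collapse = ", "),
              object$w_gen, object$w_cutoff))
  invisible(object)
}

#' Reconstruct absolute pose trajectories from a pose model
#'
#' Runs the model over a query series and adds the predicted antenna-relative
#' offsets to the antenna track, giving absolute COM and ski trajectories.
#' Works for any model with a matrix-returning `predict` method over queries
#' (`ski_lwpr`, `ski_mlp`).
#'
#' @param model a fitted `ski_lwpr` or `ski_mlp`.
#' @param queries a `query_series` aligned with `antenna`.
#' @param antenna a `trajectory3d`.
#' @return a `pose_series`.
#' @export
predict_pose <- function(model, queries, antenna) {
  stopifnot(inherits(antenna, "trajectory3d"))
  if (nrow(queries) != length(antenna$t))
    stop("queries and antenna must be aligned")
  rel <- matrix_as_relative(stats::predict(model, queries))
  relative_to_pose(rel, antenna)
}

#' Serialize / restore a pose model as JSON
#'
#' Stores every numeric component (receptive-field centers, metrics and
#' coefficients, or network weights, plus standardization) in a plain JSON
#' document, so trained models are portable text artifacts.
#'
#' @param model a `ski_lwpr` or `ski_mlp`.
#' @param path output file.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "ski_lwpr")) {
    doc <- list(type = "lwpr",
                D = model$D, w_gen = model$w_gen, w_cutoff = model$w_cutoff,
                ridge = model$ridge, n_train = model$n_train,
                scaling = model$scaling,
                centers = model$centers,
                B = lapply(model$fields, function(f) f$B))
  } else if (inherits(model, "ski_mlp")) {
    doc <- list(type = "mlp", sizes = model$sizes,
                W = model$W, b = model$b,
                scaling = model$scaling,
                target_center = model$target_center,
                target_scale = model$target_scale,
                meta = model$meta)
  } else stop("unsupported model class")
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the restored model object.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- list(center = as.numeric(doc$scaling$center),
             scale = as.numeric(doc$scaling$scale))
  if (doc$type == "lwpr") {
    centers <- matrix(as.numeric(as.matrix(doc$centers)), ncol = 3)
    D <- matrix(as.numeric(as.matrix(doc$D)), 3, 3)
    get_B <- function(i) {
      # jsonlite may return the per-field coefficient list as a 3-D array
      if (is.array(doc$B) && length(dim(doc$B)) == 3L)
        matrix(doc$B[i, , ], 4, 9)
      else matrix(as.numeric(as.matrix(doc$B[[i]])), 4, 9)
    }
    fields <- lapply(seq_len(nrow(centers)), function(i)
      list(c = centers[i, ], D = D,
           P = NULL, # prediction-only restore
           B = get_B(i)))
    structure(list(fields = fields, centers = centers, D = D,
                   w_gen = doc$w_gen, w_cutoff = doc$w_cutoff,
                   ridge = doc$ridge, scaling = sc, n_train = doc$n_train),
              class = "ski_lwpr")
  } else if (doc$type == "mlp") {
    structure(list(sizes = as.integer(doc$sizes),
                   W = lapply(doc$W, function(w) matrix(as.numeric(as.matrix(w)),
                                                        nrow = nrow(as.matrix(w)))),
                   b = lapply(doc$b, as.numeric),
                   scaling = sc,
                   target_center = as.numeric(doc$target_center),
                   target_scale = as.numeric(doc$target_scale),
                   meta = doc$meta),
              class = "ski_mlp")
  } else stop("unknown model type: ", doc$type)
}
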