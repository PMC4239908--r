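#' Resample a series onto the normalized path-fraction grid
#'
#' Runs of different length and speed are compared on a common axis: the
#' path fraction `s` in [0, 1], 0 at the start and 1 at the end of the run,
#' defined by cumulative horizontal arc length (the path-faithful reading;
#' set `by = "time"` for plain duration normalization — the two coincide at
#' constant speed). Values are linearly interpolated onto `n_points` equally
#' spaced `s` values.
#'
#' @param values numeric vector or matrix (rows = samples) to resample.
#' @param path n-by-2/3 matrix of positions defining the arc length, or a
#'   `trajectory3d`; ignored when `by = "time"`.
#' @param t timestamps, required when `by = "time"`.
#' @param n_points grid size. Default 200.
#' @param by "arclength" (default) or "time".
#' @return matrix (or vector) of resampled values with attribute `s`.
#' @export
path_normalize <- function(values, path = NULL, t = NULL, n_points = 200,
                           by = c("arclength", "time")) {
  by <- match.arg(by)
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 3L) stop("need at least 3 samples")
  if (by == "arclength") {
    if (inherits(path, "trajectory3d")) path <- path$p
    path <- as.matrix(path)
    if (nrow(path) != n) stop("values/path length mismatch")
    d <- sqrt(rowSums(diff(path[, 1:2, drop = FALSE])^2))
    s <- c(0, cumsum(d))
  } else {
    if (is.null(t)) stop("`t` required for duration normalization")
    s <- t - t[1]
  }
  total <- s[n]
  if (total <= 0) stop("zero total path length")
  s <- s / total
  grid <- seq(0, 1, length.out = n_points)
  out <- apply(values, 2, function(col) stats::approx(s, col, xout = grid,
                                                      ties = mean)$y)
  out <- if (ncol(values) == 1L) drop(out) else out
  attr(out, "s") <- grid
  out
}

#' Per-sample pose errors
#'
#' Euclidean norm of the 3-D distance between estimated and reference
#' positions, per sample, for the COM and each ski; `ski_mean` averages the
#' two ski errors.
#'
#' @param est,ref `pose_series` on a common time base (resample first).
#' @return data frame with columns `com`, `ski_left`, `ski_right`,
#'   `ski_mean`.
#' @export
pose_error <- function(est, ref) {
  stopifnot(inherits(est, "pose_series"), inherits(ref, "pose_series"))
  if (length(est$t) != length(ref$t)) stop("length mismatch; resample first")
  nrm <- function(a, b) sqrt(rowSums((a - b)^2))
  com <- nrm(est$com, ref$com)
  sl <- nrm(est$ski_left, ref$ski_left)
  sr <- nrm(est$ski_right, ref$ski_right)
  data.frame(com = com, ski_left = sl, ski_right = sr,
             ski_mean = (sl + sr) / 2)
}

#' Pendulum ground-point error against the mid-ski point
#'
#' The pendulum estimator predicts a single ground-contact point; assuming
#' equally distributed weight it is compared with the midpoint of the two
#' reference skis. COM errors compare directly.
#'
#' @param ip a `ski_ip` fit.
#' @param ref a reference `pose_series`; interpolated onto the fit's time
#'   base if needed.
#' @return data frame with columns `com`, `ground` (metres per sample).
#' @export
ip_ground_error <- function(ip, ref) {
  stopifnot(inherits(ip, "ski_ip"), inherits(ref, "pose_series"))
  tt <- ip$com$t
  interp <- function(m) vapply(1:3, function(j)
    stats::approx(ref$t, m[, j], xout = tt, rule = 2)$y, numeric(length(tt)))
  mid <- (interp(ref$ski_left) + interp(ref$ski_right)) / 2
  comr <- interp(ref$com)
  data.frame(com = sqrt(rowSums((ip$com$p - comr)^2)),
             ground = sqrt(rowSums((ip$ground$p - mid)^2)))
}

#' Aggregate per-run error series into an error curve
#'
#' Each run's per-sample errors are resampled onto the common path-fraction
#' grid, then averaged pointwise across runs; the spread is the pointwise SD.
#'
#' @param errors list of numeric error vectors, one per run.
#' @param paths list of position matrices (or `trajectory3d`) matching
#'   `errors`, defining each run's arc length.
#' @param n_points grid size. Default 200.
#' @return An object of class `error_curve`: list with `s`, `mean`, `sd`,
#'   `per_run` (runs-by-s matrix).
#' @export
aggregate_runs <- function(errors, paths, n_points = 200) {
  if (length(errors) < 1L) stop("need at least one run")
  if (length(paths) != length(errors)) stop("errors/paths length mismatch")
  per <- t(vapply(seq_along(errors), function(i)
    path_normalize(errors[[i]], paths[[i]], n_points = n_points),
    numeric(n_points)))
  m <- colMeans(per)
  s <- if (nrow(per) > 1L) apply(per, 2, stats::sd) else rep(0, n_points)
  structure(list(s = seq(0, 1, length.out = n_points), mean = m, sd = s,
                 per_run = per),
            class = "error_curve")
}

#' @export
print.error_curve <- function(x, ...) {
  cat(sprintf("<error_curve> %d runs on %d path points; overall mean %.3f m (sd %.3f)\n",
              nrow(x$per_run), length(x$s), mean(x$mean), mean(x$sd)))
  invisible(x)
}

#' @export
plot.error_curve <- function(x, ...) {
  up <- x$mean + x$sd; lo <- pmax(x$mean - x$sd, 0)
  graphics::plot(x$s, x$mean, type = "n", ylim = c(0, max(up)),
                 xlab = "path fraction s", ylab = "error (m)", ...)
  graphics::polygon(c(x$s, rev(x$s)), c(up, rev(lo)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(x$s, x$mean, col = "steelblue4", lwd = 2)
  invisible(x)
}

#' Cross-validate per-skier pose models
#'
#' Trains one model per skier on that skier's runs and evaluates every model
#' on every run, mirroring the cross-validation table layout: one row per
#' (skier, run), one column per model-training skier, each cell the mean
#' (and SD) over the run's samples of the per-sample error. Two tables are
#' produced: COM error and mean-ski error.
#'
#' @param runs named list: one element per skier, each a list of runs; every
#'   run is a list with elements `query` (a `query_series`), `target` (a
#'   `relative_pose9d`) and optionally `pose`/`antenna`.
#' @param method "lwpr" or "nn".
#' @param ... passed to the fitter ([lwpr_fit()] or [mlp_fit()]).
#' @return An object of class `crossval_table`: list with matrices `com_mean`,
#'   `com_sd`, `ski_mean`, `ski_sd` ((total runs) x (n skiers)), row labels
#'   `skier`/`run`, and the fitted `models`.
#' @export
cross_validate <- function(runs, method = c("lwpr", "nn"), ...) {
  method <- match.arg(method)
  if (length(runs) < 1L) stop("no skiers")
  if (any(vapply(runs, length, 0L) < 1L)) stop("every skier needs runs")
  skiers <- names(runs)
  if (is.null(skiers)) skiers <- paste0("S", seq_along(runs))

  fit_one <- function(runlist, ...) {
    Q <- do.call(rbind, lapply(runlist, function(r) .as_query_matrix(r$query)))
    Y <- do.call(rbind, lapply(runlist, function(r) .as_target_matrix(r$target)))
    if (method == "lwpr") lwpr_fit(Q, Y, ...) else mlp_fit(Q, Y, ...)
  }
  models <- lapply(runs, fit_one, ...)

  labels <- do.call(rbind, lapply(seq_along(runs), function(i)
    data.frame(skier = skiers[i], run = seq_along(runs[[i]]))))
  nr <- nrow(labels); nc <- length(runs)
  com_mean <- com_sd <- ski_mean <- ski_sd <- matrix(NA_real_, nr, nc,
    dimnames = list(paste(labels$skier, labels$run, sep = ":"), skiers))
  row <- 0L
  for (i in seq_along(runs)) for (r in seq_along(runs[[i]])) {
    row <- row + 1L
    q <- runs[[i]][[r]]$query
    ytrue <- .as_target_matrix(runs[[i]][[r]]$target)
    for (j in seq_along(models)) {
      pred <- stats::predict(models[[j]], q)
      ec <- sqrt(rowSums((pred[, 1:3] - ytrue[, 1:3])^2))
      el <- sqrt(rowSums((pred[, 4:6] - ytrue[, 4:6])^2))
      er <- sqrt(rowSums((pred[, 7:9] - ytrue[, 7:9])^2))
      es <- (el + er) / 2
      com_mean[row, j] <- mean(ec); com_sd[row, j] <- stats::sd(ec)
      ski_mean[row, j] <- mean(es); ski_sd[row, j] <- stats::sd(es)
    }
  }
  structure(list(com_mean = com_mean, com_sd = com_sd,
                 ski_mean = ski_mean, ski_sd = ski_sd,
                 labels = labels, method = method, models = models),
            class = "crossval_table")
}

#' @export
print.crossval_table <- function(x, digits = 3, ...) {
  cat(sprintf("Cross-validation (%s): %d runs x %d per-skier models\n",
              x$method, nrow(x$com_mean), ncol(x$com_mean)))
  cat("COM error, mean (sd) metres:\n")
  cells <- matrix(sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
                          x$com_mean, x$com_sd), nrow = nrow(x$com_mean),
                  dimnames = dimnames(x$com_mean))
  print(cells, quote = FALSE)
  invisible(x)
}

#' Format a cross-validation table as a data frame
#'
#' One row per (skier, run) with `mean (sd)` strings per model column plus
#' machine-readable numeric columns.
#'
#' @param x a `crossval_table`.
#' @param which "com" or "ski".
#' @return data frame.
#' @export
crossval_as_data_frame <- function(x, which = c("com", "ski")) {
  which <- match.arg(which)
  m <- x[[paste0(which, "_mean")]]
  s <- x[[paste0(which, "_sd")]]
  out <- x$labels
  for (j in colnames(m)) {
    out[[paste0("model_", j)]] <- sprintf("%.3f (%.3f)", m[, j], s[, j])
    out[[paste0("mean_", j)]] <- m[, j]
    out[[paste0("sd_", j)]] <- s[, j]
  }
  out
}

#' Off-diagonal pairing of two cross-validation tables
#'
#' The method comparison uses only predictions made with a model trained on a
#' different subject than the one being predicted (every off-diagonal cell),
#' pairing the two methods cell by cell. With 18 runs and 5 per-skier models
#' this yields 90 - 18 = 72 paired cases, hence 71 degrees of freedom.
#'
#' @param tab_a,tab_b `crossval_table`s with identical layout.
#' @param which "com" or "ski".
#' @return data frame with columns `skier`, `run`, `model`, `a`, `b`.
#' @export
crossval_pairs <- function(tab_a, tab_b, which = c("com", "ski")) {
  which <- match.arg(which)
  ma <- tab_a[[paste0(which, "_mean")]]
  mb <- tab_b[[paste0(which, "_mean")]]
  if (!identical(dim(ma), dim(mb))) stop("table layouts differ")
  out <- NULL
  for (row in seq_len(nrow(ma))) for (j in seq_len(ncol(ma))) {
    if (tab_a$labels$skier[row] == colnames(ma)[j]) next # own-subject cell
    out <- rbind(out, data.frame(skier = tab_a$labels$skier[row],
                                 run = tab_a$labels$run[row],
                                 model = colnames(ma)[j],
                                 a = ma[row, j], b = mb[row, j]))
  }
  out
}

#' Paired-samples t-test
#'
#' Two-sided paired t-test on per-case mean errors:
#' `t = mean(d) / (sd(d)/sqrt(n))`, `df = n - 1`, p from the t distribution.
#' Degenerate cases: all differences zero gives `t = 0, p = 1`; zero
#' variance with nonzero mean gives `p = 0` by convention.
#'
#' @param errors_a,errors_b equal-length numeric vectors, paired by case.
#' @return list with `t`, `df`, `p`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `mean_diff`.
#' @export
paired_t_test <- function(errors_a, errors_b) {
  n <- length(errors_a)
  if (length(errors_b) != n) stop("inputs must be paired (equal length)")
  if (n < 2L) stop("need at least 2 pairs")
  d <- errors_a - errors_b
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    tval <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    tval <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(tval), df = n - 1)
  }
  list(t = tval, df = n - 1L, p = p,
       mean_a = mean(errors_a), sd_a = stats::sd(errors_a),
       mean_b = mean(errors_b), sd_b = stats::sd(errors_b),
       mean_diff = md)
}
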