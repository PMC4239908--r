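#' Construct a 3-D trajectory
#'
#' A `trajectory3d` is a timestamped series of positions in the site frame:
#' X points along the horizontal projection of the mean downhill (fall-line)
#' direction, Y across the slope (right-handed), Z up. Units are metres and
#' seconds; time is counted from the start of the run.
#'
#' @param t numeric vector of timestamps (seconds), strictly increasing.
#' @param p numeric matrix with one row per sample and columns x, y, z (metres).
#' @param rate_hz nominal sampling frequency in Hz. Defaults to the inverse
#'   median time step.
#' @return An object of class `trajectory3d` with fields `t`, `p`, `rate_hz`.
#' @export
trajectory3d <- function(t, p, rate_hz = NULL) {
  t <- as.numeric(t)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) stop("`p` must have 3 columns (x, y, z)")
  if (length(t) != nrow(p)) stop("`t` and `p` must have the same length")
  if (length(t) < 3L) stop("a trajectory needs at least 3 samples")
  if (any(!is.finite(t)) || any(!is.finite(p))) stop("non-finite values in trajectory")
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing")
  if (is.null(rate_hz)) rate_hz <- 1 / stats::median(diff(t))
  colnames(p) <- c("x", "y", "z")
  structure(list(t = t, p = p, rate_hz = rate_hz), class = "trajectory3d")
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("<trajectory3d> %d samples, %.3f-%.3f s, ~%.1f Hz\n",
              length(x$t), x$t[1], x$t[length(x$t)], x$rate_hz))
  invisible(x)
}

#' @export
length.trajectory3d <- function(x) length(x$t)

#' Construct a full skier pose series
#'
#' Holds the four tracked points of the reduced body model on a shared time
#' base: GNSS antenna (behind the neck), center of mass, and both skis.
#'
#' @param t shared timestamps (seconds), strictly increasing.
#' @param antenna,com,ski_left,ski_right n-by-3 position matrices (metres,
#'   site frame).
#' @param rate_hz nominal sampling frequency in Hz.
#' @param check validate that the COM lies below the antenna and the skis
#'   below the COM (upright skier). Default TRUE.
#' @return An object of class `pose_series`.
#' @export
pose_series <- function(t, antenna, com, ski_left, ski_right, rate_hz = NULL,
                        check = TRUE) {
  t <- as.numeric(t)
  mats <- lapply(list(antenna = antenna, com = com,
                      ski_left = ski_left, ski_right = ski_right),
                 function(m) {
                   m <- as.matrix(m); storage.mode(m) <- "double"
                   colnames(m) <- c("x", "y", "z"); m
                 })
  n <- length(t)
  if (n < 3L) stop("a pose series needs at least 3 samples")
  if (any(vapply(mats, nrow, 0L) != n)) stop("all series must share the time base")
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing")
  if (any(!vapply(mats, function(m) all(is.finite(m)), TRUE)))
    stop("non-finite values in pose series")
  if (check) {
    if (any(mats$com[, 3] >= mats$antenna[, 3]))
      stop("COM must lie below the antenna at every sample")
    if (any(mats$ski_left[, 3] >= mats$com[, 3]) ||
        any(mats$ski_right[, 3] >= mats$com[, 3]))
      stop("skis must lie below the COM at every sample")
  }
  if (is.null(rate_hz)) rate_hz <- 1 / stats::median(diff(t))
  structure(c(list(t = t), mats, list(rate_hz = rate_hz)), class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("<pose_series> %d samples, %.3f-%.3f s, ~%.1f Hz\n",
              length(x$t), x$t[1], x$t[length(x$t)], x$rate_hz))
  invisible(x)
}

#' Antenna-relative 9-D pose offsets
#'
#' Converts a pose series to per-sample offsets of COM and both skis from the
#' antenna position (the 9-dimensional learning target), and back. The two
#' conversions are exact inverses given the antenna track.
#'
#' @param pose a `pose_series`.
#' @return `pose_to_relative()`: an object of class `relative_pose9d` with
#'   n-by-3 matrices `d_com`, `d_ski_left`, `d_ski_right`.
#' @export
pose_to_relative <- function(pose) {
  stopifnot(inherits(pose, "pose_series"))
  structure(list(d_com = pose$com - pose$antenna,
                 d_ski_left = pose$ski_left - pose$antenna,
                 d_ski_right = pose$ski_right - pose$antenna),
            class = "relative_pose9d")
}

#' @rdname pose_to_relative
#' @param rel a `relative_pose9d`.
#' @param antenna a `trajectory3d` of the antenna, aligned sample-for-sample.
#' @export
relative_to_pose <- function(rel, antenna) {
  stopifnot(inherits(rel, "relative_pose9d"), inherits(antenna, "trajectory3d"))
  if (nrow(rel$d_com) != nrow(antenna$p)) stop("length mismatch")
  pose_series(antenna$t,
              antenna = antenna$p,
              com = antenna$p + rel$d_com,
              ski_left = antenna$p + rel$d_ski_left,
              ski_right = antenna$p + rel$d_ski_right,
              rate_hz = antenna$rate_hz, check = FALSE)
}

#' Flatten a relative pose to an n-by-9 matrix (and back)
#'
#' Column order: COM xyz, left-ski xyz, right-ski xyz.
#' @param rel a `relative_pose9d`.
#' @keywords internal
#' @export
relative_as_matrix <- function(rel) {
  m <- cbind(rel$d_com, rel$d_ski_left, rel$d_ski_right)
  colnames(m) <- c("cx", "cy", "cz", "lx", "ly", "lz", "rx", "ry", "rz")
  m
}

#' @rdname relative_as_matrix
#' @param m an n-by-9 matrix in the documented column order.
#' @export
matrix_as_relative <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 9L) stop("expected 9 columns")
  sub <- function(cols) {
    out <- m[, cols, drop = FALSE]
    colnames(out) <- c("x", "y", "z")
    out
  }
  structure(list(d_com = sub(1:3), d_ski_left = sub(4:6),
                 d_ski_right = sub(7:9)),
            class = "relative_pose9d")
}

# fixed-precision CSV writer: 9 decimals keeps round-trips bit-stable
.write_fixed_csv <- function(df, path, digits = 9L) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf(paste0("%.", digits, "f"), v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read / write trajectory CSV files
#'
#' Trajectory files are UTF-8 CSV with header `t,x,y,z` ('.' decimal
#' separator); values are written with 9 fixed decimals so that a
#' write-then-read round trip reproduces the stored fields exactly at that
#' precision. Rows containing NA/NaN are dropped with a message.
#'
#' @param path file path.
#' @return `read_trajectory()` returns a `trajectory3d`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns t,x,y,z; got: ",
         paste(names(df), collapse = ","))
  ok <- stats::complete.cases(df[need])
  if (any(!ok)) message(sum(!ok), " row(s) with missing values dropped")
  df <- df[ok, , drop = FALSE]
  if (nrow(df) < 3L) stop("fewer than 3 valid rows in ", path)
  trajectory3d(df$t, as.matrix(df[c("x", "y", "z")]))
}

#' @rdname read_trajectory
#' @param traj a `trajectory3d`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory3d"))
  df <- data.frame(t = traj$t, x = traj$p[, 1], y = traj$p[, 2], z = traj$p[, 3])
  .write_fixed_csv(df, path)
  invisible(path)
}

#' Read / write pose CSV files
#'
#' Pose files carry 13 columns in this fixed order:
#' `t,ax,ay,az,cx,cy,cz,lx,ly,lz,rx,ry,rz` (antenna, COM, left ski, right
#' ski). Same dialect and precision as [read_trajectory()].
#'
#' @param path file path.
#' @return `read_pose()` returns a `pose_series`.
#' @export
read_pose <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("t", "ax", "ay", "az", "cx", "cy", "cz",
            "lx", "ly", "lz", "rx", "ry", "rz")
  if (!all(need %in% names(df)))
    stop("pose file must have columns ", paste(need, collapse = ","))
  ok <- stats::complete.cases(df[need])
  if (any(!ok)) message(sum(!ok), " row(s) with missing values dropped")
  df <- df[ok, , drop = FALSE]
  if (nrow(df) < 3L) stop("fewer than 3 valid rows in ", path)
  pose_series(df$t,
              antenna = as.matrix(df[c("ax", "ay", "az")]),
              com = as.matrix(df[c("cx", "cy", "cz")]),
              ski_left = as.matrix(df[c("lx", "ly", "lz")]),
              ski_right = as.matrix(df[c("rx", "ry", "rz")]),
              check = FALSE)
}

#' @rdname read_pose
#' @param pose a `pose_series`.
#' @export
write_pose <- function(pose, path) {
  stopifnot(inherits(pose, "pose_series"))
  df <- data.frame(t = pose$t,
                   ax = pose$antenna[, 1], ay = pose$antenna[, 2], az = pose$antenna[, 3],
                   cx = pose$com[, 1], cy = pose$com[, 2], cz = pose$com[, 3],
                   lx = pose$ski_left[, 1], ly = pose$ski_left[, 2], lz = pose$ski_left[, 3],
                   rx = pose$ski_right[, 1], ry = pose$ski_right[, 2], rz = pose$ski_right[, 3])
  .write_fixed_csv(df, path)
  invisible(path)
}

#' Upsample a trajectory with cubic splines
#'
#' Fits a cubic interpolation spline per coordinate (Forsythe-Malcolm-Moler
#' boundary conditions, which reproduce cubic polynomials exactly) and
#' resamples on a uniform grid at `target_hz` spanning the original time
#' range. Used to bring a 20 Hz GNSS track up to the 120 Hz pose rate before
#' combining the two streams. Original sample instants reproduce the original
#' values.
#'
#' @param traj a `trajectory3d`.
#' @param target_hz target sampling frequency (Hz), above the source rate.
#' @return a `trajectory3d` at `target_hz`.
#' @export
upsample_spline <- function(traj, target_hz) {
  stopifnot(inherits(traj, "trajectory3d"))
  if (target_hz <= traj$rate_hz) stop("`target_hz` must exceed the source rate")
  if (length(traj$t) < 4L) stop("cubic spline needs at least 4 samples")
  t0 <- traj$t[1]; tn <- traj$t[length(traj$t)]
  tt <- seq(t0, tn, by = 1 / target_hz)
  p <- vapply(1:3, function(j)
    stats::spline(traj$t, traj$p[, j], xout = tt, method = "fmm")$y,
    numeric(length(tt)))
  trajectory3d(tt, p, rate_hz = target_hz)
}

#' Smooth a trajectory with cross-validated splines
#'
#' Fits a smoothing spline per coordinate (smoothness chosen by generalized
#' cross-validation) and resamples on a uniform grid. This is the standard
#' pre-processing step before differentiating a GNSS track: three-point
#' curvature at 20 Hz is noise-dominated on raw RTK positions, and the
#' spline suppresses the measurement noise while following the turn
#' dynamics. On noise-free tracks it is near-lossless.
#'
#' @param traj a `trajectory3d`.
#' @param target_hz output rate (Hz); defaults to the input rate.
#' @return a smoothed `trajectory3d`.
#' @export
smooth_trajectory <- function(traj, target_hz = NULL) {
  stopifnot(inherits(traj, "trajectory3d"))
  if (is.null(target_hz)) target_hz <- traj$rate_hz
  .prepare_antenna(traj, target_hz, smooth = TRUE)
}

# trapezoidal cumulative integral
.cumtrapz <- function(t, y) c(0, cumsum(diff(t) * (y[-1] + y[-length(y)]) / 2))

# time of the upward zero-crossing of v nearest the global minimum of its
# integral (the bottom of the squat), linearly interpolated
.squat_crossing <- function(t, v) {
  z <- .cumtrapz(t, v)
  imin <- which.min(z)
  up <- which(v[-length(v)] <= 0 & v[-1] > 0)
  if (length(up) == 0L) stop("no upward zero-crossing of vertical velocity found")
  i <- up[which.min(abs(up - imin))]
  if (v[i + 1] == v[i]) return(t[i])
  t[i] + (0 - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
}

#' Time-synchronize two streams by the pre-run squat
#'
#' Both measurement systems record an isolated explosive squat before the run;
#' the bottom of the squat — where vertical velocity crosses zero on the way
#' up — is the synchronization point. Given the two vertical-velocity series,
#' returns the time offset (seconds) to add to stream b's clock so it aligns
#' with stream a: `offset = t_cross_a - t_cross_b`.
#'
#' @param vz_a,vz_b data frames with columns `t` (seconds) and `vz` (m/s),
#'   each containing a single dominant squat.
#' @return time offset in seconds.
#' @export
sync_by_squat <- function(vz_a, vz_b) {
  for (d in list(vz_a, vz_b))
    if (!all(c("t", "vz") %in% names(d))) stop("inputs need columns t, vz")
  .squat_crossing(vz_a$t, vz_a$vz) - .squat_crossing(vz_b$t, vz_b$vz)
}
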