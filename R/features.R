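#' Circumradius of three points
#'
#' Radius of the circle through three points: `R = |p1p2| |p2p3| |p1p3| /
#' (4 A)` with `A` the triangle area. The trajectory curvature radius is
#' estimated from circles spanned through three adjacent samples. Collinear
#' points give `Inf` (a straight segment).
#'
#' @param p1,p2,p3 numeric 2- or 3-vectors.
#' @return circumradius in the input units; `Inf` when collinear.
#' @export
circumradius_3pt <- function(p1, p2, p3) {
  if (length(p1) == 2L) { p1 <- c(p1, 0); p2 <- c(p2, 0); p3 <- c(p3, 0) }
  a <- p2 - p1; b <- p3 - p2; c_ <- p3 - p1
  la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2)); lc <- sqrt(sum(c_^2))
  if (la == 0 || lb == 0 || lc == 0) stop("duplicated points")
  cr <- c(a[2] * c_[3] - a[3] * c_[2],
          a[3] * c_[1] - a[1] * c_[3],
          a[1] * c_[2] - a[2] * c_[1])
  area2 <- sqrt(sum(cr^2)) # = 2 * area
  if (area2 < .Machine$double.eps * la * lc) return(Inf)
  la * lb * lc / (2 * area2)
}

# vectorized circumradius + signed curvature over a horizontal (x, y) path;
# sign > 0 when the path bends left (counter-clockwise), from the cross
# product of successive chords. Ends copy their neighbors.
.curvature_series <- function(x, y) {
  n <- length(x)
  ax <- x[2:(n - 1)] - x[1:(n - 2)]; ay <- y[2:(n - 1)] - y[1:(n - 2)]
  bx <- x[3:n] - x[2:(n - 1)];       by <- y[3:n] - y[2:(n - 1)]
  cx <- x[3:n] - x[1:(n - 2)];       cy <- y[3:n] - y[1:(n - 2)]
  la <- sqrt(ax^2 + ay^2); lb <- sqrt(bx^2 + by^2); lc <- sqrt(cx^2 + cy^2)
  cross <- ax * by - ay * bx
  r <- ifelse(abs(cross) < .Machine$double.eps * la * lc,
              Inf, la * lb * lc / (2 * abs(cross)))
  sgn <- sign(cross)
  r <- c(r[1], r, r[length(r)])
  sgn <- c(sgn[1], sgn, sgn[length(sgn)])
  list(r = r, sign = sgn)
}

# central differences with one-sided ends
.diff_central <- function(t, y) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  d
}

#' Speed along a trajectory
#'
#' Absolute velocity `|dp/dt|` by central differences (one-sided at the ends).
#'
#' @param traj a `trajectory3d`.
#' @return numeric vector of speeds (m/s).
#' @export
speed <- function(traj) {
  stopifnot(inherits(traj, "trajectory3d"))
  vx <- .diff_central(traj$t, traj$p[, 1])
  vy <- .diff_central(traj$t, traj$p[, 2])
  vz <- .diff_central(traj$t, traj$p[, 3])
  sqrt(vx^2 + vy^2 + vz^2)
}

#' Radial acceleration, curvature radius and angular velocity
#'
#' Per sample, the curvature radius `r` is the circumradius of the circle
#' through the horizontal projections of the three adjacent samples; the turn
#' rate is `omega = v_h / r` and the radial acceleration `a_r = v_h^2 / r`
#' (with `v_h` the horizontal speed). `a_r` is signed: positive in
#' left-hand (counter-clockwise) turns, negative in right-hand turns, so the
#' sign flips at turn transitions. Straight segments give `a_r = 0`,
#' `omega = 0`, `r = Inf`.
#'
#' @param traj a `trajectory3d`.
#' @return data frame with columns `a_r` (m/s^2), `r` (m), `omega` (rad/s).
#' @export
radial_acceleration <- function(traj) {
  stopifnot(inherits(traj, "trajectory3d"))
  x <- traj$p[, 1]; y <- traj$p[, 2]
  cv <- .curvature_series(x, y)
  vx <- .diff_central(traj$t, x)
  vy <- .diff_central(traj$t, y)
  vh2 <- vx^2 + vy^2
  a_r <- ifelse(is.finite(cv$r), cv$sign * vh2 / cv$r, 0)
  omega <- ifelse(is.finite(cv$r), cv$sign * sqrt(vh2) / cv$r, 0)
  data.frame(a_r = a_r, r = cv$r, omega = omega)
}

# horizontal unit vector from each sample toward its instantaneous turn
# center: the left normal of horizontal velocity times the turn sign
.radial_direction <- function(traj) {
  x <- traj$p[, 1]; y <- traj$p[, 2]
  cv <- .curvature_series(x, y)
  vx <- .diff_central(traj$t, x)
  vy <- .diff_central(traj$t, y)
  vh <- sqrt(vx^2 + vy^2)
  vh[vh < 1e-12] <- 1
  s <- cv$sign
  s[s == 0] <- 1
  cbind(-s * vy / vh, s * vx / vh)
}

#' Skiing angle in the local tangent plane
#'
#' At each sample the velocity is projected onto the slope tangent plane at
#' the ground point below the antenna; `alpha` is the angle of that projected
#' direction measured from the tangent-plane fall-line axis (`ex` of
#' [surface_frame()]), positive toward `ey`, in (-pi, pi]. Zero-velocity
#' samples carry the previous value.
#'
#' @param traj a `trajectory3d` (antenna track).
#' @param mesh a `slope_mesh` covering the track.
#' @return numeric vector of angles (radians).
#' @export
skiing_angle <- function(traj, mesh) {
  stopifnot(inherits(traj, "trajectory3d"), inherits(mesh, "slope_mesh"))
  n <- length(traj$t)
  vx <- .diff_central(traj$t, traj$p[, 1])
  vy <- .diff_central(traj$t, traj$p[, 2])
  vz <- .diff_central(traj$t, traj$p[, 3])
  alpha <- numeric(n)
  prev <- 0
  for (i in seq_len(n)) {
    fr <- surface_frame(mesh, traj$p[i, 1], traj$p[i, 2])
    v <- c(vx[i], vy[i], vz[i])
    vt <- v - sum(v * fr$normal) * fr$normal
    if (sqrt(sum(vt^2)) < 1e-12) {
      alpha[i] <- prev
    } else {
      alpha[i] <- atan2(sum(vt * fr$ey), sum(vt * fr$ex))
      prev <- alpha[i]
    }
  }
  alpha
}

#' Assemble the 3-D model query
#'
#' The learned pose models take a three-dimensional query per sample: radial
#' acceleration `a_r`, absolute velocity `v` and skiing angle `alpha`. The
#' intermediates `r` (curvature radius) and `omega` (turn rate) are kept for
#' diagnostics and for the pendulum estimator.
#'
#' @param traj a `trajectory3d` (antenna track).
#' @param mesh a `slope_mesh`.
#' @param standardize if TRUE, append per-feature z-score parameters (means
#'   and SDs of `a_r`, `v`, `alpha`) as the `scaling` attribute; the stored
#'   columns stay on their physical scales. Model fitters use the attribute.
#' @return A data frame of class `query_series` with columns
#'   `t, a_r, v, alpha, r, omega`.
#' @export
build_query <- function(traj, mesh, standardize = FALSE) {
  ra <- radial_acceleration(traj)
  q <- data.frame(t = traj$t, a_r = ra$a_r, v = speed(traj),
                  alpha = skiing_angle(traj, mesh), r = ra$r, omega = ra$omega)
  class(q) <- c("query_series", "data.frame")
  if (standardize) attr(q, "scaling") <- query_scaling(q)
  q
}

#' Standardization helpers for query features
#'
#' `query_scaling()` computes per-feature means and SDs of `(a_r, v, alpha)`;
#' `standardize_query()` applies a scaling (z-scores) and
#' `destandardize_query()` undoes it exactly.
#'
#' @param q a `query_series` (or data frame with columns a_r, v, alpha).
#' @return `query_scaling()`: list with `center` and `scale` 3-vectors.
#' @export
query_scaling <- function(q) {
  m <- as.matrix(q[, c("a_r", "v", "alpha")])
  s <- apply(m, 2, stats::sd)
  s[s < 1e-12] <- 1 # constant feature: leave unscaled
  list(center = colMeans(m), scale = s)
}

#' @rdname query_scaling
#' @param scaling a list with `center` and `scale` as from `query_scaling()`.
#' @return `standardize_query()`: n-by-3 matrix of z-scored features.
#' @export
standardize_query <- function(q, scaling) {
  m <- as.matrix(q[, c("a_r", "v", "alpha")])
  sweep(sweep(m, 2, scaling$center), 2, scaling$scale, "/")
}

#' @rdname query_scaling
#' @param m an n-by-3 standardized matrix.
#' @return `destandardize_query()`: matrix on the physical scales.
#' @export
destandardize_query <- function(m, scaling) {
  sweep(sweep(m, 2, scaling$scale, "*"), 2, scaling$center, "+")
}
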