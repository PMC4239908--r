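#' Inverted-pendulum model parameters
#'
#' The skier is reduced to a single rigid bar pivoting at the snow contact
#' and kept dynamically balanced by gravity and the radial force. `k` is the
#' COM height as a fraction of the antenna height along the body axis
#' (population values: 0.57 for women, 0.55 for men). Mass cancels in the
#' balance equation and is kept only so radial/gravity forces can be
#' reported; the driving torque is taken as zero and the pendulum inertia as
#' a point mass at the COM.
#'
#' @param k COM height fraction, in (0, 1). Default 0.56.
#' @param g gravitational acceleration (m/s^2).
#' @param m skier mass (kg); does not affect the estimate.
#' @return list of class `pendulum_params`.
#' @export
pendulum_params <- function(k = 0.56, g = 9.81, m = 75) {
  if (k <= 0 || k >= 1) stop("`k` must be in (0, 1)")
  if (g <= 0) stop("`g` must be positive")
  structure(list(k = k, g = g, m = m, tau = 0), class = "pendulum_params")
}

#' Balance-equation residual
#'
#' The dynamic balance of the pendulum reads
#' `l_g * theta_dd + a_r * cos(theta) - (a_z + g) * sin(theta) = 0`,
#' with `theta` the lean from global Z, `l_g` the COM height along the bar,
#' and `(a_r, a_z)` the radial and vertical COM accelerations. This helper
#' evaluates the left-hand side (vectorized).
#'
#' @param theta lean angle (rad).
#' @param a_r radial COM acceleration (m/s^2), signed like `theta`.
#' @param a_z vertical COM acceleration (m/s^2).
#' @param theta_ddot angular acceleration (rad/s^2).
#' @param l_g COM height along the bar (m).
#' @param g gravitational acceleration (m/s^2).
#' @return residual (m/s^2 scale).
#' @export
pendulum_residual <- function(theta, a_r, a_z, theta_ddot, l_g, g = 9.81) {
  l_g * theta_ddot + a_r * cos(theta) - (a_z + g) * sin(theta)
}

#' Closed-form pendulum angle
#'
#' Solves the balance equation for `theta` via the tangent half-angle
#' substitution, which turns it into a quadratic in `tan(theta/2)`. Of the
#' two roots, the one with `|theta| < pi/2` and the smaller balance residual
#' is returned (for `theta_ddot = 0` this reduces to
#' `theta = atan(a_r / (a_z + g))`). Vectorized over samples.
#'
#' @inheritParams pendulum_residual
#' @return `theta` (rad), same length as the inputs.
#' @export
solve_theta <- function(a_r, a_z, theta_ddot, l_g, g = 9.81) {
  A <- a_z + g
  disc <- a_r^2 + A^2 - (l_g * theta_ddot)^2
  if (any(disc < 0))
    stop("no real pendulum angle: |theta_ddot| too large (negative discriminant)")
  den <- l_g * theta_ddot - a_r
  sq <- sqrt(disc)
  # quadratic (lg*thdd - ar) u^2 - 2A u + (lg*thdd + ar) = 0, u = tan(theta/2)
  lin <- abs(den) < 1e-12 * pmax(abs(A), 1)
  u1 <- ifelse(lin, (l_g * theta_ddot + a_r) / (2 * A), (A + sq) / den)
  u2 <- ifelse(lin, (l_g * theta_ddot + a_r) / (2 * A), (A - sq) / den)
  th1 <- 2 * atan(u1)
  th2 <- 2 * atan(u2)
  r1 <- abs(pendulum_residual(th1, a_r, a_z, theta_ddot, l_g, g))
  r2 <- abs(pendulum_residual(th2, a_r, a_z, theta_ddot, l_g, g))
  ok1 <- abs(th1) < pi / 2
  ok2 <- abs(th2) < pi / 2
  pick1 <- (ok1 & !ok2) | (ok1 == ok2 & r1 <= r2)
  ifelse(pick1, th1, th2)
}

#' Kalman smoother for angle, rate and angular acceleration
#'
#' Estimates `(theta, theta_dot, theta_ddot)` from a noisy angle series with
#' a constant-acceleration (white-jerk) process model and position-only
#' measurements: forward Kalman filter followed by a Rauch-Tung-Striebel
#' backward smoothing pass. This is how the angular acceleration entering the
#' balance equation is obtained from the per-sample closed-form angles.
#'
#' @param theta_meas measured angle series (rad), uniformly sampled.
#' @param dt sample interval (s).
#' @param q jerk power spectral density (rad^2/s^5); larger tracks faster
#'   angle dynamics, smaller smooths harder. Default 10.
#' @param r_meas measurement variance (rad^2). Default 1e-4.
#' @return list with numeric vectors `theta`, `theta_dot`, `theta_ddot`.
#' @export
kalman_theta <- function(theta_meas, dt, q = 10, r_meas = 1e-4) {
  n <- length(theta_meas)
  if (n < 10L) stop("need at least 10 samples")
  if (length(dt) != 1L || dt <= 0) stop("`dt` must be a positive scalar")
  F_ <- matrix(c(1, 0, 0,
                 dt, 1, 0,
                 dt^2 / 2, dt, 1), 3, 3)
  Q <- q * matrix(c(dt^5 / 20, dt^4 / 8, dt^3 / 6,
                    dt^4 / 8, dt^3 / 3, dt^2 / 2,
                    dt^3 / 6, dt^2 / 2, dt), 3, 3)
  H <- matrix(c(1, 0, 0), 1, 3)
  xf <- matrix(0, 3, n)      # filtered means
  Pf <- array(0, c(3, 3, n)) # filtered covariances
  xp <- matrix(0, 3, n)      # one-step predictions
  Pp <- array(0, c(3, 3, n))
  x <- c(theta_meas[1], 0, 0)
  P <- diag(c(1, 10, 100))
  for (i in seq_len(n)) {
    if (i > 1L) {
      x <- F_ %*% x
      P <- F_ %*% P %*% t(F_) + Q
    }
    xp[, i] <- x; Pp[, , i] <- P
    S <- P[1, 1] + r_meas
    K <- P[, 1] / S
    x <- x + K * (theta_meas[i] - x[1])
    P <- P - tcrossprod(K, P[, 1])
    xf[, i] <- x; Pf[, , i] <- P
  }
  xs <- xf
  P <- Pf[, , n]
  for (i in (n - 1L):1L) {
    G <- Pf[, , i] %*% t(F_) %*% solve(Pp[, , i + 1L])
    xs[, i] <- xf[, i] + G %*% (xs[, i + 1L] - xp[, i + 1L])
  }
  list(theta = xs[1, ], theta_dot = xs[2, ], theta_ddot = xs[3, ])
}

#' Transfer antenna accelerations to the COM
#'
#' The antenna sits at the top of the pendulum, the COM at fraction `k` of
#' the bar; their offset is `(k - 1) * l` along the lean unit vector
#' `u = sin(theta) e_r + cos(theta) e_z`, with `e_r` the horizontal radial
#' axis of the lean plane rotating at the turn rate `omega`. Differentiating
#' the rigid kinematics twice gives the COM accelerations from the antenna
#' accelerations:
#' \deqn{a_r = a_r^* + (k-1)[\sin\theta(\ddot l - l\dot\theta^2 - l\omega^2)
#'   + \cos\theta(l\ddot\theta + 2\dot l\dot\theta)]}
#' \deqn{a_z = a_z^* + (k-1)[\cos\theta(\ddot l - l\dot\theta^2)
#'   - \sin\theta(l\ddot\theta + 2\dot l\dot\theta)]}
#'
#' @param a_r_star,a_z_star antenna radial / vertical accelerations (m/s^2).
#' @param theta lean angle series (rad).
#' @param l pendulum length series (m).
#' @param k COM height fraction.
#' @param omega turn rate of the lean plane (rad/s).
#' @param dt sample interval (s), used for derivatives not supplied.
#' @param theta_dot,theta_ddot,l_dot,l_ddot optional derivative series; any
#'   left NULL are computed by central differences.
#' @return list with COM acceleration series `a_r`, `a_z`.
#' @export
com_accel_from_antenna <- function(a_r_star, a_z_star, theta, l, k, omega,
                                   dt, theta_dot = NULL, theta_ddot = NULL,
                                   l_dot = NULL, l_ddot = NULL) {
  n <- length(theta)
  if (length(a_r_star) != n || length(a_z_star) != n || length(l) != n ||
      length(omega) != n)
    stop("series length mismatch")
  tgrid <- seq(0, by = dt, length.out = n)
  if (is.null(theta_dot)) theta_dot <- .diff_central(tgrid, theta)
  if (is.null(theta_ddot)) theta_ddot <- .diff_central(tgrid, theta_dot)
  if (is.null(l_dot)) l_dot <- .diff_central(tgrid, l)
  if (is.null(l_ddot)) l_ddot <- .diff_central(tgrid, l_dot)
  km1 <- k - 1
  rad <- l_ddot - l * theta_dot^2
  tan_ <- l * theta_ddot + 2 * l_dot * theta_dot
  list(a_r = a_r_star + km1 * (sin(theta) * (rad - l * omega^2) + cos(theta) * tan_),
       a_z = a_z_star + km1 * (cos(theta) * rad - sin(theta) * tan_))
}

# resample antenna track onto a uniform grid, optionally through a
# cross-validated smoothing spline (GNSS noise suppression)
.prepare_antenna <- function(antenna, target_hz, smooth) {
  fs <- if (antenna$rate_hz >= target_hz) antenna$rate_hz else target_hz
  tt <- seq(antenna$t[1], antenna$t[length(antenna$t)], by = 1 / fs)
  p <- matrix(0, length(tt), 3)
  for (j in 1:3) {
    if (smooth) {
      fit <- stats::smooth.spline(antenna$t, antenna$p[, j])
      p[, j] <- stats::predict(fit, tt)$y
    } else {
      p[, j] <- stats::spline(antenna$t, antenna$p[, j], xout = tt,
                              method = "fmm")$y
    }
  }
  trajectory3d(tt, p, rate_hz = fs)
}

#' Estimate COM and ground-contact trajectories by the inverted pendulum
#'
#' Implements the fixed-point estimation loop: (i) from the antenna track,
#' compute radial acceleration, vertical acceleration and turn rate
#' (three-point circumradius features); (ii) take the antenna accelerations
#' as the first approximation of the COM accelerations; (iii) solve the
#' balance equation per sample for the lean angle; (iv) intersect the lean
#' ray with the slope mesh to get the pendulum length; (v) Kalman-smooth the
#' angle series to obtain the angular acceleration; (vi) transfer the antenna
#' accelerations to the COM through the rigid-pendulum kinematics; repeat
#' (iii)-(vi) until the angle update falls below tolerance.
#'
#' The returned object carries the full per-sample pendulum state plus the
#' derived COM and ground-point trajectories.
#'
#' @param antenna a `trajectory3d` of the GNSS antenna (20 Hz tracks are
#'   resampled to `target_hz` internally).
#' @param mesh a `slope_mesh` covering the run.
#' @param params a [pendulum_params()].
#' @param tol convergence tolerance on `max |delta theta|` (rad).
#' @param max_iter maximum number of outer iterations.
#' @param kalman_q,kalman_r Kalman smoother tuning, see [kalman_theta()].
#' @param smooth smooth the antenna track with a cross-validated spline
#'   before differentiation (recommended whenever the track carries GNSS
#'   noise; near-lossless on clean tracks). Default TRUE.
#' @param target_hz internal working rate (Hz). Default 120.
#' @return An object of class `ski_ip`: list with `pendulum` (per-sample
#'   state data frame), `com`, `ground`, `antenna` (`trajectory3d`),
#'   `n_iterations`, `converged`, `residual_history`, `params`.
#' @export
estimate_ip <- function(antenna, mesh, params = pendulum_params(),
                        tol = 1e-3, max_iter = 20,
                        kalman_q = 10, kalman_r = 1e-4,
                        smooth = TRUE, target_hz = 120) {
  stopifnot(inherits(antenna, "trajectory3d"), inherits(mesh, "slope_mesh"))
  if (diff(range(antenna$t)) < 3) stop("need at least 3 s of data")
  work <- .prepare_antenna(antenna, target_hz, smooth)
  tt <- work$t
  dt <- tt[2] - tt[1]
  n <- length(tt)

  ra <- radial_acceleration(work)
  a_r_star <- ra$a_r
  omega <- ra$omega
  e_lat <- .radial_direction_signed(work)  # fixed left-normal axis
  vz <- .diff_central(tt, work$p[, 3])
  a_z_star <- .diff_central(tt, vz)
  # one-sided differencing makes the outermost samples unreliable; copy the
  # nearest interior feature values
  a_r_star[1:2] <- a_r_star[3]; a_r_star[(n - 1):n] <- a_r_star[n - 2]
  a_z_star[1:2] <- a_z_star[3]; a_z_star[(n - 1):n] <- a_z_star[n - 2]
  omega[1:2] <- omega[3]; omega[(n - 1):n] <- omega[n - 2]

  k <- params$k
  g <- params$g
  # first approximation: COM accelerations = antenna accelerations,
  # quasi-static angle (theta_ddot = 0)
  theta <- solve_theta(a_r_star, a_z_star, 0, 1, g)
  # physical lean bound; also keeps the lean ray steep enough to intersect
  theta <- pmin(pmax(theta, -1.2), 1.2)
  # the outermost two samples stay at the quasi-static solution: one-sided
  # differencing offers no stable angular-acceleration estimate there
  free <- 3:(n - 2)
  residuals <- numeric(0)
  converged <- FALSE
  iter <- 0L
  acc <- list(a_r = a_r_star, a_z = a_z_star)

  repeat {
    iter <- iter + 1L
    # (iv) pendulum length from the lean-ray / mesh intersection,
    # Kalman-smoothed before differentiation (finite differences of the raw
    # per-sample lengths amplify cast jitter by 1/dt^2)
    u <- cbind(sin(theta) * e_lat[, 1], sin(theta) * e_lat[, 2], cos(theta))
    hit <- ray_intersect(mesh, work$p, -u)
    kl <- kalman_theta(hit$t, dt, kalman_q, kalman_r)
    l <- kl$theta
    l_dot <- kl$theta_dot
    l_ddot <- kl$theta_ddot
    l_g <- k * l
    # (v)-(vi) angular acceleration and COM accelerations: theta_ddot is
    # discretized by central differences and the balance equation is updated
    # by one implicit (quasi-Newton) step on the full nonlinear system. The
    # angle feedback through the antenna->COM transfer contributes another
    # (k-1)*l second-difference operator, so the effective implicit weight
    # is l*(2k-1)/dt^2; treating these terms explicitly (closed-form
    # per-sample solve) is unstable above ~1 Hz.
    theta_dot <- .diff_central(tt, theta)
    thdd_tight <- c(0, (theta[1:(n - 2)] - 2 * theta[2:(n - 1)] +
                          theta[3:n]) / dt^2, 0)
    theta_ddot <- thdd_tight
    acc <- com_accel_from_antenna(a_r_star, a_z_star, theta, l, k, omega, dt,
                                  theta_dot = theta_dot, theta_ddot = theta_ddot,
                                  l_dot = l_dot, l_ddot = l_ddot)
    Fv <- l_g * thdd_tight + acc$a_r * cos(theta) - (acc$a_z + g) * sin(theta)
    diagv <- (-acc$a_r * sin(theta) - (acc$a_z + g) * cos(theta) -
                2 * (2 * k - 1) * l / dt^2)[free]
    off <- ((2 * k - 1) * l / dt^2)[free]
    step <- .tridiag_solve(off, diagv, off, -Fv[free])
    step <- pmin(pmax(step, -0.3), 0.3)
    theta_new <- theta
    theta_new[free] <- pmin(pmax(theta[free] + step, -1.2), 1.2)
    dmax <- max(abs(theta_new - theta))
    residuals <- c(residuals, dmax)
    theta <- theta_new
    if (dmax < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  u <- cbind(sin(theta) * e_lat[, 1], sin(theta) * e_lat[, 2], cos(theta))
  hit <- ray_intersect(mesh, work$p, -u)
  l <- hit$t
  ground <- hit$point
  com <- work$p + (k - 1) * l * u
  kf <- kalman_theta(theta, dt, kalman_q, kalman_r)

  pend <- data.frame(t = tt, theta = theta, theta_dot = kf$theta_dot,
                     theta_ddot = kf$theta_ddot, l = l, l_g = k * l,
                     a_r_star = a_r_star, a_z_star = a_z_star,
                     a_r = acc$a_r, a_z = acc$a_z, omega = omega)
  structure(list(pendulum = pend,
                 com = trajectory3d(tt, com, rate_hz = 1 / dt),
                 ground = trajectory3d(tt, ground, rate_hz = 1 / dt),
                 antenna = work,
                 n_iterations = iter,
                 converged = converged,
                 residual_history = residuals,
                 params = params,
                 tol = tol),
            class = "ski_ip")
}

# signed-lean convention: a fixed lateral axis (left normal of horizontal
# velocity); theta > 0 then means leaning left, matching the sign of a_r
.radial_direction_signed <- function(traj) {
  vx <- .diff_central(traj$t, traj$p[, 1])
  vy <- .diff_central(traj$t, traj$p[, 2])
  vh <- sqrt(vx^2 + vy^2)
  vh[vh < 1e-12] <- 1
  cbind(-vy / vh, vx / vh)
}

#' @export
print.ski_ip <- function(x, ...) {
  cat("Inverted-pendulum pose estimate\n")
  cat(sprintf("  samples: %d (%.1f s at %.0f Hz)\n", length(x$com$t),
              diff(range(x$com$t)), x$com$rate_hz))
  cat(sprintf("  iterations: %d (%s, tol %.1e rad)\n", x$n_iterations,
              if (x$converged) "converged" else "NOT converged", x$tol))
  cat(sprintf("  lean angle: %.1f to %.1f deg, pendulum length %.2f-%.2f m\n",
              min(x$pendulum$theta) * 180 / pi, max(x$pendulum$theta) * 180 / pi,
              min(x$pendulum$l), max(x$pendulum$l)))
  invisible(x)
}

#' @export
summary.ski_ip <- function(object, ...) {
  p <- object$pendulum
  res <- pendulum_residual(p$theta, p$a_r, p$a_z, p$theta_ddot, p$l_g,
                           object$params$g)
  out <- list(n = nrow(p), n_iterations = object$n_iterations,
              converged = object$converged,
              residual_history = object$residual_history,
              theta_range_deg = range(p$theta) * 180 / pi,
              l_range = range(p$l),
              balance_residual_rms = sqrt(mean(res^2)))
  class(out) <- "summary.ski_ip"
  out
}

#' @export
print.summary.ski_ip <- function(x, ...) {
  cat("Inverted-pendulum estimate summary\n")
  cat(sprintf("  %d samples; %d iterations (%s)\n", x$n, x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  angle-update history (rad): %s\n",
              paste(sprintf("%.2e", x$residual_history), collapse = " ")))
  cat(sprintf("  lean angle %.1f..%.1f deg, length %.2f..%.2f m\n",
              x$theta_range_deg[1], x$theta_range_deg[2],
              x$l_range[1], x$l_range[2]))
  cat(sprintf("  balance-equation RMS residual: %.3e m/s^2\n",
              x$balance_residual_rms))
  invisible(x)
}

#' @export
fitted.ski_ip <- function(object, which = c("com", "ground"), ...) {
  which <- match.arg(which)
  object[[which]]
}

#' @export
residuals.ski_ip <- function(object, ...) {
  p <- object$pendulum
  pendulum_residual(p$theta, p$a_r, p$a_z, p$theta_ddot, p$l_g,
                    object$params$g)
}

#' @export
plot.ski_ip <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$antenna$p[, 1], x$antenna$p[, 2], type = "l", col = "grey40",
                 xlab = "x (m)", ylab = "y (m)", main = "Horizontal tracks", ...)
  graphics::lines(x$com$p[, 1], x$com$p[, 2], col = "red")
  graphics::lines(x$ground$p[, 1], x$ground$p[, 2], col = "blue")
  graphics::legend("topleft", c("antenna", "COM", "ground"), bty = "n",
                   col = c("grey40", "red", "blue"), lty = 1, cex = 0.8)
  graphics::plot(x$pendulum$t, x$pendulum$theta * 180 / pi, type = "l",
                 xlab = "t (s)", ylab = "lean (deg)", main = "Pendulum angle")
  graphics::plot(x$pendulum$t, x$pendulum$l, type = "l",
                 xlab = "t (s)", ylab = "l (m)", main = "Pendulum length")
  graphics::plot(seq_along(x$residual_history), x$residual_history, log = "y",
                 type = "b", xlab = "iteration", ylab = "max |delta theta| (rad)",
                 main = "Convergence")
  invisible(x)
}
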