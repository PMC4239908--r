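# shared builders and independent oracles for the test suite

# uniform circular motion in the horizontal plane
circle_traj <- function(radius, omega, rate_hz, n_s = 5, z0 = 0, phase = 0) {
  tt <- seq(0, n_s, by = 1 / rate_hz)
  p <- cbind(radius * cos(omega * tt + phase),
             radius * sin(omega * tt + phase),
             rep(z0, length(tt)))
  trajectory3d(tt, p, rate_hz = rate_hz)
}

# uniform straight-line motion
line_traj <- function(v = c(10, 0, 0), rate_hz = 20, n_s = 5,
                      p0 = c(0, 0, 0)) {
  tt <- seq(0, n_s, by = 1 / rate_hz)
  trajectory3d(tt, cbind(p0[1] + v[1] * tt, p0[2] + v[2] * tt,
                         p0[3] + v[3] * tt), rate_hz = rate_hz)
}

# planar mesh z = a*x + b*y + c over a square grid
plane_mesh <- function(a = 0, b = 0, c = 0, half = 60, spacing = 5) {
  xs <- seq(-half, half, by = spacing)
  z <- outer(xs, xs, function(x, y) a * x + b * y + c)
  slope_mesh(-half, -half, spacing, spacing, z)
}

# tight-stencil second difference (the balance equation's theta_ddot
# convention; ends zero)
second_diff <- function(x, dt) {
  n <- length(x)
  c(0, (x[1:(n - 2)] - 2 * x[2:(n - 1)] + x[3:n]) / dt^2, 0)
}

# independent balance-equation residual of a generated pose: recompute the
# COM-path accelerations from the pose positions with the package's discrete
# feature operators and evaluate the balance equation
pose_balance_residual <- function(pose, k) {
  tr <- attr(pose, "truth")
  tt <- pose$t
  dt <- tt[2] - tt[1]
  com <- pose$com
  cv <- skipose:::.curvature_series(com[, 1], com[, 2])
  vx <- skipose:::.diff_central(tt, com[, 1])
  vy <- skipose:::.diff_central(tt, com[, 2])
  a_r <- ifelse(is.finite(cv$r), cv$sign * (vx^2 + vy^2) / cv$r, 0)
  a_z <- skipose:::.diff_central(tt, skipose:::.diff_central(tt, com[, 3]))
  thdd <- second_diff(tr$theta, dt)
  pendulum_residual(tr$theta, a_r, a_z, thdd, k * tr$l)
}

# small fast course for unit tests (acceptance tests use the defaults)
small_course_spec <- function(seed = 1L)
  course_spec(length_m = 160, drop_m = 45, n_gates = 6, rng_seed = seed)

# assemble (query, target) training data from runs at 20 Hz
run_training_data <- function(pose, mesh) {
  idx <- seq(1, length(pose$t), by = 6)
  ant <- trajectory3d(pose$t[idx], pose$antenna[idx, , drop = FALSE], 20)
  q <- build_query(smooth_trajectory(ant), mesh)
  y <- relative_as_matrix(pose_to_relative(pose))[idx, , drop = FALSE]
  n <- min(nrow(q), nrow(y))
  list(q = q[1:n, ], y = y[1:n, , drop = FALSE])
}

# subtract/add a constant 3-vector offset from every row
off3 <- function(m, v) sweep(m, 2, v)
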