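test_that("closed-form pendulum angle solves the balance equation", {
  expect_equal(solve_theta(9.81, 0, 0, 1), pi / 4, tolerance = 1e-12)
  expect_equal(solve_theta(0, 0, 0, 1), 0, tolerance = 1e-12)
  # quasi-static reduction theta = atan(a_r / (a_z + g))
  expect_equal(solve_theta(3, 1, 0, 0.8), atan(3 / (1 + 9.81)),
               tolerance = 1e-12)
  th <- solve_theta(5, 1, 0.3, 1)
  expect_lt(abs(pendulum_residual(th, 5, 1, 0.3, 1)), 1e-9)
})

test_that("closed-form roots agree with a bracketing root-finder", {
  # independent oracle: bracketed uniroot on the balance equation
  set.seed(99)
  n_draws <- 10000
  a_r <- runif(n_draws, -12, 12)
  a_z <- runif(n_draws, -4, 4)
  l_g <- runif(n_draws, 0.5, 1.2)
  # |l_g * thdd| < a_z + g guarantees a unique root inside (-pi/2, pi/2)
  thdd <- runif(n_draws, -0.9, 0.9) * (a_z + 9.81) / l_g
  th <- solve_theta(a_r, a_z, thdd, l_g)
  res <- abs(pendulum_residual(th, a_r, a_z, thdd, l_g))
  expect_lt(max(res), 1e-9)
  expect_true(all(abs(th) < pi / 2))
  # spot-check a sample of draws against uniroot directly
  for (i in sample.int(n_draws, 200)) {
    root <- uniroot(function(x) pendulum_residual(x, a_r[i], a_z[i], thdd[i], l_g[i]),
                    c(-pi / 2 + 1e-9, pi / 2 - 1e-9), tol = 1e-12)$root
    expect_equal(th[i], root, tolerance = 1e-7)
  }
  expect_error(solve_theta(1, 0, 100, 1), "discriminant")
})

test_that("the Kalman smoother recovers angular accelerations", {
  dt <- 1 / 120
  tt <- seq(0, 5, by = dt)
  # quadratic angle: constant true acceleration 0.2
  kf <- kalman_theta(0.1 * tt^2, dt)
  core <- 60:(length(tt) - 60)
  expect_equal(kf$theta_ddot[core], rep(0.2, length(core)), tolerance = 1e-3)
  # constant angle: derivatives vanish
  kf0 <- kalman_theta(rep(0.4, length(tt)), dt)
  expect_lt(max(abs(kf0$theta_dot)), 1e-6)
  expect_lt(max(abs(kf0$theta_ddot)), 1e-6)
  # noisy sinusoid: RMSE of the acceleration under 0.15 rad/s^2
  set.seed(17)
  th <- 0.3 * sin(2 * tt) + rnorm(length(tt), 0, 0.01)
  # r_meas matched to the noise variance, q sized for rad/s^3-scale jerk
  kf2 <- kalman_theta(th, dt, q = 1, r_meas = 1e-4)
  truth <- -0.3 * 4 * sin(2 * tt)
  rmse <- sqrt(mean((kf2$theta_ddot[core] - truth[core])^2))
  expect_lt(rmse, 0.15)
  expect_error(kalman_theta(1:5, dt), "10 samples")
})

test_that("antenna-to-COM transfer matches static and centripetal limits", {
  n <- 20
  ar <- rep(2, n); az <- rep(0.5, n)
  th <- rep(0.3, n); l <- rep(1.4, n)
  out <- com_accel_from_antenna(ar, az, th, l, k = 0.56, omega = rep(0, n),
                                dt = 1 / 120,
                                theta_dot = rep(0, n), theta_ddot = rep(0, n),
                                l_dot = rep(0, n), l_ddot = rep(0, n))
  expect_equal(out$a_r, ar)
  expect_equal(out$a_z, az)
  # pure rotation at fixed length: relative acceleration is centripetal,
  # magnitude offset * theta_dot^2 pointing along the pendulum
  thd <- rep(0.8, n)
  out2 <- com_accel_from_antenna(ar, az, th, l, k = 0.56, omega = rep(0, n),
                                 dt = 1 / 120, theta_dot = thd,
                                 theta_ddot = rep(0, n),
                                 l_dot = rep(0, n), l_ddot = rep(0, n))
  rel <- cbind(out2$a_r - ar, out2$a_z - az)
  mag <- sqrt(rowSums(rel^2))
  expect_equal(mag, rep((1 - 0.56) * 1.4 * 0.8^2, n), tolerance = 1e-12)
})

test_that("antenna-to-COM transfer matches a finite-difference oracle", {
  # scene: pivot moving on a horizontal circle (rotating lean plane), with
  # smoothly varying theta(t) and l(t); compare the analytic transfer with
  # second differences of the exactly-placed antenna and COM points
  dt <- 1 / 120
  tt <- seq(0, 4, by = dt)
  R <- 20; Om <- 0.45; k <- 0.56
  phi <- Om * tt
  e_r <- cbind(-cos(phi), -sin(phi))     # horizontal radial axis (to center)
  theta <- 0.35 * sin(1.3 * tt + 0.4)
  l <- 1.4 + 0.08 * sin(0.9 * tt)
  base <- cbind(R * cos(phi), R * sin(phi), 0.2 * tt)
  u3 <- cbind(sin(theta) * e_r[, 1], sin(theta) * e_r[, 2], cos(theta))
  antenna <- base + l * u3
  com <- base + k * l * u3

  fd2 <- function(m) apply(m, 2, function(col) {
    n <- length(col)
    c(NA, (col[1:(n - 2)] - 2 * col[2:(n - 1)] + col[3:n]) / dt^2, NA)
  })
  acc_ant <- fd2(antenna); acc_com <- fd2(com)
  proj <- function(acc) cbind(rowSums(acc[, 1:2] * e_r), acc[, 3])
  pa <- proj(acc_ant); pc <- proj(acc_com)

  thd <- c(NA, diff(theta, lag = 2) / (2 * dt), NA)
  thdd <- fd2(matrix(theta))[, 1]
  ld <- c(NA, diff(l, lag = 2) / (2 * dt), NA)
  ldd <- fd2(matrix(l))[, 1]
  out <- com_accel_from_antenna(pa[, 1], pa[, 2], theta, l, k,
                                omega = rep(Om, length(tt)), dt = dt,
                                theta_dot = thd, theta_ddot = thdd,
                                l_dot = ld, l_ddot = ldd)
  core <- 5:(length(tt) - 5)
  expect_lt(max(abs(out$a_r[core] - pc[core, 1])), 1e-3)
  expect_lt(max(abs(out$a_z[core] - pc[core, 2])), 1e-3)
})

test_that("the estimator recovers a balanced skier on a small course", {
  cs <- small_course_spec(8L)
  course <- make_course(cs)
  pose <- make_run(course, skier_spec(), cs, seed = 8)
  tr <- attr(pose, "truth")
  ant <- trajectory3d(pose$t, pose$antenna, pose$rate_hz)
  fit <- estimate_ip(ant, course$mesh, pendulum_params(k = 0.56))
  expect_true(fit$converged)
  expect_lte(fit$n_iterations, 10)
  com_err <- sqrt(rowSums((fit$com$p - pose$com)^2))
  expect_lt(sqrt(mean(com_err^2)), 0.02)
  # angle-update history is non-increasing after the second iteration
  rh <- fit$residual_history
  if (length(rh) > 2) expect_true(all(diff(rh[-1]) <= 1e-12))
  # ground point lies on the mesh
  gz <- elevation(course$mesh, fit$ground$p[, 1], fit$ground$p[, 2])
  expect_lt(max(abs(fit$ground$p[, 3] - gz)), 1e-5)
})

test_that("a straight fall-line run reduces to the upright degenerate case", {
  cs <- course_spec(length_m = 160, drop_m = 45, n_gates = 4,
                    gate_lateral_offset_m = 0, rng_seed = 9L)
  course <- make_course(cs)
  pose <- make_run(course, skier_spec(), cs, seed = 9)
  tr <- attr(pose, "truth")
  ant <- trajectory3d(pose$t, pose$antenna, pose$rate_hz)
  fit <- estimate_ip(ant, course$mesh, pendulum_params(k = 0.56))
  expect_true(fit$converged)
  expect_lt(diff(range(fit$pendulum$theta)), 2e-2) # essentially constant
  grd_err <- sqrt(rowSums((fit$ground$p - tr$ground)^2))
  expect_lt(mean(grd_err), 0.01)
})

test_that("estimator methods expose the fit consistently", {
  cs <- small_course_spec(10L)
  course <- make_course(cs)
  pose <- make_run(course, skier_spec(), cs, seed = 10)
  fit <- estimate_ip(trajectory3d(pose$t, pose$antenna, pose$rate_hz),
                     course$mesh, pendulum_params())
  expect_output(print(fit), "Inverted-pendulum")
  s <- summary(fit)
  expect_output(print(s), "iterations")
  expect_s3_class(fitted(fit), "trajectory3d")
  expect_s3_class(fitted(fit, "ground"), "trajectory3d")
  expect_length(residuals(fit), length(fit$com$t))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  expect_error(estimate_ip(line_traj(n_s = 1), plane_mesh()), "3 s")
})
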