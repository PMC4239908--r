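#' Giant-slalom course specification
#'
#' Defaults describe a typical giant-slalom training course: 350 m long with
#' 99 m of drop (mean pitch `atan(99/350) ~ 15.8` deg) and 12 gates set at
#' equal along-slope intervals with alternating lateral offsets.
#'
#' @param length_m course length along the slope (m).
#' @param drop_m altitude difference (m), less than `length_m`.
#' @param n_gates number of gates.
#' @param gate_lateral_offset_m alternating lateral gate offset (m). The
#'   default 4 m gives turn radii around 25 m at the default gate spacing.
#' @param v0 initial speed (m/s).
#' @param v_max speed cap (m/s).
#' @param accel along-path acceleration of the speed ramp (m/s^2).
#' @param rng_seed default random seed for runs generated on this course.
#' @return list of class `course_spec`.
#' @export
course_spec <- function(length_m = 350, drop_m = 99, n_gates = 12,
                        gate_lateral_offset_m = 4,
                        v0 = 8, v_max = 16, accel = 1.5, rng_seed = 1L) {
  if (length_m <= 0 || drop_m <= 0 || n_gates <= 0) stop("course dimensions must be positive")
  if (drop_m >= length_m) stop("`drop_m` must be smaller than `length_m`")
  if (v0 <= 0 || v_max < v0 || accel < 0) stop("invalid speed model")
  structure(list(length_m = length_m, drop_m = drop_m, n_gates = n_gates,
                 gate_lateral_offset_m = gate_lateral_offset_m,
                 v0 = v0, v_max = v_max, accel = accel,
                 rng_seed = as.integer(rng_seed)),
            class = "course_spec")
}

#' Skier specification
#'
#' Geometry and style of a synthetic skier. With `balanced = TRUE` the body
#' axis satisfies the inverted-pendulum balance equation at every sample
#' (the estimator's own model class); with `balanced = FALSE` the style
#' offsets apply: a constant lean bias, a fore-aft COM offset along the
#' direction of travel, turn-synchronous body flexion shortening the
#' antenna height, and smooth stochastic wobble of the COM and of each ski
#' (unpredictable from the trajectory, emulating real technique variability;
#' skis wobble more than the COM).
#'
#' @param l antenna height along the body axis (m), ground to antenna.
#' @param k COM height fraction in (0, 1); 0.57 female, 0.55 male, 0.56 default.
#' @param stance_width_m lateral ski separation (m).
#' @param lean_bias constant lean offset (rad), styled runs only.
#' @param fore_aft fore-aft COM offset along travel direction (m), styled only.
#' @param flexion flexion amplitude (m) shortening `l` in the turns, styled only.
#' @param com_noise_m,ski_noise_m SD of the smooth positional wobble (m),
#'   styled runs only.
#' @param balanced if TRUE the skier is perfectly balanced and style
#'   offsets/noise are ignored.
#' @return list of class `skier_spec`.
#' @export
skier_spec <- function(l = 1.4, k = 0.56, stance_width_m = 0.3,
                       lean_bias = 0, fore_aft = 0, flexion = 0,
                       com_noise_m = 0.01, ski_noise_m = 0.03,
                       balanced = TRUE) {
  if (k <= 0 || k >= 1) stop("`k` must be in (0, 1)")
  if (l <= 0) stop("`l` must be positive")
  if (stance_width_m < 0) stop("`stance_width_m` must be nonnegative")
  structure(list(l = l, k = k, stance_width_m = stance_width_m,
                 lean_bias = lean_bias, fore_aft = fore_aft, flexion = flexion,
                 com_noise_m = com_noise_m, ski_noise_m = ski_noise_m,
                 balanced = isTRUE(balanced)),
            class = "skier_spec")
}

#' GNSS noise specification
#'
#' Defaults match differential RTK GNSS accuracy observed on snow: 95%
#' bounds of 7 mm horizontal and 16 mm vertical, read as ~2 sigma, i.e.
#' sigma_h = 3.5 mm per horizontal axis and sigma_v = 8 mm, at 20 Hz.
#'
#' @param sigma_h horizontal noise SD per axis (m).
#' @param sigma_v vertical noise SD (m).
#' @param rate_hz GNSS sampling rate (Hz).
#' @return list of class `gnss_noise_spec`.
#' @export
gnss_noise_spec <- function(sigma_h = 0.0035, sigma_v = 0.008, rate_hz = 20) {
  if (sigma_h < 0 || sigma_v < 0) stop("noise SDs must be nonnegative")
  if (rate_hz <= 0) stop("`rate_hz` must be positive")
  structure(list(sigma_h = sigma_h, sigma_v = sigma_v, rate_hz = rate_hz),
            class = "gnss_noise_spec")
}

#' Build the course terrain and gate layout
#'
#' The slope is an inclined plane `z = -tan(pitch) * x` with
#' `pitch = atan(drop/length)`, sampled on a regular grid with lateral
#' margin. Gates sit at equal along-slope intervals `length/(n_gates - 1)`
#' with alternating `+/-` lateral offsets.
#'
#' @param spec a [course_spec()].
#' @param grid_spacing mesh node spacing (m).
#' @return list with `mesh` (a `slope_mesh`), `gates` (n_gates-by-3 matrix
#'   with attribute `s`, the along-slope gate positions), and `pitch` (rad).
#' @export
make_course <- function(spec = course_spec(), grid_spacing = 5) {
  stopifnot(inherits(spec, "course_spec"))
  pitch <- atan(spec$drop_m / spec$length_m)
  ds <- spec$length_m / (spec$n_gates - 1)
  s <- (seq_len(spec$n_gates) - 1) * ds
  gx <- s * cos(pitch)
  gy <- spec$gate_lateral_offset_m * (-1)^(seq_len(spec$n_gates) - 1)
  width <- abs(spec$gate_lateral_offset_m) + 30
  xs <- seq(-30, max(gx) + 30, by = grid_spacing)
  ys <- seq(-width, width, by = grid_spacing)
  z <- outer(xs, ys, function(x, y) -tan(pitch) * x)
  mesh <- slope_mesh(xs[1], ys[1], grid_spacing, grid_spacing, z)
  gz <- elevation(mesh, gx, gy)
  gates <- cbind(x = gx, y = gy, z = gz)
  attr(gates, "s") <- s
  list(mesh = mesh, gates = gates, pitch = pitch)
}

# smooth, zero-mean, unit-SD noise: white Gaussian low-passed by two passes
# of a running mean (triangular kernel) over a given window (seconds)
.smooth_noise <- function(n, dt, window_s = 0.5) {
  w <- max(3L, as.integer(round(window_s / dt)))
  x <- stats::rnorm(n + 4L * w)
  x <- stats::filter(x, rep(1 / w, w), sides = 2)
  x <- stats::filter(x, rep(1 / w, w), sides = 2)
  x <- x[(2L * w + 1L):(2L * w + n)]
  x <- x - mean(x)
  sdx <- stats::sd(x)
  if (sdx < 1e-12) return(rep(0, n))
  x / sdx
}

#' Generate a synthetic ski run
#'
#' Builds a smooth ground-contact path through the gates (cubic spline in the
#' lateral coordinate over along-slope position, with small seeded per-run
#' gate-passage jitter), advances the mid-ski point along it with a monotone
#' speed ramp clipped at the cap, and erects the skier on top of it. For a
#' balanced skier the lean angle is solved self-consistently so the balance
#' equation holds at every sample for the COM path's own accelerations
#' (fixed-point iteration to residual < 1e-8); style offsets and wobble
#' apply only to unbalanced skiers. Skis sit at half the stance width either
#' side of the ground point, across the local direction of travel, on the
#' mesh surface.
#'
#' @param course output of [make_course()].
#' @param skier a [skier_spec()].
#' @param spec the [course_spec()] that built the course (speed model, seed).
#' @param rate_hz output sampling rate (Hz). Default 120.
#' @param seed random seed for the per-run jitter; defaults to
#'   `spec$rng_seed`.
#' @return a `pose_series` with attribute `truth`: list with the generating
#'   `theta`, `l`, `ground` matrix, lateral axis `e_lat` and the specs.
#' @export
make_run <- function(course, skier = skier_spec(), spec = course_spec(),
                     rate_hz = 120, seed = NULL) {
  stopifnot(inherits(skier, "skier_spec"), inherits(spec, "course_spec"))
  if (is.null(seed)) seed <- spec$rng_seed
  set.seed(seed)
  mesh <- course$mesh
  gates <- course$gates
  pitch <- course$pitch
  s_g <- attr(gates, "s")

  # lateral path through (jittered) gate positions, parameterized by the
  # along-slope coordinate; jitter emulates run-to-run line choice and
  # scales with how far the line swings
  jit <- stats::rnorm(nrow(gates), 0, 0.075 * abs(spec$gate_lateral_offset_m))
  s_dense <- seq(0, max(s_g), by = 0.05)
  yfun <- stats::splinefun(s_g, gates[, "y"] + jit, method = "fmm")
  y_dense <- yfun(s_dense)

  # smooth monotone speed ramp along the slope, v0 -> v_max over a ~60 m
  # e-folding, with a gentle seeded spline perturbation (run-to-run pacing);
  # everything is kept C2-smooth so path accelerations are well defined
  s_ramp <- 60
  v_base <- spec$v_max - (spec$v_max - spec$v0) * exp(-s_dense / s_ramp)
  kn <- seq(0, max(s_g), length.out = max(4L, ceiling(max(s_g) / 60)))
  vmul <- stats::splinefun(kn, 1 + stats::rnorm(length(kn), 0, 0.015),
                           method = "fmm")
  v_dense <- pmax(v_base * vmul(s_dense), 1)
  # time along the path: dt/ds = J(s)/v(s) with J the 3-D path stretch
  dyds <- yfun(s_dense, deriv = 1)
  J <- sqrt(1 + dyds^2) # (dx,dy,dz)/ds = (cos(pitch), y'(s), -sin(pitch))
  tcum <- .cumtrapz(s_dense, J / v_dense)
  t_end <- tcum[length(tcum)]
  tt <- seq(0, floor(t_end * rate_hz) / rate_hz, by = 1 / rate_hz)
  n <- length(tt)
  s_t <- stats::spline(tcum, s_dense, xout = tt, method = "fmm")$y
  gx <- s_t * cos(pitch)
  gy <- yfun(s_t)
  gz <- elevation(mesh, gx, gy)
  ground <- cbind(gx, gy, gz)

  # direction of travel (horizontal) and its left normal
  vx <- .diff_central(tt, gx); vy <- .diff_central(tt, gy)
  vh <- sqrt(vx^2 + vy^2); vh[vh < 1e-12] <- 1
  e_trav <- cbind(vx / vh, vy / vh)
  e_lat <- cbind(-vy / vh, vx / vh)

  l_series <- rep(skier$l, n)
  theta <- .solve_balanced_theta(tt, ground, e_lat, skier$k, l_series)

  if (!skier$balanced) {
    ra_g <- radial_acceleration(trajectory3d(tt, ground, rate_hz))
    turn_mag <- abs(ra_g$a_r) / max(abs(ra_g$a_r), 1e-9)
    l_series <- l_series - skier$flexion * turn_mag
    # lean bias follows the turn direction smoothly (tanh ramp over ~0.15
    # rad of balanced lean), plus slow stochastic lean variability
    theta <- theta + skier$lean_bias * tanh(theta / 0.15) +
      0.02 * .smooth_noise(n, tt[2] - tt[1], 2.0)
  }

  u <- cbind(sin(theta) * e_lat[, 1], sin(theta) * e_lat[, 2], cos(theta))
  antenna <- ground + l_series * u
  com <- ground + skier$k * l_series * u
  half <- skier$stance_width_m / 2
  ski_l <- cbind(gx + half * e_lat[, 1], gy + half * e_lat[, 2], 0)
  ski_r <- cbind(gx - half * e_lat[, 1], gy - half * e_lat[, 2], 0)
  ski_l[, 3] <- elevation(mesh, ski_l[, 1], ski_l[, 2])
  ski_r[, 3] <- elevation(mesh, ski_r[, 1], ski_r[, 2])

  if (!skier$balanced) {
    dtau <- tt[2] - tt[1]
    com <- com + skier$fore_aft * cbind(e_trav, 0) +
      skier$com_noise_m * cbind(.smooth_noise(n, dtau), .smooth_noise(n, dtau),
                                .smooth_noise(n, dtau))
    ski_l <- ski_l + skier$ski_noise_m *
      cbind(.smooth_noise(n, dtau), .smooth_noise(n, dtau), .smooth_noise(n, dtau))
    ski_r <- ski_r + skier$ski_noise_m *
      cbind(.smooth_noise(n, dtau), .smooth_noise(n, dtau), .smooth_noise(n, dtau))
  }

  # drop 4 samples at each end: the balance solve holds its outermost
  # samples quasi-static (one-sided differencing), so only the smooth
  # interior of the solution is returned
  keep <- 5:(n - 4)
  tk <- tt[keep] - tt[keep[1]]
  pose <- pose_series(tk, antenna[keep, ], com[keep, ], ski_l[keep, ],
                      ski_r[keep, ], rate_hz = rate_hz, check = FALSE)
  attr(pose, "truth") <- list(theta = theta[keep], l = l_series[keep],
                              ground = ground[keep, ], e_lat = e_lat[keep, ],
                              skier = skier, spec = spec, seed = seed)
  pose
}

# Thomas algorithm for a tridiagonal system (sub, diag, super, rhs)
.tridiag_solve <- function(a, b, c_, d) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- c_[1] / b[1]; dp[1] <- d[1] / b[1]
  for (i in 2:n) {
    m <- b[i] - a[i] * cp[i - 1]
    cp[i] <- c_[i] / m
    dp[i] <- (d[i] - a[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# Solve the balance equation over the whole run so that it holds, sample by
# sample, for the accelerations of the COM path that the lean itself
# generates (COM = ground + k l u(theta)), with theta_ddot discretized by
# central differences and the COM accelerations computed with the same
# discrete operators the estimator uses (three-point circumradius, central
# differences). The residual is driven to ~1e-10 by a quasi-Newton
# iteration: the exact discrete residual is evaluated each step, while the
# Jacobian is approximated by its dominant banded part — the explicit
# theta_ddot term plus the COM-offset feedback, whose linearization is
# another k*l*D^2 second-difference operator. Solving that tridiagonal
# system implicitly is what keeps high-frequency modes stable (an explicit
# fixed point amplifies them by k*l/dt^2 and diverges at 120 Hz).
.solve_balanced_theta <- function(tt, ground, e_lat, k, l_series,
                                  g = 9.81, tol = 2e-9, max_iter = 200) {
  n <- nrow(ground)
  dt <- tt[2] - tt[1]
  l_g <- k * l_series
  com_feat <- function(theta) {
    u <- cbind(sin(theta) * e_lat[, 1], sin(theta) * e_lat[, 2], cos(theta))
    com <- ground + k * l_series * u
    cv <- .curvature_series(com[, 1], com[, 2])
    vx <- .diff_central(tt, com[, 1]); vy <- .diff_central(tt, com[, 2])
    vh2 <- vx^2 + vy^2
    a_r <- ifelse(is.finite(cv$r), cv$sign * vh2 / cv$r, 0)
    vz <- .diff_central(tt, com[, 3])
    a_z <- .diff_central(tt, vz)
    list(a_r = a_r, a_z = a_z)
  }
  fe0 <- com_feat(rep(0, n))
  theta <- atan(fe0$a_r / (fe0$a_z + g))
  # two samples at each end stay quasi-static: one-sided differences there
  # break the banded feedback structure and destabilize the iteration
  free <- 3:(n - 2)
  w_res <- l_g / dt^2             # residual: explicit theta_ddot weight
  w_jac <- (l_g + k * l_series) / dt^2 # + COM-offset feedback linearization
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    fe <- com_feat(theta)
    thdd_term <- c(0, w_res[2:(n - 1)] *
                     (theta[1:(n - 2)] - 2 * theta[2:(n - 1)] + theta[3:n]), 0)
    Fv <- thdd_term + fe$a_r * cos(theta) - (fe$a_z + g) * sin(theta)
    if (max(abs(Fv[free])) < tol) { ok <- TRUE; break }
    diagv <- (-fe$a_r * sin(theta) - (fe$a_z + g) * cos(theta) -
                2 * w_jac)[free]
    off <- w_jac[free] # row-local off-diagonal weight (ends unused by solver)
    step <- .tridiag_solve(off, diagv, off, -Fv[free])
    step <- pmin(pmax(step, -0.3), 0.3)
    theta[free] <- theta[free] + step
  }
  if (!ok)
    stop("balanced-skier solution did not converge; speed model too aggressive?")
  theta
}

#' Degrade a pose series to a GNSS antenna track
#'
#' Decimates the antenna channel to the GNSS rate and adds i.i.d. Gaussian
#' noise per axis (seeded, reproducible), emulating the rate mismatch between
#' the 120 Hz reference pose and the 20 Hz GNSS receiver.
#'
#' @param pose a `pose_series` at a rate at least `noise$rate_hz`.
#' @param noise a [gnss_noise_spec()].
#' @param seed random seed.
#' @return a `trajectory3d` at `noise$rate_hz`.
#' @export
degrade_to_gnss <- function(pose, noise = gnss_noise_spec(), seed = 1L) {
  stopifnot(inherits(pose, "pose_series"), inherits(noise, "gnss_noise_spec"))
  if (pose$rate_hz < noise$rate_hz)
    stop("pose rate below the requested GNSS rate")
  step <- pose$rate_hz / noise$rate_hz
  if (abs(step - round(step)) > 1e-6)
    stop("pose rate must be an integer multiple of the GNSS rate")
  idx <- seq(1L, length(pose$t), by = as.integer(round(step)))
  set.seed(seed)
  n <- length(idx)
  p <- pose$antenna[idx, , drop = FALSE]
  p[, 1] <- p[, 1] + stats::rnorm(n, 0, noise$sigma_h)
  p[, 2] <- p[, 2] + stats::rnorm(n, 0, noise$sigma_h)
  p[, 3] <- p[, 3] + stats::rnorm(n, 0, noise$sigma_v)
  trajectory3d(pose$t[idx], p, rate_hz = noise$rate_hz)
}

#' Generate a full synthetic study
#'
#' Emulates the structure of the reference experiment: several skiers with
#' distinct styles, each skiing the same course a few times (18 runs for the
#' default 5 skiers with 4+4+4+3+3 runs). Every run comes with the inputs
#' the pose models consume: the 3-D query built from the GCV-smoothed 20 Hz
#' GNSS-rate antenna track, and the 9-D antenna-relative targets.
#'
#' @param course_spec a [course_spec()]; the shared course.
#' @param runs_per integer vector: runs per skier. Default `c(4,4,4,3,3)`.
#' @param seed master seed; skier styles and per-run seeds derive from it.
#' @param balanced generate balanced skiers (default FALSE: styled skiers
#'   with distinct lean bias, fore-aft offset, flexion and stance).
#' @param gnss optional [gnss_noise_spec()] to sample the antenna track at
#'   GNSS rate with noise; NULL (default) decimates the clean track.
#' @return list with `course`, `skiers` (list of `skier_spec`), and `runs`:
#'   a named list (one element per skier) of per-run lists with `pose`,
#'   `antenna` (20 Hz `trajectory3d`), `query` and `target`, ready for
#'   [cross_validate()].
#' @export
make_study <- function(course_spec = skipose::course_spec(),
                       runs_per = c(4L, 4L, 4L, 3L, 3L),
                       seed = 1L, balanced = FALSE, gnss = NULL) {
  course <- make_course(course_spec)
  set.seed(seed)
  n_sk <- length(runs_per)
  skiers <- lapply(seq_len(n_sk), function(i)
    skier_spec(l = stats::runif(1, 1.3, 1.5),
               k = stats::runif(1, 0.55, 0.57),
               stance_width_m = stats::runif(1, 0.25, 0.4),
               lean_bias = stats::runif(1, -0.1, 0.1),
               fore_aft = stats::runif(1, -0.12, 0.12),
               flexion = stats::runif(1, 0, 0.25),
               balanced = balanced))
  names(skiers) <- paste0("S", seq_len(n_sk))
  runs <- lapply(seq_len(n_sk), function(i) {
    lapply(seq_len(runs_per[i]), function(r) {
      run_seed <- (seed * 1000L + i * 100L + r) %% .Machine$integer.max
      pose <- make_run(course, skiers[[i]], course_spec, seed = run_seed)
      idx <- seq(1L, length(pose$t), by = max(1L, round(pose$rate_hz / 20)))
      ant <- trajectory3d(pose$t[idx], pose$antenna[idx, , drop = FALSE], 20)
      if (!is.null(gnss)) {
        ant <- degrade_to_gnss(pose, gnss, seed = run_seed)
      }
      ants <- smooth_trajectory(ant)
      q <- build_query(ants, course$mesh)
      nq <- min(nrow(q), length(idx))
      target <- relative_as_matrix(pose_to_relative(pose))[idx[1:nq], ,
                                                          drop = FALSE]
      list(pose = pose, antenna = ant, query = q[1:nq, ],
           target = matrix_as_relative(target))
    })
  })
  names(runs) <- names(skiers)
  list(course = course, skiers = skiers, runs = runs)
}
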