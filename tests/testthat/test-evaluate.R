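test_that("path normalization places samples at equal path fractions", {
  n <- 101
  path <- cbind(seq(0, 100, length.out = n), 0, 0)
  vals <- seq(0, 100, length.out = n) # value == distance along path
  out <- path_normalize(vals, path, n_points = 11)
  expect_equal(unname(out), seq(0, 100, by = 10), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(attr(out, "s"), seq(0, 1, by = 0.1))
  # normalizing an already-normalized series is the identity
  out2 <- path_normalize(out, cbind(seq(0, 1, by = 0.1), 0, 0), n_points = 11)
  expect_equal(unname(out2), unname(out), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("arc-length fractions on a circle match the analytic values", {
  th <- seq(0, pi, length.out = 721)
  path <- cbind(30 * cos(th), 30 * sin(th), 0)
  out <- path_normalize(th, path, n_points = 101)
  # arc length grows linearly in angle: resampled angle = s * pi
  expect_lt(max(abs(as.vector(out) - seq(0, 1, length.out = 101) * pi)), 1e-4)
  expect_error(path_normalize(1:5, cbind(rep(0, 5), 0, 0)), "zero total")
  # duration normalization needs t
  expect_error(path_normalize(1:5, by = "time"), "required")
})

test_that("pose errors are per-sample Euclidean norms", {
  n <- 40
  tt <- seq(0, 2, length.out = n)
  ant <- cbind(10 * tt, 0, 5)
  ref <- pose_series(tt, ant, off3(ant, c(0, 0, 0.5)),
                     off3(ant, c(0, 0.2, 1.5)), off3(ant, c(0, -0.2, 1.5)))
  expect_true(all(pose_error(ref, ref) == 0))
  est <- ref
  est$com <- ref$com + rep(c(0.03, 0.04, 0), each = n)
  err <- pose_error(est, ref)
  expect_equal(err$com, rep(0.05, n))
  expect_equal(err$ski_mean, rep(0, n))

  set.seed(3)
  est2 <- ref
  off <- matrix(rnorm(n * 3, 0, 0.1), n, 3)
  est2$ski_left <- ref$ski_left + off
  expect_equal(pose_error(est2, ref)$ski_left, sqrt(rowSums(off^2)),
               tolerance = 1e-12)
})

test_that("mid-ski geometry behaves as the weighting assumption implies", {
  n <- 30
  tt <- seq(0, 2, length.out = n)
  ant <- cbind(8 * tt, sin(tt), 5)
  mk <- function(stance) {
    pose_series(tt, ant, off3(ant, c(0, 0, 0.6)),
                off3(ant, c(0, -stance / 2, 1.5)),
                off3(ant, c(0, stance / 2, 1.5)))
  }
  narrow <- mk(0.2); wide <- mk(0.6)
  # midpoint independent of stance width for a symmetric stance
  expect_equal((narrow$ski_left + narrow$ski_right) / 2,
               (wide$ski_left + wide$ski_right) / 2)
  zero <- mk(0)
  expect_equal(zero$ski_left, (zero$ski_left + zero$ski_right) / 2)
})

test_that("error curves aggregate runs with pointwise mean and SD", {
  n <- 50
  path <- cbind(seq(0, 100, length.out = n), 0, 0)
  e1 <- rep(0.1, n)
  one <- aggregate_runs(list(e1), list(path), n_points = 20)
  expect_equal(one$mean, rep(0.1, 20))
  expect_equal(one$sd, rep(0, 20))
  two <- aggregate_runs(list(e1, e1), list(path, path), n_points = 20)
  expect_equal(two$sd, rep(0, 20))
  # arithmetic oracle with constant-per-run errors
  three <- aggregate_runs(list(rep(1, n), rep(2, n), rep(4, n)),
                          list(path, path, path), n_points = 10)
  expect_equal(three$mean, rep(mean(c(1, 2, 4)), 10))
  expect_equal(three$sd, rep(sd(c(1, 2, 4)), 10))
})

test_that("cross-validation tables have the reference layout", {
  st <- make_study(course_spec(length_m = 160, drop_m = 45, n_gates = 5),
                   runs_per = c(2L, 2L, 1L), seed = 3)
  tab <- cross_validate(st$runs, method = "lwpr")
  expect_equal(dim(tab$com_mean), c(5L, 3L)) # total runs x skiers
  expect_true(all(tab$com_mean >= 0))
  expect_true(all(tab$ski_mean >= 0))
  df <- crossval_as_data_frame(tab)
  expect_true(all(c("model_S1", "mean_S1", "sd_S1") %in% names(df)))
  expect_match(df$model_S1[1], "^[0-9.]+ \\([0-9.]+\\)$")
  # single skier: degenerate 1-column table
  tab1 <- cross_validate(st$runs["S3"], method = "lwpr")
  expect_equal(dim(tab1$com_mean), c(1L, 1L))
})

test_that("off-diagonal pairing yields runs x (skiers - 1) cases", {
  # synthetic table layout: 5 skiers, 18 runs (4+4+4+3+3)
  labels <- do.call(rbind, Map(function(s, k)
    data.frame(skier = s, run = seq_len(k)),
    paste0("S", 1:5), c(4, 4, 4, 3, 3)))
  m <- matrix(runif(18 * 5), 18, 5,
              dimnames = list(paste(labels$skier, labels$run, sep = ":"),
                              paste0("S", 1:5)))
  fake <- function(m) structure(list(com_mean = m, ski_mean = m,
                                     labels = labels), class = "crossval_table")
  pairs <- crossval_pairs(fake(m), fake(m + 1))
  expect_equal(nrow(pairs), 72L) # 90 cells - 18 own-subject cells
  expect_true(all(pairs$skier != pairs$model))
  tt <- paired_t_test(pairs$a, pairs$b)
  expect_equal(tt$df, 71L)
})

test_that("paired t-test matches closed-form and reference implementations", {
  expect_equal(paired_t_test(c(1, 2, 3), c(1, 2, 3))[c("t", "p")],
               list(t = 0, p = 1))
  out <- paired_t_test(c(2, 4, 6, 8), c(1, 2, 3, 4)) # differences 1,2,3,4
  expect_equal(out$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(out$t, 3.872983, tolerance = 1e-6)
  expect_equal(out$df, 3L)
  # antisymmetry
  expect_equal(paired_t_test(c(1, 5, 2), c(4, 1, 1))$t,
               -paired_t_test(c(4, 1, 1), c(1, 5, 2))$t)
  # reference oracle: stats::t.test on 100 random paired samples
  set.seed(12)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    a <- rnorm(n); b <- rnorm(n, 0.2)
    mine <- paired_t_test(a, b)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
  }
  # degenerate: constant nonzero difference
  zv <- paired_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_equal(zv$p, 0)
  expect_error(paired_t_test(1:3, 1:4), "paired")
})

test_that("the pendulum ground point is scored against the mid-ski point", {
  cs <- small_course_spec(12L)
  course <- make_course(cs)
  pose <- make_run(course, skier_spec(stance_width_m = 0), cs, seed = 12)
  fit <- estimate_ip(trajectory3d(pose$t, pose$antenna, pose$rate_hz),
                     course$mesh, pendulum_params())
  err <- ip_ground_error(fit, pose)
  expect_lt(mean(err$ground), 0.02)
  expect_lt(mean(err$com), 0.02)
})
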