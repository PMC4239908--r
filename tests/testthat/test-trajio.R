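test_that("trajectory validation rejects malformed input", {
  expect_error(trajectory3d(c(0, 1), matrix(0, 2, 3)), "at least 3")
  expect_error(trajectory3d(c(0, 2, 1), matrix(0, 3, 3)), "increasing")
  expect_error(trajectory3d(c(0, 1, 2), matrix(c(0, NA, rep(0, 7)), 3, 3)),
               "finite")
  expect_error(trajectory3d(c(0, 1, 2), matrix(0, 3, 2)), "3 columns")
})

test_that("trajectory CSV round trip is lossless at 9 decimals", {
  set.seed(42)
  tr <- trajectory3d(seq(0, 2, by = 0.05),
                     matrix(rnorm(123, sd = 30), ncol = 3), rate_hz = 20)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(back$t, round(tr$t, 9))
  expect_equal(unname(back$p), unname(round(tr$p, 9)), tolerance = 1e-12)
  # write-then-read of already-rounded values is the exact identity
  f2 <- tempfile(fileext = ".csv")
  write_trajectory(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("trajectory reader enforces the documented format", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("t,x,q,z", "0,1,2,3"), f)
  expect_error(read_trajectory(f), "t,x,y,z")
  writeLines(c("t,x,y,z", "0,1,2,3", "1,NA,2,3", "2,1,2,3", "3,1,2,3"), f)
  expect_message(tr <- read_trajectory(f), "dropped")
  expect_equal(length(tr$t), 3L)
  writeLines(c("t,x,y,z", "0,1,2,3", "0.5,1,2,3"), f)
  expect_error(suppressMessages(read_trajectory(f)), "fewer than 3")
})

test_that("trajectory file column order is stable (golden file)", {
  tr <- trajectory3d(c(0, 0.05, 0.1, 0.15),
                     cbind(c(0, 0.75, 1.5, 2.25), c(0, 0.1, 0.2, 0.3),
                           c(10, 9.9, 9.8, 9.7)), rate_hz = 20)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  expect_identical(readLines(f), readLines(test_path("golden_trajectory.csv")))
})

test_that("pose round trip preserves fields and the shared time base", {
  set.seed(7)
  n <- 30
  tt <- seq(0, 1, length.out = n)
  ant <- cbind(tt * 10, sin(tt), 2 + 0 * tt)
  pose <- pose_series(tt, ant, off3(ant, c(0, 0, 0.6)),
                      off3(ant, c(0.2, 0.1, 1.6)), off3(ant, c(0.2, -0.1, 1.6)))
  f <- tempfile(fileext = ".csv")
  write_pose(pose, f)
  back <- read_pose(f)
  expect_equal(back$t, round(pose$t, 9))
  for (fld in c("antenna", "com", "ski_left", "ski_right"))
    expect_equal(unname(back[[fld]]), unname(round(pose[[fld]], 9)))
  expect_identical(strsplit(readLines(f, n = 1), ",")[[1]],
                   c("t", "ax", "ay", "az", "cx", "cy", "cz",
                     "lx", "ly", "lz", "rx", "ry", "rz"))
})

test_that("relative pose <-> pose series is a bijection given the antenna", {
  set.seed(11)
  n <- 25
  tt <- seq(0, 2, length.out = n)
  ant <- matrix(rnorm(n * 3), n, 3)
  ant[, 3] <- ant[, 3] + 10
  pose <- pose_series(tt, ant, off3(ant, c(0, 0, 0.5)),
                      off3(ant, c(0, 0.2, 1.5)), off3(ant, c(0, -0.2, 1.5)))
  rel <- pose_to_relative(pose)
  back <- relative_to_pose(rel, trajectory3d(tt, ant))
  expect_identical(back$com, pose$com)
  expect_identical(back$ski_left, pose$ski_left)
  expect_identical(back$ski_right, pose$ski_right)
  # matrix flattening round trip
  expect_identical(matrix_as_relative(relative_as_matrix(rel))$d_com, rel$d_com)
})

test_that("cubic-spline upsampling is exact on cubic paths", {
  tt <- seq(0, 2, by = 1 / 20)
  poly <- function(t) cbind(1 + 2 * t - 0.5 * t^2 + 0.25 * t^3,
                            3 - t + t^2, 2 + t^3)
  tr <- trajectory3d(tt, poly(tt), rate_hz = 20)
  up <- upsample_spline(tr, 120)
  expect_equal(up$rate_hz, 120)
  expect_lt(max(abs(up$p - poly(up$t))), 1e-9)
  # original instants reproduce original values
  idx <- match(round(tr$t, 9), round(up$t, 9))
  expect_lt(max(abs(up$p[idx, ] - tr$p)), 1e-9)
})

test_that("upsampling keeps constants constant and validates input", {
  tt <- seq(0, 1, by = 1 / 20)
  tr <- trajectory3d(tt, matrix(5, length(tt), 3), rate_hz = 20)
  up <- upsample_spline(tr, 120)
  expect_true(all(abs(up$p - 5) < 1e-12))
  expect_error(upsample_spline(tr, 10), "exceed")
  tr3 <- trajectory3d(c(0, 1, 2), matrix(rnorm(9), 3, 3), rate_hz = 1)
  expect_error(upsample_spline(tr3, 10), "4 samples")
})

test_that("upsampled circular arc stays within 1e-4 m of the circle", {
  # 25 m radius at 15 m/s, sampled at 20 Hz, upsampled to 120 Hz
  r <- 25; v <- 15
  tr <- circle_traj(r, v / r, 20, n_s = 4)
  up <- upsample_spline(tr, 120)
  radial_dev <- abs(sqrt(up$p[, 1]^2 + up$p[, 2]^2) - r)
  expect_lt(max(radial_dev), 1e-4)
})

test_that("squat synchronization recovers known time offsets", {
  squat_vz <- function(tt, t0) {
    # downward then upward spike: vz = d/dt of a Gaussian dip
    -(-2 * (tt - t0) / 0.18) * 0.25 * exp(-(tt - t0)^2 / 0.18)
  }
  tt <- seq(0, 10, by = 1 / 120)
  a <- data.frame(t = tt, vz = squat_vz(tt, 4))
  expect_equal(sync_by_squat(a, a), 0)
  b <- data.frame(t = tt, vz = squat_vz(tt, 4.5))
  expect_equal(sync_by_squat(b, a), 0.5, tolerance = 1 / 120)
  # noisy recovery: 5 mm-scale velocity noise, 20 Hz vs 120 Hz streams
  set.seed(3)
  t20 <- seq(0, 10, by = 1 / 20)
  c_ <- data.frame(t = t20, vz = squat_vz(t20, 4.35) + rnorm(length(t20), 0, 0.005))
  expect_equal(sync_by_squat(c_, a), 0.35, tolerance = 2 / 20)
  flat <- data.frame(t = tt, vz = rep(-1, length(tt)))
  expect_error(sync_by_squat(flat, a), "zero-crossing")
})
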