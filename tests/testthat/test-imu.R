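test_that("an aligned sensor needs no correction", {
  corr <- estimate_orientation(static_imu(c(0, 0, -1)))
  expect_equal(corr$alpha_rad, 0)
  expect_equal(corr$beta_rad, 0)
  expect_equal(corr$rotation, diag(3))
})

test_that("a 30 degree tilt is recovered and corrected to (0,0,-1) g", {
  corr <- estimate_orientation(static_imu(c(0.5, 0, -sqrt(3) / 2)))
  expect_equal(corr$beta_rad * 180 / pi, 30, tolerance = 1e-9)
  expect_equal(corr$alpha_rad, 0, tolerance = 1e-12)
  corrected <- corr$rotation %*% c(0.5, 0, -sqrt(3) / 2)
  expect_equal(as.numeric(corrected), c(0, 0, -1), tolerance = 1e-12)
})

test_that("orientation estimation round-trips random tilts to 1e-9 g", {
  set.seed(99)
  worst <- 0
  for (k in 1:200) {
    ab <- runif(2, -30, 30) * pi / 180
    R <- equiback:::tilt_rotation(ab[1], ab[2])
    sensor_reading <- as.numeric(t(R) %*% c(0, 0, -1))
    corr <- estimate_orientation(static_imu(sensor_reading))
    corrected <- as.numeric(corr$rotation %*% sensor_reading)
    worst <- max(worst, sqrt(sum((corrected - c(0, 0, -1))^2)))
  }
  expect_lt(worst, 1e-9)
})

test_that("a moving window is rejected for calibration", {
  t <- seq(0, 2, by = 1 / 225)
  shaky <- imu_recording(back_ts(t, cbind(0.1 * sin(2 * pi * 3 * t), 0, -1)),
                         units = "g")
  expect_error(estimate_orientation(shaky), "not motionless")
})

test_that("terrestrial correction is an isometry and identity when aligned", {
  tr <- simulate_trial(gait_params("trot"), sensor_params(), 8, seed = 2)
  rec <- tr$imus$withers
  ident <- estimate_orientation(static_imu(c(0, 0, -1)))
  expect_equal(correct_to_terrestrial(rec, ident)$accel$values,
               rec$accel$values)
  static_rec <- rec
  static_rec$accel <- trim(rec$accel, c(0.2, 2.7))
  corr <- estimate_orientation(static_rec)
  out <- correct_to_terrestrial(rec, corr)
  expect_equal(sqrt(rowSums(out$accel$values^2)),
               sqrt(rowSums(rec$accel$values^2)), tolerance = 1e-12)
})

test_that("zero acceleration integrates to zero displacement", {
  t <- seq(0, 10, by = 1 / 225)
  rec <- imu_recording(back_ts(t, cbind(0, 0, rep(-1, length(t)))), units = "g")
  d <- vertical_displacement(rec)
  expect_lt(max(abs(d$values)), 1e-9)
})

test_that("sinusoidal acceleration recovers displacement amplitude within 2%", {
  A <- 0.03; f <- 2
  t <- seq(0, 10, by = 1 / 225)
  az_ms2 <- -A * (2 * pi * f)^2 * sin(2 * pi * f * t)
  rec <- imu_recording(back_ts(t, cbind(0, 0, az_ms2 / 9.81 - 1)), units = "g")
  d <- vertical_displacement(rec)
  amp <- max(abs(d$values[t > 2 & t < 8]))
  expect_lt(abs(amp - A) / A, 0.02)

  # a constant accelerometer offset must be rejected by the drift filter
  rec_off <- rec
  rec_off$accel$values[, 3] <- rec_off$accel$values[, 3] + 0.05
  d_off <- vertical_displacement(rec_off)
  amp_off <- max(abs(d_off$values[t > 2 & t < 8]))
  expect_lt(abs(amp_off - amp) / A, 0.05)
})

test_that("flat displacements give a 180 degree back angle", {
  t <- seq(0, 2, by = 1 / 200)
  z <- back_ts(t, rep(0, length(t)))
  ang <- compute_imu_angle(displacement_triplet(z, z, z),
                           geometry_config(0.5, 0.5))
  expect_equal(ang$values, rep(180, length(t)), tolerance = 1e-9)
})

test_that("the trigonometric angle matches its closed form", {
  t <- seq(0, 2, by = 1 / 200)
  z0 <- back_ts(t, rep(0, length(t)))
  zt <- back_ts(t, rep(-0.05, length(t)))   # delta-z = 0.05 m
  ang <- compute_imu_angle(displacement_triplet(z0, zt, z0),
                           geometry_config(0.5, 0.5), smooth_cutoff_hz = NULL)
  expect_equal(ang$values[1], 2 * acos(0.1) * 180 / pi, tolerance = 1e-9)
  expect_equal(ang$values[1], 168.5216, tolerance = 1e-4)
})

test_that("the IMU angle decreases in delta-z and is symmetric in X, X2", {
  t <- seq(0, 1, by = 1 / 200)
  ang_for <- function(dz, x, x2) {
    z0 <- back_ts(t, rep(0, length(t)))
    zt <- back_ts(t, rep(-dz, length(t)))
    compute_imu_angle(displacement_triplet(z0, zt, z0),
                      geometry_config(x, x2), smooth_cutoff_hz = NULL)$values[1]
  }
  dz <- seq(-0.2, 0.2, by = 0.05)
  angles <- vapply(dz, ang_for, 1, x = 0.5, x2 = 0.4)
  expect_true(all(diff(angles) < 0))
  for (d in dz) {
    expect_equal(ang_for(d, 0.3, 0.6), ang_for(d, 0.6, 0.3), tolerance = 1e-12)
  }
})

test_that("extreme delta-z is clipped and counted", {
  t <- seq(0, 1, by = 1 / 200)
  z0 <- back_ts(t, rep(0, length(t)))
  zt <- back_ts(t, rep(-0.6, length(t)))   # exceeds both segment lengths
  ang <- compute_imu_angle(displacement_triplet(z0, zt, z0),
                           geometry_config(0.5, 0.5), smooth_cutoff_hz = NULL)
  expect_true(all(is.finite(ang$values)))
  expect_equal(attr(ang, "clip_count"), 2 * length(t))
})
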