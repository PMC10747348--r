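test_that("identical seeds reproduce bit-identical trials", {
  gp <- gait_params("trot")
  a <- simulate_trial(gp, sensor_params(), 8, seed = 123)
  b <- simulate_trial(gp, sensor_params(), 8, seed = 123)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- simulate_trial(gp, sensor_params(), 8, seed = 124)
  expect_false(identical(a$markers$t18$values, c2$markers$t18$values))
})

test_that("truth ranges equal the configured target by construction", {
  for (g in c("walk", "trot", "gallop")) {
    gp <- gait_params(g)
    tr <- simulate_trial(gp, sensor_params_ideal(), 10, seed = 1)
    expect_true(all(tr$truth$ranges$flexion_deg == gp$target_flexion_deg))
    expect_gte(nrow(tr$truth$ranges), 3)
  }
})

test_that("the analytic angle is 180 degrees during the pre-roll and hits the target range", {
  gp <- gait_params("trot")
  expect_equal(analytic_angle(gp, c(0, 1, 2.9)), rep(180, 3))
  # peak-to-trough over one steady cycle equals the target
  t <- seq(6, 6 + 1 / gp$cycle_hz, by = 1e-4)
  a <- analytic_angle(gp, t)
  expect_equal(max(a) - min(a), gp$target_flexion_deg, tolerance = 1e-6)
})

test_that("the analytic angle agrees with compute_imu_angle on noiseless displacements", {
  gp <- gait_params("trot")
  t <- seq(0, 10, by = 1 / 200)
  d <- equiback:::osc_pos(t, 3, 1, 2 * pi * gp$cycle_hz,
                          equiback:::solve_differential_amp(3.9, gp$geometry))
  z0 <- back_ts(t, rep(0, length(t)))
  zt <- back_ts(t, -d)
  ang <- compute_imu_angle(displacement_triplet(z0, zt, z0), gp$geometry,
                           smooth_cutoff_hz = NULL)
  expect_lt(max(abs(ang$values - analytic_angle(gp, t))), 0.05)
})

test_that("tilted static windows still read exactly 1 g", {
  tilt <- data.frame(sensor = c("withers", "t18", "pelvis", "pastern"),
                     alpha_deg = c(10, -5, 3, 0),
                     beta_deg = c(-5, 10, -8, 2))
  tr <- simulate_trial(gait_params("trot"),
                       sensor_params_ideal(tilt = tilt), 8, seed = 1)
  for (s in c("withers", "t18", "pelvis")) {
    acc <- tr$imus[[s]]$accel
    still <- acc$values[acc$time < 2.5, ]
    expect_equal(mean(sqrt(rowSums(still^2))), 1, tolerance = 1e-9)
  }
})

test_that("IMU acceleration is the second derivative of the site trajectory", {
  # finite differences of the 200 Hz marker positions vs the generated
  # acceleration; the central-difference bias at these rates is ~5e-3 m/s^2
  gp <- gait_params("trot")
  tr <- simulate_trial(gp, sensor_params_ideal(), 8, seed = 4)
  zm <- tr$markers$t18$values[, 3]
  tm <- tr$markers$t18$time
  h <- tm[2] - tm[1]
  acc_fd <- diff(zm, differences = 2) / h^2
  t_fd <- tm[2:(length(tm) - 1)]
  # terrestrial z acceleration from the zero-tilt g-convention reading
  rec <- tr$imus$t18$accel
  acc_imu <- (rec$values[, 3] + 1) * 9.81
  acc_interp <- stats::spline(rec$time, acc_imu, xout = t_fd)$y
  # check the static and steady-gait segments; the stand-to-gait ramp has
  # jerk discontinuities where the central difference itself is biased
  segs <- (t_fd > 0.5 & t_fd < 2.5) | (t_fd > 4.5 & t_fd < 7.5)
  expect_lt(max(abs(acc_fd - acc_interp)[segs]), 0.02)
})

test_that("configured accelerometer noise is realised", {
  sp <- sensor_params(accel_noise_sd_g = 0.02, tilt = equiback:::flat_tilt(),
                      marker_noise_sd_mm = 0, imu_bias_offset_deg = 0)
  tr <- simulate_trial(gait_params("walk"), sp, 60, seed = 8)
  acc <- tr$imus$pelvis$accel
  still <- acc$values[acc$time < 2.8, ]
  sds <- apply(still, 2, sd)
  # pooled over 3 axes x ~630 samples
  expect_lt(abs(sqrt(mean(sds^2)) - 0.02) / 0.02, 0.05)
})

test_that("geometrically unreachable targets are rejected", {
  expect_error(
    equiback:::solve_differential_amp(250, geometry_config(0.1, 0.5)),
    "unreachable")
  expect_error(gait_params("trot", target_flexion_deg = 2,
                           target_extension_deg = 3), "equal")
})

test_that("noise-free agreement simulation is exact and noisy bias is recovered", {
  p0 <- simulate_agreement_study(3, 5, bias_deg = 0, noise_sd_deg = 0, seed = 2)
  ba <- bland_altman(p0)
  expect_equal(ba$bias, 0, tolerance = 1e-12)
  expect_equal(pearson_with_strength(p0)$r, 1, tolerance = 1e-12)

  p <- simulate_agreement_study(4, c(walk = 28, trot = 29, gallop = 28),
                                bias_deg = 0.8, noise_sd_deg = 1.5, seed = 3)
  expect_lt(abs(bland_altman(p)$bias - 0.8), 2 * 1.5 / sqrt(340))
})
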