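test_that("extrema of a clean sinusoid are all found and alternate", {
  t <- seq(0, 3, by = 1 / 200)
  ang <- angle_trace(t, 180 + 2 * sin(2 * pi * 2.8 * t), method = "mocap")
  # maxima at t = (0.25 + k)/2.8 for k = 0..8, minima at (0.75 + k)/2.8
  # for k = 0..7 within [0, 3]
  ex <- find_extrema(ang, "trot", edge_guard_s = 0)
  expect_equal(sum(ex$kinds == "max"), 9)
  expect_equal(sum(ex$kinds == "min"), 8)
  expect_true(all(ex$kinds[-1] != ex$kinds[-length(ex$kinds)]))
  # parabolic refinement recovers the true amplitude closely
  expect_lt(max(abs(abs(ex$values - 180) - 2)), 1e-3)

  # with the default 0.5 s edge guard, edge-touching extrema are dropped
  ex_guard <- find_extrema(ang, "trot")
  expect_true(all(ex_guard$times >= 0.5 & ex_guard$times <= 2.5))
})

test_that("a constant trace is a segmentation error", {
  t <- seq(0, 3, by = 1 / 200)
  ang <- angle_trace(t, rep(180, length(t)), method = "imu")
  expect_error(find_extrema(ang, "trot"), "extrema")
})

test_that("sub-prominence jitter does not change the extrema count", {
  t <- seq(0, 5, by = 1 / 200)
  clean <- angle_trace(t, 180 + 2 * sin(2 * pi * 2.8 * t), method = "mocap")
  set.seed(5)
  noisy <- angle_trace(t, clean$values + runif(length(t), -0.1, 0.1),
                       method = "mocap")
  n_clean <- length(find_extrema(clean, "trot")$times)
  n_noisy <- length(find_extrema(noisy, "trot")$times)
  expect_equal(n_noisy, n_clean)
})

test_that("ranges follow the max/min bookkeeping", {
  ex <- structure(list(times = 1:5,
                       values = c(181, 178, 183, 177, 182),
                       kinds = c("max", "min", "max", "min", "max")),
                  class = "extrema_seq")
  rt <- compute_ranges(ex)
  expect_equal(rt$extension_deg, c(3, 6))
  expect_equal(rt$flexion_deg, c(5, 5))

  # a leading minimum is dropped
  ex2 <- structure(list(times = 0:5,
                        values = c(179, 181, 178, 183, 177, 182),
                        kinds = c("min", "max", "min", "max", "min", "max")),
                   class = "extrema_seq")
  expect_equal(compute_ranges(ex2)$extension_deg, c(3, 6))

  # trailing minimum: extension only, no flexion
  ex3 <- structure(list(times = 1:2, values = c(182, 178),
                        kinds = c("max", "min")), class = "extrema_seq")
  rt3 <- compute_ranges(ex3)
  expect_equal(rt3$extension_deg, 4)
  expect_true(is.na(rt3$flexion_deg))
})

test_that("on a symmetric wave every flexion equals every extension", {
  t <- seq(0, 6, by = 1 / 200)
  for (A in c(1.3, 1.95, 4.75)) {
    ang <- angle_trace(t, 180 + A * sin(2 * pi * 1.8 * t), method = "mocap")
    rt <- compute_ranges(find_extrema(ang, "walk"))
    expect_true(all(rt$flexion_deg >= 0 & rt$extension_deg >= 0, na.rm = TRUE))
    expect_lt(abs(mean(rt$flexion_deg, na.rm = TRUE) -
                  mean(rt$extension_deg)), 1e-6)
    expect_equal(mean(rt$flexion_deg, na.rm = TRUE), 2 * A, tolerance = 1e-3)
  }
})

test_that("simulator truth ranges are recovered from the truth trace", {
  for (g in c("walk", "trot", "gallop")) {
    gp <- gait_params(g)
    tr <- simulate_trial(gp, sensor_params_ideal(), duration_s = 10,
                         seed = 17)
    flex <- steady_flexion(tr, tr$truth$angle)
    expect_equal(flex, gp$target_flexion_deg, tolerance = 1e-4)
  }
})
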