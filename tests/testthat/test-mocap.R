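test_that("back vectors are the T18-anchored differences", {
  ms <- static_markers(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  bv <- back_vectors(ms, 1)
  expect_equal(bv$v_withers, c(1, 0, 0))
  expect_equal(bv$v_pelvis, c(-1, 0, 0))

  ms2 <- static_markers(c(1, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(back_vectors(ms2, 1), "coincident")

  set.seed(42)
  for (k in 1:20) {
    w <- rnorm(3); t18 <- rnorm(3); p <- rnorm(3)
    bv <- back_vectors(static_markers(w, t18, p), 1)
    expect_equal(bv$v_withers, t18 - w)
    expect_equal(bv$v_pelvis, t18 - p)
  }
})

test_that("straight and perpendicular marker configurations give 180 and 90 deg", {
  straight <- static_markers(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(compute_mocap_angle(straight, smooth_cutoff_hz = NULL)$values,
               rep(180, 5))
  perp <- static_markers(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(compute_mocap_angle(perp, smooth_cutoff_hz = NULL)$values,
               rep(90, 5))
})

test_that("marker angle matches the law-of-cosines apex angle", {
  set.seed(7)
  for (k in 1:100) {
    w <- runif(3, -1, 1); t18 <- runif(3, -1, 1); p <- runif(3, -1, 1)
    a <- sqrt(sum((t18 - w)^2)); b <- sqrt(sum((t18 - p)^2))
    cc <- sqrt(sum((w - p)^2))
    if (a < 1e-3 || b < 1e-3) next
    oracle <- acos(pmin(1, pmax(-1, (a^2 + b^2 - cc^2) / (2 * a * b)))) * 180 / pi
    ang <- compute_mocap_angle(static_markers(w, t18, p),
                               smooth_cutoff_hz = NULL)$values[1]
    expect_lt(abs(ang - oracle), 1e-9)
  }
})

test_that("marker angle is invariant under rigid transforms", {
  set.seed(13)
  for (k in 1:25) {
    w <- runif(3); t18 <- runif(3) + c(1, 0, 0); p <- runif(3) + c(2, 0, 0)
    base <- compute_mocap_angle(static_markers(w, t18, p),
                                smooth_cutoff_hz = NULL)$values[1]
    R <- random_rotation(); shift <- rnorm(3, sd = 5)
    moved <- compute_mocap_angle(
      static_markers(R %*% w + shift, R %*% t18 + shift, R %*% p + shift),
      smooth_cutoff_hz = NULL)$values[1]
    expect_lt(abs(moved - base), 1e-9)
  }
})

test_that("numerically collinear markers never produce NaN", {
  eps <- 1e-16
  ms <- static_markers(c(0, 0, 0), c(1, eps, 0), c(2, 0, 0))
  ang <- compute_mocap_angle(ms, smooth_cutoff_hz = NULL)$values
  expect_true(all(is.finite(ang)))
})

test_that("unfiltered marker angle tracks the simulator truth up to the static sag", {
  gp <- gait_params("trot")
  tr <- simulate_trial(gp, sensor_params_ideal(), duration_s = 10, seed = 21)
  ang <- compute_mocap_angle(tr$markers, smooth_cutoff_hz = NULL)
  sag <- 180 - gp$rest_angle_deg
  resid <- (ang$values + sag) - tr$truth$angle$values
  interior <- ang$time > 1 & ang$time < 9
  expect_lt(max(abs(resid[interior])), 0.05)
})
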