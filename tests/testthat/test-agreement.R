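test_that("identical methods give zero bias, unit slope, perfect correlation", {
  p <- paired_ranges(c(2, 4, 6, 8), c(2, 4, 6, 8))
  ba <- bland_altman(p)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, 0)
  expect_equal(c(ba$ula, ba$lla), c(0, 0))
  olp <- olp_regression(p)
  expect_equal(olp$slope, 1)
  expect_equal(olp$intercept, 0)
  expect_false(olp$constant_bias)
  expect_false(olp$proportional_bias)
  pc <- pearson_with_strength(p)
  expect_equal(pc$r, 1)
  expect_equal(pc$strength, "large")
})

test_that("Bland-Altman matches the direct mean/SD formulas", {
  set.seed(31)
  ref <- runif(1000, 2, 10)
  dev <- ref + rnorm(1000, 0.5, 1.2)
  ba <- bland_altman(paired_ranges(dev, ref))
  d <- dev - ref
  expect_equal(ba$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba$sd, sd(d), tolerance = 1e-12)
  expect_equal(ba$ula, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$lla, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
})

test_that("about 95% of differences fall inside the limits of agreement", {
  set.seed(77)
  n <- 1e5
  ref <- runif(n, 2, 10)
  dev <- ref + rnorm(n, 0.8, 1.5)
  ba <- bland_altman(paired_ranges(dev, ref))
  inside <- mean(ba$differences >= ba$lla & ba$differences <= ba$ula)
  expect_lt(abs(inside - 0.95), 0.007)
})

test_that("an exact linear map is fit exactly by OLP", {
  ref <- c(1, 2, 3, 4, 7)
  olp <- olp_regression(paired_ranges(2 * ref + 1, ref))
  expect_equal(olp$slope, 2, tolerance = 1e-12)
  expect_equal(olp$intercept, 1, tolerance = 1e-12)
})

test_that("OLP slope equals the SD-ratio moment formula", {
  set.seed(41)
  x <- rnorm(500, 5, 2)
  y <- 1.3 * x + rnorm(500, 0, 1)
  olp <- olp_regression(paired_ranges(y, x))
  expect_equal(olp$slope, sign(cor(x, y)) * sd(y) / sd(x), tolerance = 1e-12)
})

test_that("OLP is scale-equivariant and symmetric under axis swap", {
  set.seed(43)
  x <- runif(100, 1, 9)
  y <- x + rnorm(100, 0, 0.8)
  b <- olp_regression(paired_ranges(y, x))$slope
  expect_equal(olp_regression(paired_ranges(3 * y, x))$slope, 3 * b,
               tolerance = 1e-12)
  expect_equal(olp_regression(paired_ranges(x, y))$slope, 1 / b,
               tolerance = 1e-12)
})

test_that("Pearson r is affine-invariant and strengths follow Cohen classes", {
  set.seed(47)
  x <- runif(60, 1, 9)
  y <- x + rnorm(60, 0, 1)
  r0 <- pearson_with_strength(paired_ranges(y, x))$r
  r1 <- pearson_with_strength(paired_ranges(2 * y + 3, x))$r
  expect_equal(r0, r1, tolerance = 1e-12)

  expect_equal(pearson_with_strength(paired_ranges(-x, x))$strength, "large")
  # zero correlation classifies as none
  xx <- c(1, 2, 3, 4)
  yy <- c(1, -1, -1, 1)
  expect_equal(pearson_with_strength(paired_ranges(yy, xx))$strength, "none")
  expect_error(pearson_with_strength(paired_ranges(c(1, 1, 1), 1:3)),
               "zero variance")
})

test_that("an injected constant offset is recovered within 2 standard errors", {
  p <- simulate_agreement_study(4, c(walk = 28, trot = 29, gallop = 28),
                                bias_deg = 0.7, noise_sd_deg = 1.5, seed = 9)
  ba <- bland_altman(p)
  expect_equal(ba$n, 340)
  expect_lt(abs(ba$bias - 0.7), 2 * 1.5 / sqrt(340))
})

test_that("a proportional distortion raises the proportional-bias flag", {
  p <- simulate_agreement_study(4, c(walk = 28, trot = 29, gallop = 28),
                                bias_deg = 0, noise_sd_deg = 1.5,
                                slope = 1.2, seed = 9)
  expect_true(olp_regression(p)$proportional_bias)
})

test_that("the report assembles all three analyses coherently", {
  set.seed(53)
  ref <- runif(100, 2, 10)
  dev <- ref + rnorm(100, 0.8, 1.5)
  rep <- agreement_report(paired_ranges(dev, ref))
  expect_s3_class(rep, "agreement_report")
  expect_equal(rep$bland_altman$bias,
               mean(dev - ref), tolerance = 1e-12)
  expect_equal(unname(coef(rep)["slope"]), rep$olp$slope)
  s <- summary(rep)
  expect_equal(s$pearson_r, rep$pearson$r)
  expect_output(print(rep), "limits of agreement")
})
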