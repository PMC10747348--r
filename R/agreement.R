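#' Paired range measurements from two methods
#'
#' Pairs the per-cycle ranges of the developed (IMU) method with the
#' reference (MOCAP) method.
#'
#' @param developed numeric vector, developed-method ranges in degrees.
#' @param reference numeric vector, reference-method ranges in degrees.
#' @param labels optional data frame (or vector) of per-pair labels
#'   (horse, gait, ...).
#' @return An object of class \code{paired_ranges}.
#' @export
paired_ranges <- function(developed, reference, labels = NULL) {
  developed <- as.numeric(developed)
  reference <- as.numeric(reference)
  if (length(developed) != length(reference)) {
    stop("paired_ranges: lengths differ")
  }
  if (length(developed) < 3L) stop("paired_ranges: need at least 3 pairs")
  if (any(!is.finite(developed)) || any(!is.finite(reference))) {
    stop("paired_ranges: non-finite values")
  }
  structure(list(developed = developed, reference = reference,
                 labels = labels),
            class = "paired_ranges")
}

#' @export
print.paired_ranges <- function(x, ...) {
  cat(sprintf("<paired_ranges> n = %d, developed mean %.2f deg, reference mean %.2f deg\n",
              length(x$developed), mean(x$developed), mean(x$reference)))
  invisible(x)
}

#' Bland-Altman agreement statistics
#'
#' For paired measurements the per-pair difference is developed minus
#' reference; the bias is its mean, the precision its sample standard
#' deviation (n - 1 denominator), and the 95\% limits of agreement are
#' \deqn{\mathrm{ULA} = \mathrm{bias} + 1.96\,\mathrm{SD}, \qquad
#'       \mathrm{LLA} = \mathrm{bias} - 1.96\,\mathrm{SD}.}
#'
#' @param pairs a \code{\link{paired_ranges}}.
#' @return A list with \code{bias}, \code{sd}, \code{ula}, \code{lla},
#'   \code{n}, and the per-pair \code{means}/\code{differences} for
#'   plotting.
#' @examples
#' p <- paired_ranges(c(4.1, 3.8, 4.4, 5.0), c(3.5, 3.2, 3.9, 4.1))
#' bland_altman(p)$bias
#' @export
bland_altman <- function(pairs) {
  stopifnot(inherits(pairs, "paired_ranges"))
  d <- pairs$developed - pairs$reference
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s,
       ula = bias + 1.96 * s, lla = bias - 1.96 * s,
       n = length(d),
       means = (pairs$developed + pairs$reference) / 2,
       differences = d)
}

#' Ordinary least products (geometric mean) regression
#'
#' Method-comparison regression treating both variables as error-prone.
#' The slope is \eqn{b = \mathrm{sign}(r)\, s_y / s_x} and the intercept
#' \eqn{a = \bar y - b \bar x}, with developed on y and reference on x.
#' 95\% confidence intervals use the analytic geometric-mean-regression
#' formulas: with \eqn{B = t^2_{0.975,\,n-2}(1 - r^2)/(n - 2)}, the slope
#' interval is \eqn{b(\sqrt{B + 1} \pm \sqrt{B})} and the intercept
#' interval follows by propagating the slope limits through
#' \eqn{a = \bar y - b\bar x}. A constant bias is declared when the
#' intercept interval excludes 0; a proportional bias when the slope
#' interval excludes 1.
#'
#' @param pairs a \code{\link{paired_ranges}}.
#' @return An object of class \code{olp_fit} with components \code{slope},
#'   \code{intercept}, \code{slope_ci}, \code{intercept_ci}, \code{r},
#'   \code{n}, \code{constant_bias}, \code{proportional_bias}. Methods:
#'   \code{coef}, \code{confint}, \code{print}.
#' @examples
#' p <- paired_ranges(c(1, 2, 3, 4), c(1, 2, 3, 4))
#' olp_regression(p)$slope  # 1
#' @export
olp_regression <- function(pairs) {
  stopifnot(inherits(pairs, "paired_ranges"))
  x <- pairs$reference
  y <- pairs$developed
  n <- length(x)
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx < 1e-12 || sy < 1e-12) {
    stop("olp_regression: zero variance in one of the methods")
  }
  r <- stats::cor(x, y)
  b <- sign(r) * sy / sx
  if (r == 0) b <- sy / sx   # sign convention for the degenerate r = 0 case
  a <- mean(y) - b * mean(x)
  tq <- stats::qt(0.975, n - 2)
  B <- tq^2 * (1 - r^2) / (n - 2)
  lims <- b * (sqrt(B + 1) + c(-1, 1) * sqrt(B))
  slope_ci <- sort(lims)
  int_lims <- mean(y) - slope_ci * mean(x)
  intercept_ci <- sort(int_lims)
  structure(list(slope = b, intercept = a,
                 slope_ci = slope_ci, intercept_ci = intercept_ci,
                 r = r, n = n,
                 constant_bias = !(intercept_ci[1] <= 0 && 0 <= intercept_ci[2]),
                 proportional_bias = !(slope_ci[1] <= 1 && 1 <= slope_ci[2])),
            class = "olp_fit")
}

#' @export
coef.olp_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
confint.olp_fit <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95) warning("olp_fit intervals are computed at 95% only")
  m <- rbind(intercept = object$intercept_ci, slope = object$slope_ci)
  colnames(m) <- c("2.5 %", "97.5 %")
  m
}

#' @export
print.olp_fit <- function(x, digits = 3, ...) {
  cat("Ordinary least products regression (developed ~ reference)\n")
  cat(sprintf("  slope     %s  [%s, %s] %s\n",
              format(x$slope, digits = digits),
              format(x$slope_ci[1], digits = digits),
              format(x$slope_ci[2], digits = digits),
              if (x$proportional_bias) "-> proportional bias" else "(no proportional bias)"))
  cat(sprintf("  intercept %s  [%s, %s] %s\n",
              format(x$intercept, digits = digits),
              format(x$intercept_ci[1], digits = digits),
              format(x$intercept_ci[2], digits = digits),
              if (x$constant_bias) "-> constant bias" else "(no constant bias)"))
  cat(sprintf("  n = %d, r = %s\n", x$n, format(x$r, digits = digits)))
  invisible(x)
}

#' Pearson correlation with Cohen strength class
#'
#' Sample Pearson correlation between the two methods, classified by
#' absolute value against Cohen's thresholds: |r| in [0, 0.1] none,
#' (0.1, 0.3] small, (0.3, 0.5] medium, above 0.5 large (boundaries assigned
#' to the lower class).
#'
#' @param pairs a \code{\link{paired_ranges}}.
#' @return A list with \code{r} and \code{strength}.
#' @export
pearson_with_strength <- function(pairs) {
  stopifnot(inherits(pairs, "paired_ranges"))
  if (stats::sd(pairs$developed) < 1e-12 || stats::sd(pairs$reference) < 1e-12) {
    stop("pearson_with_strength: zero variance")
  }
  r <- stats::cor(pairs$developed, pairs$reference)
  a <- abs(r)
  strength <- if (a <= 0.1) "none" else if (a <= 0.3) "small"
              else if (a <= 0.5) "medium" else "large"
  list(r = r, strength = strength)
}

#' Full agreement report for a method comparison
#'
#' Assembles the Bland-Altman statistics, the ordinary least products
#' regression with constant/proportional bias flags, and the Pearson
#' correlation with its strength class into one report object with print,
#' summary, coef and plot methods.
#'
#' @param pairs a \code{\link{paired_ranges}}.
#' @return An object of class \code{agreement_report}.
#' @examples
#' set.seed(1)
#' ref <- runif(50, 2, 10)
#' dev <- ref + 0.8 + rnorm(50, sd = 1.5)
#' rep <- agreement_report(paired_ranges(dev, ref))
#' rep
#' @export
agreement_report <- function(pairs) {
  stopifnot(inherits(pairs, "paired_ranges"))
  ba <- bland_altman(pairs)
  olp <- olp_regression(pairs)
  pc <- pearson_with_strength(pairs)
  structure(list(bland_altman = ba, olp = olp, pearson = pc,
                 pairs = pairs),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  ba <- x$bland_altman
  cat("Method agreement report (developed vs reference)\n")
  cat(sprintf("  n pairs          %d\n", ba$n))
  cat(sprintf("  bias (SD)        %s (%s) deg\n",
              round_half_away(ba$bias, 1), round_half_away(ba$sd, 1)))
  cat(sprintf("  limits of agreement  [%s, %s] deg\n",
              round_half_away(ba$lla, 1), round_half_away(ba$ula, 1)))
  cat(sprintf("  Pearson r        %.2f (%s)\n", x$pearson$r, x$pearson$strength))
  print(x$olp)
  invisible(x)
}

#' @export
summary.agreement_report <- function(object, ...) {
  ba <- object$bland_altman
  data.frame(n = ba$n, bias_deg = ba$bias, sd_deg = ba$sd,
             ula_deg = ba$ula, lla_deg = ba$lla,
             olp_slope = object$olp$slope,
             olp_intercept = object$olp$intercept,
             constant_bias = object$olp$constant_bias,
             proportional_bias = object$olp$proportional_bias,
             pearson_r = object$pearson$r,
             strength = object$pearson$strength)
}

#' @export
coef.agreement_report <- function(object, ...) {
  c(bias = object$bland_altman$bias, sd = object$bland_altman$sd,
    ula = object$bland_altman$ula, lla = object$bland_altman$lla,
    slope = object$olp$slope, intercept = object$olp$intercept,
    r = object$pearson$r)
}

#' Plot an agreement report
#'
#' Left: Bland-Altman plot (pair means vs differences with bias and limits
#' of agreement). Right: developed vs reference scatter with the identity
#' and OLP regression lines.
#'
#' @param x an \code{\link{agreement_report}}.
#' @param ... passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.agreement_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  ba <- x$bland_altman
  graphics::plot(ba$means, ba$differences,
                 xlab = "mean of methods (deg)",
                 ylab = "developed - reference (deg)",
                 main = "Bland-Altman", ...)
  graphics::abline(h = c(ba$bias, ba$ula, ba$lla),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  graphics::plot(x$pairs$reference, x$pairs$developed,
                 xlab = "reference (deg)", ylab = "developed (deg)",
                 main = sprintf("OLP fit (r = %.2f)", x$pearson$r), ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  graphics::abline(x$olp$intercept, x$olp$slope)
  invisible(x)
}

# one-decimal display rounding, half away from zero (report convention)
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
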