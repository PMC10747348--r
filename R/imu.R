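#' Estimate sensor orientation from a motionless window
#'
#' During the standing-square calibration window the only acceleration is
#' gravity, so the mean reading reveals the sensor tilt. With window means
#' \eqn{(\bar\gamma_x, \bar\gamma_y, \bar\gamma_z)} the correction angles
#' are
#' \deqn{\beta = \arctan(-\bar\gamma_x / \bar\gamma_z), \qquad
#'       \alpha = \arctan\!\big(-\bar\gamma_y \,/\,
#'         (\sin\beta\,\bar\gamma_x - \cos\beta\,\bar\gamma_z)\big),}
#' and the rotation aligning the sensor Z axis with gravity is
#' \deqn{R = \begin{pmatrix}
#'   \cos\beta & 0 & \sin\beta \\
#'   \sin\alpha\sin\beta & \cos\alpha & -\sin\alpha\cos\beta \\
#'   -\cos\alpha\sin\beta & \sin\alpha & \cos\alpha\cos\beta
#' \end{pmatrix}.}
#' Applying \eqn{R} to the mean motionless reading yields \eqn{(0, 0, -g)}.
#' Yaw about the sensor's own Z axis is assumed zero at standing square.
#'
#' @param static_rec an \code{\link{imu_recording}} restricted to the
#'   motionless window (e.g. via \code{\link{trim}} of its \code{accel}).
#' @param check if \code{TRUE} (default), require per-axis SD < 0.02 g and
#'   mean norm within 5\% of 1 g, i.e. an actually motionless window.
#' @return An object of class \code{orientation_correction}: list with
#'   \code{alpha_rad}, \code{beta_rad}, \code{rotation} (3 x 3),
#'   \code{static_norm_g}.
#' @examples
#' t <- seq(0, 2, by = 1/225)
#' still <- imu_recording(back_ts(t, cbind(0.5, 0, -sqrt(3)/2)[rep(1, length(t)), ]))
#' estimate_orientation(still)$beta_rad * 180 / pi  # 30 degrees
#' @export
estimate_orientation <- function(static_rec, check = TRUE) {
  stopifnot(inherits(static_rec, "imu_recording"))
  rec <- imu_in_units(static_rec, "g")
  acc <- rec$accel$values
  mu <- colMeans(acc)
  if (check) {
    sds <- apply(acc, 2L, stats::sd)
    if (any(sds > 0.02)) {
      stop("estimate_orientation: window not motionless (per-axis SD up to ",
           signif(max(sds), 3), " g > 0.02 g)")
    }
    nrm <- sqrt(sum(mu^2))
    if (abs(nrm - 1) > 0.05) {
      stop("estimate_orientation: mean acceleration norm ", signif(nrm, 4),
           " g deviates from 1 g by more than 5%")
    }
  }
  if (abs(mu[3]) < 1e-9) stop("estimate_orientation: degenerate orientation (mean z ~ 0)")
  beta <- atan(-mu[1] / mu[3])
  denom <- sin(beta) * mu[1] - cos(beta) * mu[3]
  alpha <- atan(-mu[2] / denom)
  structure(list(alpha_rad = alpha, beta_rad = beta,
                 rotation = tilt_rotation(alpha, beta),
                 static_norm_g = sqrt(sum(mu^2))),
            class = "orientation_correction")
}

# rotation taking sensor-frame readings to the terrestrial frame:
# beta about the floating Y axis, alpha about the terrestrial X axis
tilt_rotation <- function(alpha, beta) {
  matrix(c(
    cos(beta), 0, sin(beta),
    sin(alpha) * sin(beta), cos(alpha), -sin(alpha) * cos(beta),
    -cos(alpha) * sin(beta), sin(alpha), cos(alpha) * cos(beta)
  ), nrow = 3, byrow = TRUE)
}

#' @export
print.orientation_correction <- function(x, ...) {
  cat(sprintf("<orientation_correction> alpha %.3f deg, beta %.3f deg, static norm %.4f g\n",
              x$alpha_rad * 180 / pi, x$beta_rad * 180 / pi, x$static_norm_g))
  invisible(x)
}

#' Rotate an IMU recording into the terrestrial frame
#'
#' Multiplies every acceleration sample by the correction rotation so all
#' sensors share one gravity-aligned reference frame (Z up; a motionless
#' corrected sensor reads (0, 0, -1) g).
#'
#' @param rec an \code{\link{imu_recording}}.
#' @param corr an \code{\link{orientation_correction}} estimated from the
#'   same sensor's standing-square window.
#' @return The corrected \code{imu_recording} (same units and time base).
#' @export
correct_to_terrestrial <- function(rec, corr) {
  stopifnot(inherits(rec, "imu_recording"),
            inherits(corr, "orientation_correction"))
  rec$accel$values <- rec$accel$values %*% t(corr$rotation)
  rec
}

#' Vertical displacement by drift-controlled double integration
#'
#' Converts orientation-corrected vertical acceleration into vertical
#' displacement. The static gravity/bias level (mean of the Z channel over
#' \code{static_window}) is subtracted, the residual acceleration is
#' integrated to velocity and high-pass filtered (order-4 zero-phase
#' Butterworth at \code{drift_cutoff_hz}), then integrated again and
#' high-pass filtered once more. Filtering after each integration stage
#' keeps integrator drift bounded; the result is a near-zero-mean
#' displacement in metres.
#'
#' @param rec an orientation-corrected \code{\link{imu_recording}}.
#' @param static_window numeric \code{c(t0, t1)} or \code{\link{sync_window}}
#'   delimiting the motionless calibration period used for gravity removal;
#'   \code{NULL} uses the whole-record mean (suitable for zero-mean test
#'   signals).
#' @param drift_cutoff_hz high-pass cutoff in Hz (default 1).
#' @param filter_order Butterworth order (default 4).
#' @return A \code{\link{back_ts}} of vertical displacement in metres.
#' @export
vertical_displacement <- function(rec, static_window = NULL,
                                  drift_cutoff_hz = 1, filter_order = 4L) {
  stopifnot(inherits(rec, "imu_recording"))
  rec <- imu_in_units(rec, "ms2")
  t <- rec$accel$time
  fs <- rec$accel$rate_hz
  if (fs < 8 * drift_cutoff_hz) {
    stop("vertical_displacement: sampling rate ", fs,
         " Hz too low for a ", drift_cutoff_hz, " Hz drift filter")
  }
  az <- rec$accel$values[, 3]
  if (is.null(static_window)) {
    az <- az - mean(az)
  } else {
    w <- as_sync_window(static_window)
    in_w <- t >= w$t_start & t <= w$t_end
    if (sum(in_w) < 2L) stop("vertical_displacement: empty static window")
    az <- az - mean(az[in_w])
  }
  hp <- function(x) {
    butterworth_filter(back_ts(t, x, fs), drift_cutoff_hz,
                       filter_order, "highpass")$values
  }
  vel <- hp(pracma::cumtrapz(t, az)[, 1])
  disp <- hp(pracma::cumtrapz(t, vel)[, 1])
  back_ts(t, disp, fs)
}

#' Displacement triplet
#'
#' Vertical displacements of the three trunk sensors on a shared time base.
#'
#' @param withers,t18,pelvis \code{\link{back_ts}} vertical displacements in
#'   metres with identical timestamps.
#' @return An object of class \code{displacement_triplet}.
#' @export
displacement_triplet <- function(withers, t18, pelvis) {
  for (d in list(withers, t18, pelvis)) stopifnot(inherits(d, "back_ts"))
  if (!isTRUE(all.equal(withers$time, t18$time)) ||
      !isTRUE(all.equal(withers$time, pelvis$time))) {
    stop("displacement_triplet: displacements must share timestamps")
  }
  structure(list(withers = withers, t18 = t18, pelvis = pelvis),
            class = "displacement_triplet")
}

#' IMU back angle from vertical displacements
#'
#' The trigonometric reconstruction of the back angle. At each instant the
#' midpoint M of the withers and pelvis vertical displacements is formed,
#' and the vertical offset \eqn{\Delta z = z_M - z_{T18}} drives two
#' sub-angles at the T18 vertex:
#' \deqn{\theta_{w} = \arccos(\Delta z / X_2), \qquad
#'       \theta_{p} = \arccos(\Delta z / X),}
#' where \eqn{X_2} is the withers-to-T18 distance and \eqn{X} the
#' T18-to-pelvis distance. The back angle is their sum, in degrees, then
#' smoothed with an order-4 zero-phase Butterworth low-pass at
#' \code{smooth_cutoff_hz}. Because the displacements are high-pass filtered
#' (zero-mean), the angle oscillates about 180 degrees and only its
#' per-cycle ranges are interpretable, not its absolute value.
#'
#' Arguments of arccos are clipped to [-1, 1]; the number of clipped samples
#' is recorded in the \code{clip_count} attribute.
#'
#' @param disp a \code{\link{displacement_triplet}} in metres.
#' @param geom a \code{\link{geometry_config}}.
#' @param smooth_cutoff_hz final low-pass cutoff in Hz (default 5);
#'   \code{NULL} skips smoothing.
#' @param filter_order Butterworth order (default 4).
#' @return An \code{\link{angle_trace}} with \code{method = "imu"} and
#'   attribute \code{clip_count}.
#' @examples
#' t <- seq(0, 2, by = 1/200)
#' z <- back_ts(t, rep(0, length(t)))
#' geom <- geometry_config(0.5, 0.5)
#' compute_imu_angle(displacement_triplet(z, z, z), geom)  # flat back: 180 deg
#' @export
compute_imu_angle <- function(disp, geom, smooth_cutoff_hz = 5,
                              filter_order = 4L) {
  stopifnot(inherits(disp, "displacement_triplet"),
            inherits(geom, "geometry_config"))
  dz <- (disp$withers$values + disp$pelvis$values) / 2 - disp$t18$values
  r2 <- dz / geom$x2_m
  r1 <- dz / geom$x_m
  clip_count <- sum(abs(r2) > 1) + sum(abs(r1) > 1)
  ang <- (acos(pmin(1, pmax(-1, r2))) + acos(pmin(1, pmax(-1, r1)))) * 180 / pi
  ts <- back_ts(disp$withers$time, ang, disp$withers$rate_hz)
  if (!is.null(smooth_cutoff_hz)) {
    ts <- butterworth_filter(ts, smooth_cutoff_hz, filter_order, "lowpass")
  }
  out <- angle_trace(ts$time, pmin(360, pmax(0, ts$values)), method = "imu",
                     rate_hz = ts$rate_hz)
  attr(out, "clip_count") <- clip_count
  out
}
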