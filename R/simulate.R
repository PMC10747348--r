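#' Gait parameters for the trunk-motion simulator
#'
#' Defines the simulated gait: stride frequency, flexion/extension cycle
#' structure (two cycles per stride at walk and trot, one at gallop), the
#' target per-cycle range of the back angle, trunk geometry and forward
#' speed. Default target ranges are typical motion-capture values for sound
#' horses (walk 2.6 deg, trot 3.9 deg, gallop 9.5 deg).
#'
#' With the periodic symmetric trunk oscillation used by the generator the
#' per-cycle flexion and extension ranges are mathematically identical
#' (both are differences between adjacent extrema of one periodic trace),
#' so \code{target_flexion_deg} and \code{target_extension_deg} must be
#' equal; both default to the gait's flexion target.
#'
#' @param gait \code{"walk"}, \code{"trot"} or \code{"gallop"}.
#' @param stride_hz stride frequency in Hz; defaults to walk 0.9, trot 1.4,
#'   gallop 1.7.
#' @param target_flexion_deg,target_extension_deg per-cycle range targets in
#'   degrees (must be equal).
#' @param x_m,x2_m trunk geometry: T18-to-pelvis and withers-to-T18
#'   distances in metres.
#' @param bounce_amp_m amplitude of the common vertical trunk oscillation in
#'   metres (default 0.04).
#' @param base_height_m standing height of the withers/pelvis sensor line in
#'   metres.
#' @param forward_speed_ms forward speed in m/s; defaults walk 1.5,
#'   trot 3.5, gallop 6.5.
#' @param rest_angle_deg standing marker-triangle back angle in degrees;
#'   defaults to \code{178 - target/2} so the marker angle keeps a 2 degree
#'   margin below the 180 degree fold at the flexion peaks.
#' @return An object of class \code{gait_params}.
#' @export
gait_params <- function(gait = c("walk", "trot", "gallop"),
                        stride_hz = NULL,
                        target_flexion_deg = NULL,
                        target_extension_deg = NULL,
                        x_m = 0.5, x2_m = 0.5,
                        bounce_amp_m = 0.04,
                        base_height_m = 1.6,
                        forward_speed_ms = NULL,
                        rest_angle_deg = NULL) {
  gait <- match.arg(gait)
  gs <- gait_cycle_structure(gait)
  if (!is.null(stride_hz)) {
    gs$stride_hz <- stride_hz
    gs$cycle_hz <- stride_hz * gs$cycles_per_stride
  }
  default_target <- c(walk = 2.6, trot = 3.9, gallop = 9.5)[[gait]]
  tf <- target_flexion_deg %||% default_target
  te <- target_extension_deg %||% tf
  if (abs(tf - te) > 1e-12) {
    stop("gait_params: the periodic trunk model implies equal flexion and ",
         "extension targets; got ", tf, " and ", te)
  }
  if (tf <= 0 || tf >= 180) stop("gait_params: target range must be in (0, 180) deg")
  geom <- geometry_config(x_m, x2_m)
  speed <- forward_speed_ms %||%
    c(walk = 1.5, trot = 3.5, gallop = 6.5)[[gait]]
  rest <- rest_angle_deg %||% (178 - tf / 2)
  if (rest + tf / 2 >= 180) {
    stop("gait_params: rest angle leaves no headroom below 180 deg at flexion peaks")
  }
  structure(list(gait = gait, stride_hz = gs$stride_hz,
                 cycles_per_stride = gs$cycles_per_stride,
                 cycle_hz = gs$cycle_hz,
                 target_flexion_deg = tf, target_extension_deg = te,
                 geometry = geom, bounce_amp_m = bounce_amp_m,
                 base_height_m = base_height_m,
                 forward_speed_ms = speed,
                 rest_angle_deg = rest),
            class = "gait_params")
}

#' Sensor parameters for the trunk-motion simulator
#'
#' Acquisition-side settings: sampling rates, per-sensor mounting tilts,
#' noise levels, the motionless standing-square pre-roll, sync-strike
#' timing, and an optional systematic offset of the IMU-observed motion
#' emulating the developed method reading consistently slightly higher than
#' the reference.
#'
#' @param imu_rate_hz IMU sampling rate (default 225).
#' @param marker_rate_hz motion-capture sampling rate (default 200).
#' @param tilt per-sensor mounting tilt: a data frame with columns
#'   \code{sensor}, \code{alpha_deg}, \code{beta_deg} covering withers, t18,
#'   pelvis, pastern; \code{NULL} draws each angle uniformly in
#'   \code{+/-15} degrees when the trial is simulated.
#' @param accel_noise_sd_g accelerometer noise SD per axis in g
#'   (default 0.01).
#' @param marker_noise_sd_mm marker position noise SD per axis in mm
#'   (default 0.5).
#' @param static_preroll_s motionless standing-square duration before the
#'   horse moves off, seconds (>= 2, default 3).
#' @param ramp_s smooth transition from standing to steady gait, seconds.
#' @param sync_spike_times_s times of the two pastern sync strikes;
#'   \code{NULL} places them 0.2 s before motion onset and 0.2 s before the
#'   end of the trial.
#' @param sync_spike_amp_g amplitude of the sync impulses in g (default 8).
#' @param imu_bias_offset_deg systematic addition to the IMU-observed
#'   per-cycle range in degrees (default 0.7); set to 0 for physically
#'   identical marker and IMU motion.
#' @return An object of class \code{sensor_params}.
#' @export
sensor_params <- function(imu_rate_hz = 225, marker_rate_hz = 200,
                          tilt = NULL,
                          accel_noise_sd_g = 0.01,
                          marker_noise_sd_mm = 0.5,
                          static_preroll_s = 3, ramp_s = 1,
                          sync_spike_times_s = NULL,
                          sync_spike_amp_g = 8,
                          imu_bias_offset_deg = 0.7) {
  if (static_preroll_s < 2) stop("sensor_params: static_preroll_s must be >= 2 s")
  if (!is.null(tilt)) {
    need <- c("withers", "t18", "pelvis", "pastern")
    if (!all(need %in% tilt$sensor)) {
      stop("sensor_params: tilt must cover sensors ", paste(need, collapse = ", "))
    }
  }
  structure(list(imu_rate_hz = imu_rate_hz, marker_rate_hz = marker_rate_hz,
                 tilt = tilt,
                 accel_noise_sd_g = accel_noise_sd_g,
                 marker_noise_sd_mm = marker_noise_sd_mm,
                 static_preroll_s = static_preroll_s, ramp_s = ramp_s,
                 sync_spike_times_s = sync_spike_times_s,
                 sync_spike_amp_g = sync_spike_amp_g,
                 imu_bias_offset_deg = imu_bias_offset_deg),
            class = "sensor_params")
}

#' Zero-tilt, zero-noise sensor parameters
#'
#' Convenience constructor for noise-free validation runs: no mounting
#' tilt, no sensor noise, no systematic IMU offset.
#'
#' @param ... overrides passed on to \code{\link{sensor_params}}.
#' @return A \code{\link{sensor_params}} object.
#' @export
sensor_params_ideal <- function(...) {
  args <- list(tilt = flat_tilt(), accel_noise_sd_g = 0,
               marker_noise_sd_mm = 0, imu_bias_offset_deg = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(sensor_params, args)
}

flat_tilt <- function() {
  data.frame(sensor = c("withers", "t18", "pelvis", "pastern"),
             alpha_deg = 0, beta_deg = 0, stringsAsFactors = FALSE)
}

# amplitude of the vertical differential offset giving a per-cycle range of
# `target_deg` through the trigonometric angle at geometry (x_m, x2_m):
# solves acos(D/x2) + acos(D/x) = 180 - target/2 (degrees)
solve_differential_amp <- function(target_deg, geom) {
  f <- function(D) {
    (acos(D / geom$x2_m) + acos(D / geom$x_m)) * 180 / pi -
      (180 - target_deg / 2)
  }
  upper <- 0.999999 * min(geom$x_m, geom$x2_m)
  if (f(upper) > 0) {
    stop("target range ", target_deg,
         " deg geometrically unreachable at X = ", geom$x_m,
         ", X2 = ", geom$x2_m, " m")
  }
  stats::uniroot(f, c(0, upper), tol = 1e-14)$root
}

# trigonometric back angle (degrees) from a vertical differential offset
trig_angle_deg <- function(dz, geom) {
  (acos(pmin(1, pmax(-1, dz / geom$x2_m))) +
     acos(pmin(1, pmax(-1, dz / geom$x_m)))) * 180 / pi
}

# marker-triangle apex offset u solving
#   atan(u/x2) + atan(u/x) = phi_rad   (vectorised Newton)
triangle_offset_from_angle <- function(phi_rad, geom) {
  x <- geom$x_m; x2 <- geom$x2_m
  u <- phi_rad / (1 / x + 1 / x2)
  for (k in 1:8) {
    g <- atan(u / x2) + atan(u / x) - phi_rad
    gp <- x2 / (x2^2 + u^2) + x / (x^2 + u^2)
    u <- u - g / gp
  }
  u
}

# raised-cosine motion envelope and derivatives
envelope <- function(t, t0, tau) {
  s <- pmin(1, pmax(0, (t - t0) / tau))
  (1 - cos(pi * s)) / 2
}
envelope_d1 <- function(t, t0, tau) {
  s <- (t - t0) / tau
  ifelse(s > 0 & s < 1, pi / (2 * tau) * sin(pi * s), 0)
}
envelope_d2 <- function(t, t0, tau) {
  s <- (t - t0) / tau
  ifelse(s > 0 & s < 1, pi^2 / (2 * tau^2) * cos(pi * s), 0)
}

# oscillation amp * E(t) * sin(w (t - t0)) and its second time derivative
osc_pos <- function(t, t0, tau, w, amp) {
  amp * envelope(t, t0, tau) * sin(w * (t - t0))
}
osc_acc <- function(t, t0, tau, w, amp) {
  E <- envelope(t, t0, tau)
  E1 <- envelope_d1(t, t0, tau)
  E2 <- envelope_d2(t, t0, tau)
  ph <- w * (t - t0)
  amp * (E2 * sin(ph) + 2 * E1 * w * cos(ph) - E * w^2 * sin(ph))
}

#' Analytic ground-truth back angle
#'
#' Closed-form evaluation of the noiseless simulated back angle: the
#' trigonometric reconstruction applied to the generated vertical
#' differential offset. During the motionless pre-roll the offset is zero
#' and the angle is exactly 180 degrees; in steady gait it oscillates so
#' that every per-cycle flexion and extension range equals the configured
#' target.
#'
#' @param gp a \code{\link{gait_params}}.
#' @param t time(s) in seconds (vectorised).
#' @param preroll_s,ramp_s timeline of the standing pre-roll and the
#'   stand-to-gait transition (defaults match \code{\link{sensor_params}}).
#' @return Angle(s) in degrees.
#' @export
analytic_angle <- function(gp, t, preroll_s = 3, ramp_s = 1) {
  stopifnot(inherits(gp, "gait_params"))
  D <- solve_differential_amp(gp$target_flexion_deg, gp$geometry)
  w <- 2 * pi * gp$cycle_hz
  d <- osc_pos(t, preroll_s, ramp_s, w, D)
  trig_angle_deg(d, gp$geometry)
}

#' Simulate one instrumented trial
#'
#' Generates a complete synthetic trial with known ground truth: marker
#' trajectories for the three trunk sites, tri-axial accelerations for the
#' three trunk IMUs plus the pastern sync channel, and the analytic truth
#' (angle trace and per-cycle range table).
#'
#' The trunk model is a common vertical bounce of the withers/pelvis line at
#' the gait's flexion/extension cycle frequency plus a differential offset
#' of the T18 site whose amplitude is solved so the trigonometric back angle
#' has exactly the target per-cycle range. Marker trajectories additionally
#' carry a static sag of the T18 site below the withers-pelvis chord so the
#' marker-triangle angle sits at \code{rest_angle_deg} (away from the
#' 180 degree fold) while reproducing the truth angle up to that constant
#' offset. IMU accelerations are the analytic second time derivatives of
#' the same site trajectories, expressed in each sensor's tilted frame with
#' a motionless reading of (0, 0, -1) g, plus optional white noise. The
#' trial starts with a motionless standing-square pre-roll and contains two
#' pastern sync impulses.
#'
#' @param gp a \code{\link{gait_params}}.
#' @param sp a \code{\link{sensor_params}}.
#' @param duration_s trial length in seconds (must allow >= 3 strides after
#'   the pre-roll and ramp).
#' @param seed integer seed; identical seeds give identical trials.
#' @return An object of class \code{synthetic_trial}: list with
#'   \code{markers} (\code{\link{marker_set}}), \code{imus} (named list of
#'   \code{\link{imu_recording}}: withers, t18, pelvis, pastern),
#'   \code{truth} (list: \code{angle} trace, \code{ranges} table,
#'   \code{differential_amp_m}), \code{gait_params}, \code{sensor_params},
#'   \code{tilt}, \code{duration_s}, \code{seed}.
#' @export
simulate_trial <- function(gp, sp = sensor_params(), duration_s = 12,
                           seed = 1L) {
  stopifnot(inherits(gp, "gait_params"), inherits(sp, "sensor_params"))
  t0 <- sp$static_preroll_s
  tau <- sp$ramp_s
  if (duration_s < t0 + tau + 3 / gp$stride_hz) {
    stop("simulate_trial: duration too short for 3 strides after the pre-roll")
  }
  set.seed(as.integer(seed))
  geom <- gp$geometry
  w <- 2 * pi * gp$cycle_hz
  D <- solve_differential_amp(gp$target_flexion_deg, geom)
  D_imu <- if (sp$imu_bias_offset_deg != 0) {
    solve_differential_amp(gp$target_flexion_deg + sp$imu_bias_offset_deg, geom)
  } else D

  tilt <- sp$tilt %||% data.frame(
    sensor = c("withers", "t18", "pelvis", "pastern"),
    alpha_deg = stats::runif(4, -15, 15),
    beta_deg = stats::runif(4, -15, 15),
    stringsAsFactors = FALSE)

  # site trajectories (terrestrial frame, z up); u = apex offset of T18
  # below the withers-pelvis chord, encoding truth angle minus static sag
  sag_rad <- (180 - gp$rest_angle_deg) * pi / 180
  u_of_t <- function(t, D_amp) {
    d <- osc_pos(t, t0, tau, w, D_amp)
    theta_m <- trig_angle_deg(d, geom) - (180 - gp$rest_angle_deg)
    triangle_offset_from_angle((180 - theta_m) * pi / 180, geom)
  }
  z_common <- function(t) gp$base_height_m + osc_pos(t, t0, tau, w, gp$bounce_amp_m)
  z_t18 <- function(t, D_amp) z_common(t) - u_of_t(t, D_amp)
  x_fwd <- function(t) {
    # forward position: speed ramps with the same envelope
    s <- pmin(1, pmax(0, (t - t0) / tau))
    ramp_int <- ifelse(t <= t0, 0,
                ifelse(t >= t0 + tau,
                       tau / 2 + (t - t0 - tau),
                       (t - t0) / 2 - tau / (2 * pi) * sin(pi * s)))
    gp$forward_speed_ms * ramp_int
  }

  # ---- markers at marker_rate ----
  tm <- seq(0, duration_s, by = 1 / sp$marker_rate_hz)
  noise_m <- sp$marker_noise_sd_mm * 1e-3
  mk <- function(xoff, z) {
    xyz <- cbind(x_fwd(tm) + xoff, 0, z)
    if (noise_m > 0) xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_m),
                                         ncol = 3)
    back_ts(tm, xyz, sp$marker_rate_hz)
  }
  markers <- marker_set(
    withers = mk(0, z_common(tm)),
    t18 = mk(geom$x2_m, z_t18(tm, D)),
    pelvis = mk(geom$x2_m + geom$x_m, z_common(tm)),
    vertical_axis = "z")

  # ---- IMUs at imu_rate ----
  ti <- seq(0, duration_s, by = 1 / sp$imu_rate_hz)
  az_common <- osc_acc(ti, t0, tau, w, gp$bounce_amp_m)
  ax_all <- gp$forward_speed_ms * envelope_d1(ti, t0, tau)
  u_acc <- function(D_amp) num_accel(function(t) u_of_t(t, D_amp), ti)
  site_acc_z <- list(withers = az_common,
                     t18 = az_common - u_acc(D_imu),
                     pelvis = az_common,
                     pastern = rep(0, length(ti)))
  imus <- list()
  for (s in c("withers", "t18", "pelvis", "pastern")) {
    ax <- if (s == "pastern") rep(0, length(ti)) else ax_all
    # vendor reading convention: motionless terrestrial reading is (0,0,-1) g
    reading <- cbind(ax / GRAVITY_MS2, 0, site_acc_z[[s]] / GRAVITY_MS2 - 1)
    if (s == "pastern") reading[, 3] <- reading[, 3] +
        sync_impulse(ti, sync_times(sp, duration_s), sp$sync_spike_amp_g)
    row <- tilt[tilt$sensor == s, ]
    R <- tilt_rotation(row$alpha_deg * pi / 180, row$beta_deg * pi / 180)
    # sensor-frame rows: (R^T terr)^T = terr^T R
    sensor_frame <- reading %*% R
    if (sp$accel_noise_sd_g > 0) {
      sensor_frame <- sensor_frame +
        matrix(stats::rnorm(length(sensor_frame), 0, sp$accel_noise_sd_g),
               ncol = 3)
    }
    imus[[s]] <- imu_recording(back_ts(ti, sensor_frame, sp$imu_rate_hz),
                               units = "g", sensor_site = s)
  }

  truth <- list(
    angle = angle_trace(tm, trig_angle_deg(osc_pos(tm, t0, tau, w, D), geom),
                        method = "truth", rate_hz = sp$marker_rate_hz),
    ranges = truth_ranges(gp, t0, tau, duration_s),
    differential_amp_m = D)

  structure(list(markers = markers, imus = imus, truth = truth,
                 gait_params = gp, sensor_params = sp, tilt = tilt,
                 duration_s = duration_s, seed = as.integer(seed)),
            class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(
    "<synthetic_trial> %s, %.1f s, target range %.2f deg, %d truth cycles, seed %d\n",
    x$gait_params$gait, x$duration_s, x$gait_params$target_flexion_deg,
    nrow(x$truth$ranges), x$seed))
  invisible(x)
}

# second derivative by 5-point central stencil on an analytic trajectory
num_accel <- function(f, t, h = 1e-3) {
  (-f(t - 2 * h) + 16 * f(t - h) - 30 * f(t) + 16 * f(t + h) - f(t + 2 * h)) /
    (12 * h^2)
}

sync_times <- function(sp, duration_s) {
  sp$sync_spike_times_s %||% c(sp$static_preroll_s - 0.2, duration_s - 0.2)
}

# half-sine impulses of the given amplitude (g) and 30 ms width
sync_impulse <- function(t, times, amp_g, width_s = 0.03) {
  out <- numeric(length(t))
  for (tc in times) {
    in_p <- t >= tc - width_s / 2 & t <= tc + width_s / 2
    out[in_p] <- out[in_p] + amp_g * cos(pi * (t[in_p] - tc) / width_s)
  }
  out
}

# steady-state cycles: minima of the truth angle at sin = +1
truth_ranges <- function(gp, t0, tau, duration_s) {
  fc <- gp$cycle_hz
  k <- 0:floor(duration_s * fc)
  t_min <- t0 + (0.25 + k) / fc
  # require the full preceding and following maxima inside the steady segment
  ok <- (t_min - 0.5 / fc) >= (t0 + tau) & (t_min + 0.5 / fc) <= duration_s
  t_min <- t_min[ok]
  T_rng <- gp$target_flexion_deg
  out <- data.frame(cycle_index = seq_along(t_min), time_s = t_min,
                    flexion_deg = rep(T_rng, length(t_min)),
                    extension_deg = rep(gp$target_extension_deg, length(t_min)),
                    gait = gp$gait, trial_id = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("range_table", "data.frame")
  out
}

#' Simulate a paired agreement study
#'
#' Emulates a multi-horse, multi-gait method-comparison study at the level
#' of per-movement ranges. Each movement has a latent true range drawn
#' around the gait's typical motion-capture mean; both methods then measure
#' it with independent Gaussian errors of SD \code{noise_sd_deg / sqrt(2)}
#' each, so the SD of the paired differences equals \code{noise_sd_deg}.
#' The developed method additionally applies \code{slope} and adds
#' \code{bias_deg}:
#' \deqn{\mathrm{ref} = u + e_1, \qquad
#'       \mathrm{dev} = \mathrm{slope}\cdot u + \mathrm{bias} + e_2.}
#'
#' @param n_horses number of horses.
#' @param movements_per_gait movements per horse per gait; scalar or a named
#'   vector with entries walk/trot/gallop.
#' @param bias_deg constant offset of the developed method, degrees.
#' @param noise_sd_deg SD of the paired differences, degrees.
#' @param slope proportional distortion of the developed method (default 1).
#' @param seed integer seed.
#' @return A \code{\link{paired_ranges}} with horse/gait labels.
#' @export
simulate_agreement_study <- function(n_horses = 4, movements_per_gait = 28,
                                     bias_deg = 0.8, noise_sd_deg = 1.5,
                                     slope = 1, seed = 1L) {
  set.seed(as.integer(seed))
  gaits <- c("walk", "trot", "gallop")
  mu <- c(walk = 2.6, trot = 3.9, gallop = 9.5)
  sdv <- c(walk = 1.3, trot = 1.1, gallop = 1.3)
  mpg <- if (length(movements_per_gait) == 1L) {
    stats::setNames(rep(movements_per_gait, 3), gaits)
  } else movements_per_gait
  rows <- list()
  for (g in gaits) {
    for (h in seq_len(n_horses)) {
      n <- mpg[[g]]
      u <- pmax(0.2, stats::rnorm(n, mu[[g]], sdv[[g]]))
      e1 <- stats::rnorm(n, 0, noise_sd_deg / sqrt(2))
      e2 <- stats::rnorm(n, 0, noise_sd_deg / sqrt(2))
      rows[[paste(g, h)]] <- data.frame(
        reference = u + e1,
        developed = slope * u + bias_deg + e2,
        gait = g, horse = h, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  paired_ranges(df$developed, df$reference,
                labels = df[, c("gait", "horse")])
}
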