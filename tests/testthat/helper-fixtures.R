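# shared fixtures built in code

# uniform sinusoidal series
sine_ts <- function(f_hz, fs_hz, dur_s = 10, amp = 1, offset = 0) {
  t <- seq(0, dur_s, by = 1 / fs_hz)
  back_ts(t, offset + amp * sin(2 * pi * f_hz * t), fs_hz)
}

# constant-orientation static IMU recording in g
static_imu <- function(reading_g, fs_hz = 225, dur_s = 2,
                       site = "withers") {
  t <- seq(0, dur_s, by = 1 / fs_hz)
  imu_recording(back_ts(t, matrix(reading_g, nrow = length(t), ncol = 3,
                                  byrow = TRUE), fs_hz),
                units = "g", sensor_site = site)
}

# three constant markers held for a few frames (for static-geometry angles)
static_markers <- function(w, t18, p, n = 5, fs = 200) {
  t <- seq(0, by = 1 / fs, length.out = n)
  m <- function(pos) back_ts(t, matrix(pos, nrow = n, ncol = 3, byrow = TRUE), fs)
  marker_set(m(w), m(t18), m(p))
}

# random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# mean steady-state flexion range: cycles matched to the simulator's truth
steady_flexion <- function(trial, angle) {
  rt <- compute_ranges(find_extrema(angle, trial$gait_params$gait))
  m <- pair_cycles(rt, trial$truth$ranges, trial$gait_params$cycle_hz)
  mean(m$flexion_dev, na.rm = TRUE)
}
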