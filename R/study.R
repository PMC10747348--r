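#' IMU angle pipeline for one trial
#'
#' Runs the full accelerometer chain for the three trunk sensors of a
#' trial: orientation estimation from the standing-square window,
#' rotation into the terrestrial frame, drift-controlled double integration
#' to vertical displacement, resampling to the common rate, and the
#' trigonometric angle reconstruction with final 5 Hz smoothing.
#'
#' @param imus named list of \code{\link{imu_recording}} with entries
#'   \code{withers}, \code{t18}, \code{pelvis}.
#' @param geom a \code{\link{geometry_config}}.
#' @param static_window numeric \code{c(t0, t1)}: the motionless
#'   standing-square period.
#' @param target_hz common sampling rate for the method comparison
#'   (default 200).
#' @param drift_cutoff_hz high-pass cutoff for drift removal (default 1).
#' @param smooth_cutoff_hz final angle low-pass cutoff (default 5).
#' @param filter_order Butterworth order (default 4).
#' @return An \code{\link{angle_trace}} (\code{method = "imu"}) with
#'   attributes \code{orientation} (per-sensor corrections) and
#'   \code{clip_count}.
#' @export
imu_angle_pipeline <- function(imus, geom, static_window,
                               target_hz = 200, drift_cutoff_hz = 1,
                               smooth_cutoff_hz = 5, filter_order = 4L) {
  need <- c("withers", "t18", "pelvis")
  if (!all(need %in% names(imus))) {
    stop("imu_angle_pipeline: imus must contain withers, t18, pelvis")
  }
  w <- as_sync_window(static_window)
  corr <- list()
  disp <- list()
  for (s in need) {
    rec <- imus[[s]]
    static_rec <- rec
    static_rec$accel <- trim(rec$accel, w)
    corr[[s]] <- estimate_orientation(static_rec)
    terr <- correct_to_terrestrial(rec, corr[[s]])
    d <- vertical_displacement(terr, static_window = w,
                               drift_cutoff_hz = drift_cutoff_hz,
                               filter_order = filter_order)
    disp[[s]] <- resample(d, target_hz)
  }
  n <- min(vapply(disp, length, 1L))
  disp <- lapply(disp, function(d) {
    back_ts(d$time[seq_len(n)],
            if (is.matrix(d$values)) d$values[seq_len(n), ] else d$values[seq_len(n)],
            d$rate_hz)
  })
  ang <- compute_imu_angle(
    displacement_triplet(disp$withers, disp$t18, disp$pelvis),
    geom, smooth_cutoff_hz = smooth_cutoff_hz, filter_order = filter_order)
  attr(ang, "orientation") <- corr
  ang
}

#' Pair per-cycle ranges from two methods
#'
#' Matches each reference-method cycle to the developed-method cycle whose
#' minimum lies nearest in time, accepting matches within
#' \code{tol_frac} of the cycle period. Unmatched cycles are dropped (and
#' counted in the \code{n_unmatched} attribute).
#'
#' @param developed,reference \code{range_table}s from
#'   \code{\link{compute_ranges}} (must contain \code{time_s}).
#' @param cycle_hz expected cycle frequency in Hz.
#' @param tol_frac matching tolerance as a fraction of the cycle period
#'   (default 0.25).
#' @return A data frame with one row per matched cycle: flexion/extension
#'   from both methods.
#' @export
pair_cycles <- function(developed, reference, cycle_hz, tol_frac = 0.25) {
  tol <- tol_frac / cycle_hz
  rows <- list()
  used <- logical(nrow(developed))
  for (i in seq_len(nrow(reference))) {
    dt <- abs(developed$time_s - reference$time_s[i])
    j <- which.min(dt)
    if (length(j) && dt[j] <= tol && !used[j]) {
      used[j] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = reference$time_s[i],
        flexion_dev = developed$flexion_deg[j],
        flexion_ref = reference$flexion_deg[i],
        extension_dev = developed$extension_deg[j],
        extension_ref = reference$extension_deg[i])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time_s = numeric(0), flexion_dev = numeric(0),
               flexion_ref = numeric(0), extension_dev = numeric(0),
               extension_ref = numeric(0))
  attr(out, "n_unmatched") <- nrow(reference) - nrow(out)
  out
}

#' Run both pipelines on simulated trials and compare the methods
#'
#' End-to-end driver: for each trial it computes the motion-capture angle
#' from the markers and the IMU angle from the accelerations, synchronises
#' both traces between the pastern sync strikes, segments them into
#' flexion/extension cycles, pairs the per-cycle ranges by cycle time, and
#' pools all pairs into one agreement analysis (Bland-Altman, OLP
#' regression, Pearson correlation).
#'
#' @param trials a \code{\link{simulate_trial}} result or list of them.
#' @param sync_threshold_g pastern strike detection threshold in g.
#' @param target_hz common sampling rate (default 200).
#' @param min_prominence_deg extrema prominence threshold (default 0.5).
#' @return An object of class \code{method_comparison}: list with
#'   \code{pairs_flexion}, \code{pairs_extension}
#'   (\code{\link{paired_ranges}}), \code{agreement_flexion},
#'   \code{agreement_extension} (\code{\link{agreement_report}}s), and
#'   per-trial range tables.
#' @examples
#' \donttest{
#' gp <- gait_params("trot")
#' trial <- simulate_trial(gp, sensor_params_ideal(), duration_s = 10, seed = 7)
#' cmp <- run_method_comparison(trial)
#' summary(cmp)
#' }
#' @export
run_method_comparison <- function(trials, sync_threshold_g = 2,
                                  target_hz = 200,
                                  min_prominence_deg = 0.5) {
  if (inherits(trials, "synthetic_trial")) trials <- list(trials)
  per_trial <- list()
  for (k in seq_along(trials)) {
    tr <- trials[[k]]
    stopifnot(inherits(tr, "synthetic_trial"))
    gp <- tr$gait_params
    sp <- tr$sensor_params
    static_w <- c(0.2, sp$static_preroll_s - 0.3)

    ang_mocap <- compute_mocap_angle(tr$markers)
    ang_imu <- imu_angle_pipeline(tr$imus, gp$geometry, static_w,
                                  target_hz = target_hz)
    sw <- detect_sync_strikes(tr$imus$pastern, threshold_g = sync_threshold_g)
    ang_mocap <- trim(ang_mocap, sw)
    ang_imu <- trim(ang_imu, sw)

    rng <- function(ang) {
      compute_ranges(find_extrema(ang, gp$gait,
                                  min_prominence_deg = min_prominence_deg),
                     gait = gp$gait, trial_id = as.character(k))
    }
    r_mocap <- rng(ang_mocap)
    r_imu <- rng(ang_imu)
    per_trial[[k]] <- list(ranges_mocap = r_mocap, ranges_imu = r_imu,
                           paired = pair_cycles(r_imu, r_mocap, gp$cycle_hz),
                           sync_window = sw)
  }
  paired <- do.call(rbind, lapply(per_trial, `[[`, "paired"))
  cf <- stats::complete.cases(paired[, c("flexion_dev", "flexion_ref")])
  ce <- stats::complete.cases(paired[, c("extension_dev", "extension_ref")])
  pairs_flexion <- paired_ranges(paired$flexion_dev[cf], paired$flexion_ref[cf])
  pairs_extension <- paired_ranges(paired$extension_dev[ce],
                                   paired$extension_ref[ce])
  structure(list(
    pairs_flexion = pairs_flexion,
    pairs_extension = pairs_extension,
    agreement_flexion = agreement_report(pairs_flexion),
    agreement_extension = agreement_report(pairs_extension),
    per_trial = per_trial),
    class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Back flexion/extension method comparison (IMU vs MOCAP)\n\n")
  cat("-- Flexion ranges --\n")
  print(x$agreement_flexion)
  cat("\n-- Extension ranges --\n")
  print(x$agreement_extension)
  invisible(x)
}

#' @export
summary.method_comparison <- function(object, ...) {
  rbind(cbind(movement = "flexion", summary(object$agreement_flexion)),
        cbind(movement = "extension", summary(object$agreement_extension)))
}

#' @export
plot.method_comparison <- function(x, which = c("flexion", "extension"), ...) {
  which <- match.arg(which)
  plot(x[[paste0("agreement_", which)]], ...)
}
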