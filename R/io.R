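#' Marker trajectory set
#'
#' Container for the three trunk marker trajectories (withers, T18, pelvis),
#' each an n x 3 position matrix in metres on a shared uniform time base.
#'
#' @param withers,t18,pelvis \code{\link{back_ts}} objects with 3-column
#'   (x, y, z) values in metres, sharing timestamps.
#' @param vertical_axis which column carries the vertical coordinate
#'   (up-positive); default \code{"z"}.
#' @return An object of class \code{marker_set}.
#' @export
marker_set <- function(withers, t18, pelvis, vertical_axis = "z") {
  for (m in list(withers, t18, pelvis)) {
    stopifnot(inherits(m, "back_ts"))
    if (ts_nchannel(m) != 3L) stop("marker_set: each trajectory needs x,y,z columns")
  }
  if (!isTRUE(all.equal(withers$time, t18$time)) ||
      !isTRUE(all.equal(withers$time, pelvis$time))) {
    stop("marker_set: trajectories must share timestamps")
  }
  vertical_axis <- match.arg(vertical_axis, c("x", "y", "z"))
  structure(list(withers = withers, t18 = t18, pelvis = pelvis,
                 vertical_axis = vertical_axis),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d frames at %.6g Hz, vertical axis %s\n",
              length(x$withers$time), x$withers$rate_hz, x$vertical_axis))
  invisible(x)
}

#' IMU recording
#'
#' Tri-axial acceleration from one sensor. Values are stored in the declared
#' units; \code{\link{imu_in_units}} converts between g and m/s^2 with
#' g = 9.81 m/s^2.
#'
#' @param accel a \code{\link{back_ts}} with 3 columns (ax, ay, az).
#' @param units \code{"g"} or \code{"ms2"}.
#' @param sensor_site one of withers, t18, pelvis, pastern.
#' @return An object of class \code{imu_recording}.
#' @export
imu_recording <- function(accel, units = c("g", "ms2"),
                          sensor_site = c("withers", "t18", "pelvis", "pastern")) {
  stopifnot(inherits(accel, "back_ts"))
  if (ts_nchannel(accel) != 3L) stop("imu_recording: need 3 acceleration channels")
  structure(list(accel = accel, units = match.arg(units),
                 sensor_site = match.arg(sensor_site)),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> site %s, %d samples at %.6g Hz [%s]\n",
              x$sensor_site, length(x$accel$time), x$accel$rate_hz, x$units))
  invisible(x)
}

#' Convert an IMU recording between g and m/s^2
#'
#' @param rec an \code{\link{imu_recording}}.
#' @param units target units, \code{"g"} or \code{"ms2"}.
#' @return The recording expressed in \code{units}.
#' @export
imu_in_units <- function(rec, units = c("g", "ms2")) {
  stopifnot(inherits(rec, "imu_recording"))
  units <- match.arg(units)
  if (units == rec$units) return(rec)
  f <- if (units == "ms2") GRAVITY_MS2 else 1 / GRAVITY_MS2
  rec$accel$values <- rec$accel$values * f
  rec$units <- units
  rec
}

#' Read marker trajectories from CSV
#'
#' Expects a header row with a time column and, for each marker,
#' \code{<marker>_x}, \code{<marker>_y}, \code{<marker>_z} columns. Gaps of
#' up to \code{max_gap} consecutive missing frames per marker are filled by
#' cubic-spline interpolation; longer gaps, or more than 10\% missing frames
#' overall for a marker, are an error.
#'
#' @param path CSV file path.
#' @param units positions in metres (\code{"m"}) or millimetres (\code{"mm"}).
#' @param column_map named list mapping roles to column names; defaults to
#'   \code{time}, \code{withers_*}, \code{t18_*}, \code{pelvis_*}.
#' @param vertical_axis which coordinate is vertical (default \code{"z"}).
#' @param max_gap longest run of missing frames to interpolate (default 5).
#' @return A \code{\link{marker_set}} in metres.
#' @export
read_marker_csv <- function(path, units = c("m", "mm"),
                            column_map = NULL, vertical_axis = "z",
                            max_gap = 5L) {
  units <- match.arg(units)
  df <- utils::read.csv(path, check.names = FALSE)
  cm <- marker_column_map(column_map)
  need <- unlist(cm, use.names = FALSE)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("read_marker_csv: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  time <- df[[cm$time]]
  if (any(diff(time) <= 0)) stop("read_marker_csv: non-monotone timestamps")
  scale <- if (units == "mm") 1e-3 else 1
  get_marker <- function(marker) {
    cols <- paste0(marker, c("_x", "_y", "_z"))
    xyz <- as.matrix(df[, vapply(cols, function(nm) cm[[nm]], "")]) * scale
    miss <- !stats::complete.cases(xyz)
    if (mean(miss) > 0.10) {
      stop("read_marker_csv: >10% missing frames for marker '", marker, "'")
    }
    if (any(miss)) xyz <- fill_marker_gaps(time, xyz, max_gap, marker)
    back_ts(time, xyz)
  }
  marker_set(get_marker("withers"), get_marker("t18"), get_marker("pelvis"),
             vertical_axis = vertical_axis)
}

marker_column_map <- function(column_map) {
  default <- list(time = "time")
  for (m in c("withers", "t18", "pelvis")) {
    for (ax in c("x", "y", "z")) default[[paste0(m, "_", ax)]] <- paste0(m, "_", ax)
  }
  if (!is.null(column_map)) default[names(column_map)] <- column_map
  default
}

fill_marker_gaps <- function(time, xyz, max_gap, marker) {
  miss <- !stats::complete.cases(xyz)
  runs <- rle(miss)
  if (any(runs$values & runs$lengths > max_gap)) {
    stop("read_marker_csv: gap of ", max(runs$lengths[runs$values]),
         " frames for marker '", marker, "' exceeds max_gap = ", max_gap)
  }
  if (miss[1] || miss[length(miss)]) {
    stop("read_marker_csv: missing frames at recording edge for '", marker, "'")
  }
  for (j in 1:3) {
    bad <- is.na(xyz[, j])
    if (any(bad)) {
      xyz[bad, j] <- stats::spline(time[!bad], xyz[!bad, j],
                                   xout = time[bad], method = "fmm")$y
    }
  }
  xyz
}

#' Write marker trajectories to CSV
#'
#' Inverse of \code{\link{read_marker_csv}} (always writes metres).
#'
#' @param markers a \code{\link{marker_set}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_marker_csv <- function(markers, path) {
  stopifnot(inherits(markers, "marker_set"))
  df <- data.frame(time = markers$withers$time)
  for (m in c("withers", "t18", "pelvis")) {
    xyz <- markers[[m]]$values
    df[[paste0(m, "_x")]] <- xyz[, 1]
    df[[paste0(m, "_y")]] <- xyz[, 2]
    df[[paste0(m, "_z")]] <- xyz[, 3]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a tri-axial IMU recording from CSV
#'
#' Expects columns \code{time, ax, ay, az} (renameable via
#' \code{column_map}).
#'
#' @param path CSV file path.
#' @param units units of the stored values, \code{"g"} or \code{"ms2"}.
#' @param sensor_site sensor placement label.
#' @param column_map optional named list overriding column names.
#' @return An \code{\link{imu_recording}} in the declared units.
#' @export
read_imu_csv <- function(path, units = c("g", "ms2"),
                         sensor_site = c("withers", "t18", "pelvis", "pastern"),
                         column_map = NULL) {
  units <- match.arg(units)
  sensor_site <- match.arg(sensor_site)
  cm <- list(time = "time", ax = "ax", ay = "ay", az = "az")
  if (!is.null(column_map)) cm[names(column_map)] <- column_map
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(unlist(cm), names(df))
  if (length(missing_cols)) {
    stop("read_imu_csv: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  time <- df[[cm$time]]
  if (any(diff(time) <= 0)) stop("read_imu_csv: non-monotone timestamps")
  acc <- cbind(df[[cm$ax]], df[[cm$ay]], df[[cm$az]])
  if (anyNA(acc)) stop("read_imu_csv: missing acceleration samples")
  imu_recording(back_ts(time, acc), units = units, sensor_site = sensor_site)
}

#' Write an IMU recording to CSV
#'
#' @param rec an \code{\link{imu_recording}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(time = rec$accel$time,
                   ax = rec$accel$values[, 1],
                   ay = rec$accel$values[, 2],
                   az = rec$accel$values[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Trunk geometry configuration
#'
#' Tape-measured distances between the sensor sites: \code{x_m} from T18 to
#' the pelvis sensor and \code{x2_m} from the withers sensor to T18, both in
#' metres. These are the two triangle sides of the trigonometric angle
#' reconstruction.
#'
#' @param x_m T18-to-pelvis distance in metres.
#' @param x2_m withers-to-T18 distance in metres.
#' @return An object of class \code{geometry_config}.
#' @export
geometry_config <- function(x_m, x2_m) {
  for (v in c(x_m, x2_m)) {
    if (!is.numeric(v) || !is.finite(v) || v <= 0 || v >= 2) {
      stop("geometry_config: distances must be in (0, 2) metres")
    }
  }
  structure(list(x_m = x_m, x2_m = x2_m), class = "geometry_config")
}

#' Read a run configuration from YAML
#'
#' Reads geometry (X, X2), sampling rates, filter settings and the sync
#' threshold; missing entries fall back to package defaults.
#'
#' @param path YAML file path.
#' @return A named list with elements \code{geometry}
#'   (a \code{\link{geometry_config}}), \code{target_hz},
#'   \code{smooth_cutoff_hz}, \code{drift_cutoff_hz}, \code{filter_order},
#'   \code{sync_threshold_g}.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$geometry) || is.null(raw$geometry$x_m) ||
      is.null(raw$geometry$x2_m)) {
    stop("read_run_config: geometry with x_m and x2_m is required")
  }
  cfg <- list(
    geometry = geometry_config(raw$geometry$x_m, raw$geometry$x2_m),
    target_hz = raw$target_hz %||% 200,
    smooth_cutoff_hz = raw$smooth_cutoff_hz %||% 5,
    drift_cutoff_hz = raw$drift_cutoff_hz %||% 1,
    filter_order = raw$filter_order %||% 4L,
    sync_threshold_g = raw$sync_threshold_g %||% 2
  )
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
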