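#' Uniform time series
#'
#' Light-weight carrier for uniformly sampled signals: a strictly increasing
#' time vector, a value vector (or an n x k matrix for multi-channel signals
#' such as tri-axial acceleration) and the sampling rate. All pipeline stages
#' consume and produce this container.
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing
#'   with a uniform step.
#' @param values numeric vector, or matrix with \code{length(time)} rows.
#' @param rate_hz sampling frequency in Hz. If missing it is inferred from
#'   the median time step.
#' @return An object of class \code{back_ts}: a list with elements
#'   \code{time}, \code{values}, \code{rate_hz}.
#' @examples
#' ts <- back_ts(seq(0, 1, by = 0.01), sin(2 * pi * seq(0, 1, by = 0.01)))
#' ts$rate_hz
#' @export
back_ts <- function(time, values, rate_hz = NULL) {
  time <- as.numeric(time)
  if (length(time) < 2L) stop("back_ts: need at least two samples")
  step <- diff(time)
  if (any(step <= 0)) stop("back_ts: timestamps must be strictly increasing")
  if (is.null(rate_hz)) rate_hz <- 1 / stats::median(step)
  if (max(abs(step - 1 / rate_hz)) > 1e-6) {
    stop("back_ts: sampling is not uniform at ", signif(rate_hz, 6),
         " Hz (max step deviation ", signif(max(abs(step - 1 / rate_hz)), 3), " s)")
  }
  if (is.matrix(values)) dimnames(values) <- NULL else values <- as.numeric(values)
  n_val <- if (is.matrix(values)) nrow(values) else length(values)
  if (n_val != length(time)) stop("back_ts: values and time lengths differ")
  structure(list(time = time, values = values, rate_hz = rate_hz),
            class = "back_ts")
}

#' @export
print.back_ts <- function(x, ...) {
  k <- if (is.matrix(x$values)) ncol(x$values) else 1L
  cat(sprintf("<back_ts> %d samples x %d channel(s), %.6g Hz, span %.3f..%.3f s\n",
              length(x$time), k, x$rate_hz, x$time[1], x$time[length(x$time)]))
  invisible(x)
}

#' @export
as.data.frame.back_ts <- function(x, ...) {
  if (is.matrix(x$values)) {
    data.frame(time = x$time, x$values)
  } else {
    data.frame(time = x$time, value = x$values)
  }
}

#' @export
length.back_ts <- function(x) length(x$time)

ts_nchannel <- function(ts) if (is.matrix(ts$values)) ncol(ts$values) else 1L

ts_column <- function(ts, j) if (is.matrix(ts$values)) ts$values[, j] else ts$values

# apply f() column-wise, preserving time base
ts_map <- function(ts, f) {
  v <- if (is.matrix(ts$values)) apply(ts$values, 2L, f) else f(ts$values)
  back_ts(ts$time, v, ts$rate_hz)
}

#' Resample a time series to a new rate
#'
#' Cubic-spline resampling (continuous first derivative) onto a uniform grid
#' at \code{target_hz} spanning the same interval as the input. Used to
#' homogenise the 225 Hz IMU streams and the 200 Hz marker streams onto one
#' common rate before comparing methods.
#'
#' @param ts a \code{\link{back_ts}}.
#' @param target_hz positive target sampling frequency in Hz.
#' @return A \code{back_ts} at \code{target_hz}.
#' @examples
#' ts <- back_ts(seq(0, 1, by = 1/225), sin(2 * pi * seq(0, 1, by = 1/225)))
#' resample(ts, 200)
#' @export
resample <- function(ts, target_hz) {
  stopifnot(inherits(ts, "back_ts"))
  if (!is.numeric(target_hz) || target_hz <= 0) {
    stop("resample: target_hz must be positive")
  }
  t0 <- ts$time[1]
  t1 <- ts$time[length(ts$time)]
  new_time <- seq(t0, t1, by = 1 / target_hz)
  # keep final point inside the input span (spline would extrapolate)
  new_time <- new_time[new_time <= t1 + 1e-12]
  interp1 <- function(v) {
    stats::spline(ts$time, v, xout = new_time, method = "fmm")$y
  }
  v <- if (is.matrix(ts$values)) {
    apply(ts$values, 2L, interp1)
  } else {
    interp1(ts$values)
  }
  back_ts(new_time, v, target_hz)
}

#' Trim a time series to a synchronisation window
#'
#' Keeps samples with \code{t_start <= t <= t_end} and re-zeroes the time
#' base to \code{t_start}, mirroring the trial-trimming step between the two
#' pastern sync strikes.
#'
#' @param ts a \code{\link{back_ts}}.
#' @param window a \code{\link{sync_window}} or numeric \code{c(t_start, t_end)}.
#' @return The trimmed, re-zeroed \code{back_ts}.
#' @export
trim <- function(ts, window) {
  stopifnot(inherits(ts, "back_ts"))
  w <- as_sync_window(window)
  span <- range(ts$time)
  if (w$t_start < span[1] - 1e-9 || w$t_end > span[2] + 1e-9) {
    stop("trim: window [", w$t_start, ", ", w$t_end, "] outside recording span")
  }
  keep <- ts$time >= w$t_start - 1e-9 & ts$time <= w$t_end + 1e-9
  if (sum(keep) < 2L) stop("trim: window retains fewer than two samples")
  v <- if (is.matrix(ts$values)) ts$values[keep, , drop = FALSE] else ts$values[keep]
  back_ts(ts$time[keep] - ts$time[keep][1], v, ts$rate_hz)
}

#' Synchronisation window
#'
#' @param t_start,t_end window bounds in seconds, \code{t_start < t_end}.
#' @return An object of class \code{sync_window}.
#' @export
sync_window <- function(t_start, t_end) {
  if (!is.finite(t_start) || !is.finite(t_end) || t_start >= t_end) {
    stop("sync_window: need t_start < t_end")
  }
  structure(list(t_start = t_start, t_end = t_end), class = "sync_window")
}

as_sync_window <- function(x) {
  if (inherits(x, "sync_window")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(sync_window(x[1], x[2]))
  stop("expected a sync_window or a numeric pair")
}

#' @export
print.sync_window <- function(x, ...) {
  cat(sprintf("<sync_window> %.4f .. %.4f s\n", x$t_start, x$t_end))
  invisible(x)
}
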