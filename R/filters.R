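#' Zero-phase Butterworth filter
#'
#' Forward-backward (zero-phase) Butterworth filtering of a uniform time
#' series. The two angle pipelines use an order-4 low-pass at 5 Hz for
#' smoothing and an order-4 high-pass at 1 Hz for integration-drift removal.
#'
#' Edge transients are controlled scipy-style: the series is extended at both
#' ends by an odd reflection before filtering and the extension is discarded
#' afterwards. The signal mean is removed before filtering and, for a
#' low-pass (unit DC gain), added back, so a constant input maps to itself
#' under a low-pass and to exactly zero under a high-pass.
#'
#' @param ts a \code{\link{back_ts}} (vector or matrix valued).
#' @param cutoff_hz cutoff frequency in Hz; must be below Nyquist.
#' @param order filter order (default 4, as used throughout the pipeline).
#' @param kind \code{"lowpass"} or \code{"highpass"}.
#' @return A filtered \code{back_ts} with identical timestamps.
#' @examples
#' t <- seq(0, 10, by = 1/200)
#' ts <- back_ts(t, sin(2 * pi * 2 * t) + sin(2 * pi * 30 * t))
#' smooth <- butterworth_filter(ts, 5, kind = "lowpass")
#' @export
butterworth_filter <- function(ts, cutoff_hz, order = 4L,
                               kind = c("lowpass", "highpass")) {
  stopifnot(inherits(ts, "back_ts"))
  kind <- match.arg(kind)
  nyq <- ts$rate_hz / 2
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq) {
    stop("butterworth_filter: cutoff must lie in (0, Nyquist = ",
         signif(nyq, 6), ") Hz")
  }
  bf <- signal::butter(order, cutoff_hz / nyq,
                       type = if (kind == "lowpass") "low" else "high")
  # pad long enough for the slowest filter transient to die out
  npad <- min(length(ts$time) - 1L, ceiling(6 * ts$rate_hz / cutoff_hz))
  ts_map(ts, function(x) filtfilt_padded(bf, x, npad, restore_mean = kind == "lowpass"))
}

# odd-reflection padded filtfilt; removes the mean first so the padding step
# discontinuities (signal::filtfilt appends zeros internally) stay small
filtfilt_padded <- function(bf, x, npad, restore_mean) {
  n <- length(x)
  m <- mean(x)
  x <- x - m
  if (npad > 0L) {
    pre <- 2 * x[1] - x[(npad + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - npad)]
    y <- signal::filtfilt(bf, c(pre, x, post))[(npad + 1L):(npad + n)]
  } else {
    y <- signal::filtfilt(bf, x)
  }
  if (restore_mean) y + m else y
}
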