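#' Back vectors at one frame
#'
#' The two vectors of the marker-based angle computation, both anchored at
#' the T18 marker: \code{v_withers} is T18 - withers (pointing from the
#' withers marker to T18) and \code{v_pelvis} is T18 - pelvis.
#'
#' @param markers a \code{\link{marker_set}}.
#' @param i frame index.
#' @return A list with 3-vectors \code{v_withers} and \code{v_pelvis}.
#' @export
back_vectors <- function(markers, i) {
  stopifnot(inherits(markers, "marker_set"))
  vw <- markers$t18$values[i, ] - markers$withers$values[i, ]
  vp <- markers$t18$values[i, ] - markers$pelvis$values[i, ]
  if (sqrt(sum(vw^2)) < 1e-12 || sqrt(sum(vp^2)) < 1e-12) {
    stop("back_vectors: coincident markers at frame ", i)
  }
  list(v_withers = as.numeric(vw), v_pelvis = as.numeric(vp))
}

#' Angle trace
#'
#' A time series of the global back angle in degrees together with the
#' method that produced it.
#'
#' @param time timestamps in seconds.
#' @param angle_deg angle in degrees, finite, in [0, 360].
#' @param method \code{"mocap"}, \code{"imu"} or \code{"truth"} (simulator
#'   ground truth).
#' @param rate_hz sampling frequency (inferred if omitted).
#' @return An object of class \code{angle_trace} (also a \code{back_ts}).
#' @export
angle_trace <- function(time, angle_deg, method = c("mocap", "imu", "truth"),
                        rate_hz = NULL) {
  method <- match.arg(method)
  if (any(!is.finite(angle_deg))) stop("angle_trace: non-finite angles")
  if (any(angle_deg < 0 | angle_deg > 360)) {
    stop("angle_trace: angles outside [0, 360] degrees")
  }
  ts <- back_ts(time, angle_deg, rate_hz)
  ts$method <- method
  class(ts) <- c("angle_trace", class(ts))
  ts
}

#' @export
print.angle_trace <- function(x, ...) {
  cat(sprintf("<angle_trace> method %s, %d samples at %.6g Hz, mean %.2f deg\n",
              x$method, length(x$time), x$rate_hz, mean(x$values)))
  invisible(x)
}

#' Motion-capture back angle
#'
#' Reference computation of the global back flexion/extension angle from the
#' three trunk markers. The marker positions are first smoothed with an
#' order-4 zero-phase Butterworth low-pass at \code{smooth_cutoff_hz}; the
#' angle at each frame is the angle at the T18 vertex between the vectors to
#' the withers and pelvis markers,
#' \deqn{\theta = \arccos\left(\frac{v_w \cdot v_p}{\|v_w\|\,\|v_p\|}\right),}
#' reported in degrees. A perfectly straight back gives 180 degrees; flexion
#' (back arching up) drives the angle below 180. The arccos argument is
#' clipped to [-1, 1] so numerically collinear frames cannot produce NaN.
#'
#' @param markers a \code{\link{marker_set}} in metres.
#' @param smooth_cutoff_hz marker low-pass cutoff in Hz (default 5); use
#'   \code{NULL} to skip filtering (e.g. for already-filtered input).
#' @param filter_order Butterworth order (default 4).
#' @return An \code{\link{angle_trace}} with \code{method = "mocap"}.
#' @export
compute_mocap_angle <- function(markers, smooth_cutoff_hz = 5,
                                filter_order = 4L) {
  stopifnot(inherits(markers, "marker_set"))
  smooth <- function(m) {
    if (is.null(smooth_cutoff_hz)) return(m)
    butterworth_filter(m, smooth_cutoff_hz, filter_order, "lowpass")
  }
  w <- smooth(markers$withers)$values
  t18 <- smooth(markers$t18)$values
  p <- smooth(markers$pelvis)$values
  vw <- t18 - w
  vp <- t18 - p
  nw <- sqrt(rowSums(vw^2))
  np <- sqrt(rowSums(vp^2))
  if (any(nw < 1e-12) || any(np < 1e-12)) {
    stop("compute_mocap_angle: coincident markers at frame ",
         which(nw < 1e-12 | np < 1e-12)[1])
  }
  cosang <- rowSums(vw * vp) / (nw * np)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  angle_trace(markers$withers$time, ang, method = "mocap",
              rate_hz = markers$withers$rate_hz)
}
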