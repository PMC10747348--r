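#' Detect synchronisation strikes on the pastern channel
#'
#' Trials are book-ended by tapping the pastern-mounted IMU with a marker
#' wand, producing short high-g impulses on the acceleration norm. The
#' detector subtracts the median norm (baseline around 1 g), finds peaks
#' exceeding \code{threshold_g} with a minimum separation of
#' \code{min_separation_s}, and returns the window spanned by the first and
#' last peak.
#'
#' @param pastern an \code{\link{imu_recording}} (any declared units; the
#'   threshold is applied in g).
#' @param threshold_g required peak height above the baseline, in g.
#' @param min_separation_s minimum time between distinct impulses, seconds.
#' @return A \code{\link{sync_window}} from the first to the last impulse.
#' @export
detect_sync_strikes <- function(pastern, threshold_g = 2,
                                min_separation_s = 0.5) {
  stopifnot(inherits(pastern, "imu_recording"))
  rec <- imu_in_units(pastern, "g")
  nrm <- sqrt(rowSums(rec$accel$values^2))
  dev <- nrm - stats::median(nrm)
  pk <- local_peaks(rec$accel$time, dev,
                    min_height = threshold_g,
                    min_separation_s = min_separation_s)
  if (length(pk) < 2L) {
    stop("detect_sync_strikes: found ", length(pk),
         " impulse(s) above ", threshold_g, " g (max excursion ",
         signif(max(dev), 3), " g); need at least 2")
  }
  sync_window(rec$accel$time[pk[1]], rec$accel$time[pk[length(pk)]])
}

# indices of local maxima of y exceeding min_height, greedily thinned so that
# retained peaks are at least min_separation_s apart (highest first)
local_peaks <- function(time, y, min_height, min_separation_s) {
  n <- length(y)
  cand <- which(y > min_height)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[y[cand] >= y[cand - 1L] & y[cand] >= y[cand + 1L]]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(y[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(time[i] - time[kept]) >= min_separation_s)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}
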