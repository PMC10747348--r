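#' Gait stride frequencies and flexion/extension cycle structure
#'
#' The thoracolumbar spine performs two flexion/extension cycles per stride
#' at walk and trot and one per stride at gallop. Default stride frequencies
#' are typical over-ground values (walk 0.9 Hz, trot 1.4 Hz, gallop 1.7 Hz)
#' and can be overridden wherever a gait argument is taken.
#'
#' @param gait \code{"walk"}, \code{"trot"} or \code{"gallop"}.
#' @return A list with \code{stride_hz}, \code{cycles_per_stride} and
#'   \code{cycle_hz} (their product).
#' @export
gait_cycle_structure <- function(gait = c("walk", "trot", "gallop")) {
  gait <- match.arg(gait)
  stride_hz <- c(walk = 0.9, trot = 1.4, gallop = 1.7)[[gait]]
  cps <- if (gait == "gallop") 1L else 2L
  list(stride_hz = stride_hz, cycles_per_stride = cps,
       cycle_hz = stride_hz * cps)
}

#' Find alternating extrema of an angle trace
#'
#' Locates the local maxima and minima that delimit flexion/extension
#' cycles. Candidate extrema are pruned by iteratively discarding the
#' smallest max-min swing until every swing has amplitude at least
#' \code{min_prominence_deg} and same-kind extrema are separated by at least
#' \code{0.4 / cycle_hz} seconds. Extremum times and values are refined by a
#' three-point parabolic fit so peak amplitudes are not biased by the
#' sampling grid. Extrema within \code{edge_guard_s} of either end of the
#' trace are dropped (filter edge effects).
#'
#' @param angle an \code{\link{angle_trace}} (5 Hz smoothed).
#' @param gait gait label used to derive the expected cycle frequency.
#' @param stride_hz optional stride frequency override in Hz.
#' @param min_prominence_deg minimum swing amplitude in degrees (default 0.5).
#' @param edge_guard_s guard band at the trace edges in seconds (default 0.5).
#' @return An object of class \code{extrema_seq}: list with \code{times},
#'   \code{values}, \code{kinds} (alternating \code{"max"}/\code{"min"}).
#' @export
find_extrema <- function(angle, gait = c("walk", "trot", "gallop"),
                         stride_hz = NULL, min_prominence_deg = 0.5,
                         edge_guard_s = 0.5) {
  stopifnot(inherits(angle, "back_ts"))
  gs <- gait_cycle_structure(match.arg(gait))
  if (!is.null(stride_hz)) gs$cycle_hz <- stride_hz * gs$cycles_per_stride
  min_sep_s <- 0.4 / gs$cycle_hz

  t <- angle$time
  y <- angle$values
  idx <- raw_extrema_indices(y)
  if (length(idx$i) < 2L) {
    stop("find_extrema: fewer than two extrema found; trace may be constant")
  }
  ext <- prune_extrema(t[idx$i], y[idx$i], idx$kind,
                       min_prominence_deg, min_sep_s)
  keep <- ext$times >= t[1] + edge_guard_s & ext$times <= t[length(t)] - edge_guard_s
  ext <- lapply(ext, `[`, keep)
  ext <- enforce_alternation(ext)
  if (length(ext$times) < 2L) {
    stop("find_extrema: fewer than two extrema after pruning")
  }
  ref <- refine_extrema(t, y, ext)
  structure(ref, class = "extrema_seq")
}

#' @export
print.extrema_seq <- function(x, ...) {
  cat(sprintf("<extrema_seq> %d extrema (%d max, %d min)\n",
              length(x$times), sum(x$kinds == "max"), sum(x$kinds == "min")))
  invisible(x)
}

# strict local extrema with plateau midpoints
raw_extrema_indices <- function(y) {
  d <- sign(diff(y))
  # carry the last non-zero slope through plateaus
  for (i in seq_along(d)[-1]) if (d[i] == 0) d[i] <- d[i - 1]
  turn <- which(diff(d) != 0) + 1L
  kind <- ifelse(d[turn] < 0, "max", "min")
  list(i = turn, kind = kind)
}

# iteratively remove the weakest adjacent swing violating prominence or
# same-kind separation; removal of an adjacent pair preserves alternation
prune_extrema <- function(times, values, kinds, min_prom, min_sep) {
  ext <- enforce_alternation(list(times = times, values = values, kinds = kinds))
  repeat {
    n <- length(ext$times)
    if (n < 2L) break
    swing <- abs(diff(ext$values))
    bad_prom <- which(swing < min_prom)
    # same-kind separation: consecutive extrema of one kind are 2 apart
    gap <- ext$times[-(1:2)] - ext$times[1:(n - 2L)]
    bad_sep <- which(gap < min_sep)
    if (!length(bad_prom) && !length(bad_sep)) break
    if (length(bad_prom)) {
      j <- bad_prom[which.min(swing[bad_prom])]   # drop extrema j, j+1
      drop <- c(j, j + 1L)
    } else {
      j <- bad_sep[1]
      # swings (j, j+1) and (j+1, j+2); drop the pair around the weaker swing
      drop <- if (swing[j] <= swing[j + 1L]) c(j, j + 1L) else c(j + 1L, j + 2L)
    }
    ext <- lapply(ext, `[`, -drop)
    ext <- enforce_alternation(ext)
  }
  ext
}

# collapse runs of same-kind extrema, keeping the most extreme one
enforce_alternation <- function(ext) {
  n <- length(ext$times)
  if (n < 2L) return(ext)
  keep <- rep(TRUE, n)
  i <- 1L
  while (i < n) {
    j <- i + 1L
    while (j <= n && ext$kinds[j] == ext$kinds[i]) j <- j + 1L
    if (j - i > 1L) {
      run <- i:(j - 1L)
      best <- if (ext$kinds[i] == "max") run[which.max(ext$values[run])]
              else run[which.min(ext$values[run])]
      keep[setdiff(run, best)] <- FALSE
    }
    i <- j
  }
  lapply(ext, `[`, keep)
}

# quadratic refinement around each extremum sample
refine_extrema <- function(t, y, ext) {
  dt <- t[2] - t[1]
  n <- length(t)
  for (k in seq_along(ext$times)) {
    i <- which.min(abs(t - ext$times[k]))
    if (i > 1L && i < n) {
      y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
      denom <- y0 - 2 * y1 + y2
      if (abs(denom) > .Machine$double.eps) {
        delta <- 0.5 * (y0 - y2) / denom
        delta <- max(-0.5, min(0.5, delta))
        ext$times[k] <- t[i] + delta * dt
        ext$values[k] <- y1 - 0.25 * (y0 - y2) * delta
      }
    }
  }
  ext
}

#' Per-cycle flexion and extension ranges
#'
#' Turns an alternating extrema sequence into per-cycle ranges. A leading
#' minimum is dropped so the sequence starts with a maximum; then each
#' minimum \eqn{m_i} with preceding maximum \eqn{M_{i-1}} and following
#' maximum \eqn{M_i} yields
#' \deqn{\mathrm{extension}_i = M_{i-1} - m_i, \qquad
#'       \mathrm{flexion}_i = M_i - m_i.}
#' A trailing minimum without a following maximum contributes its extension
#' only (\code{flexion_deg = NA}).
#'
#' @param ext an \code{\link{extrema_seq}}.
#' @param gait optional gait label stored in the table.
#' @param trial_id optional trial identifier stored in the table.
#' @return A \code{range_table}: data frame with columns
#'   \code{cycle_index}, \code{flexion_deg}, \code{extension_deg},
#'   \code{gait}, \code{trial_id}.
#' @export
compute_ranges <- function(ext, gait = NA_character_, trial_id = NA_character_) {
  stopifnot(inherits(ext, "extrema_seq") || is.list(ext))
  kinds <- ext$kinds
  values <- ext$values
  times <- ext$times
  if (length(kinds) && kinds[1] == "min") {
    kinds <- kinds[-1]; values <- values[-1]; times <- times[-1]
  }
  mins <- which(kinds == "min")
  rows <- list()
  ci <- 0L
  for (i in mins) {
    if (i == 1L) next                      # no preceding maximum
    ci <- ci + 1L
    ext_rng <- values[i - 1L] - values[i]
    flex_rng <- if (i + 1L <= length(values)) values[i + 1L] - values[i] else NA_real_
    rows[[ci]] <- data.frame(cycle_index = ci,
                             time_s = times[i],
                             flexion_deg = flex_rng,
                             extension_deg = ext_rng,
                             gait = gait, trial_id = trial_id,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("compute_ranges: no complete max-min cycle found")
    out <- data.frame(cycle_index = integer(0), time_s = numeric(0),
                      flexion_deg = numeric(0), extension_deg = numeric(0),
                      gait = character(0), trial_id = character(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
  }
  class(out) <- c("range_table", "data.frame")
  out
}
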