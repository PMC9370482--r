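#' Normalize a dual-channel trace to the ratiometric signal R
#'
#' Computes the fluorescence ratio `FR = F340 / F380` samplewise, the resting
#' baseline `FR0` as the mean of FR over the baseline window (before the
#' first indentation), and `R = FR / FR0`. R is independent of any joint
#' rescaling of the two channels (dye concentration, illumination).
#'
#' @param trace A `dual_channel_trace` (data frame with `time_s`, `f340`,
#'   `f380`).
#' @param baseline_end End of the baseline window (s); samples with
#'   `time_s < baseline_end` define FR0. Must contain at least 5 samples.
#' @return A data frame of class `ratiometric_trace` with columns `time_s`,
#'   `r`, and attribute `fr0`.
#' @export
normalize_ratio <- function(trace, baseline_end = 10) {
  if (any(trace$f380 <= 0) || any(trace$f340 <= 0))
    stop("non-positive fluorescence samples", call. = FALSE)
  base <- trace$time_s < baseline_end
  if (sum(base) < 5)
    stop("baseline window must contain at least 5 samples", call. = FALSE)
  fr <- trace$f340 / trace$f380
  fr0 <- mean(fr[base])
  out <- data.frame(time_s = trace$time_s, r = fr / fr0)
  attr(out, "fr0") <- fr0
  class(out) <- c("ratiometric_trace", "data.frame")
  out
}

# local maxima indices of a numeric vector (strict left, non-strict right)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# topographic prominence of peak at index i
peak_prominence <- function(x, i) {
  left <- x[seq_len(i - 1)]
  right <- x[seq(i + 1, length(x))]
  higher_l <- which(left > x[i])
  higher_r <- which(right > x[i])
  base_l <- if (length(higher_l)) min(left[seq(max(higher_l) + 1, i - 1)]) else min(left)
  base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1)]) else min(right)
  x[i] - max(base_l, base_r)
}

# intensity-weighted centroid time of a (positive) excursion within a window
centroid_time <- function(time, signal, lo, hi, baseline = 0) {
  idx <- lo:hi
  w <- pmax(signal[idx] - baseline, 0)
  if (sum(w) <= 0) return(mean(time[idx]))
  sum(time[idx] * w) / sum(w)
}

#' Find candidate activation transients in a ratiometric trace
#'
#' Structural detection, independent of the classification threshold:
#' local maxima of the smoothed R signal with topographic prominence of at
#' least `min_prominence` above baseline are taken as candidates; each is
#' expanded to its near-baseline width (at `R = 1 + 0.1 (peak - 1)`, a 10%
#' guard above baseline) and kept if the width reaches `min_width` and the
#' F340 peak and F380 dip coincide with the R peak within
#' `coincidence_tol` (channel extremum times are located by intensity-
#' weighted centroid over the event window, which is robust to frame noise).
#' Overlapping candidates are merged, keeping the highest.
#'
#' @param r A [normalize_ratio()] result.
#' @param trace The matching `dual_channel_trace`.
#' @param min_width Minimum width at baseline (s).
#' @param min_prominence Minimum prominence of the smoothed R peak above the
#'   surrounding signal.
#' @param coincidence_tol Maximum |time difference| (s) between the R peak
#'   and the channel peak/dip.
#' @param smooth_window_s Moving-average smoothing window (s) applied to R
#'   and the channels before peak analysis.
#' @return Data frame with one row per candidate: `peak_time_s`, `peak_r`
#'   (smoothed), `width_s`, `left_s`, `right_s`, `t_f340_s`, `t_f380_s`.
#' @export
find_candidate_events <- function(r, trace, min_width = 30,
                                  min_prominence = 0.2, coincidence_tol = 2,
                                  smooth_window_s = 4) {
  dt <- stats::median(diff(r$time_s))
  w <- samples_for(smooth_window_s, dt)
  rs <- moving_average(r$r, w)
  s340 <- moving_average(trace$f340, w)
  s380 <- moving_average(trace$f380, w)
  empty <- data.frame(peak_time_s = numeric(0), peak_r = numeric(0),
                      width_s = numeric(0), left_s = numeric(0),
                      right_s = numeric(0), t_f340_s = numeric(0),
                      t_f380_s = numeric(0))
  cand <- local_maxima(rs)
  cand <- cand[rs[cand] >= 1 + min_prominence]
  if (length(cand) == 0) return(empty)
  prom <- vapply(cand, function(i) peak_prominence(rs, i), numeric(1))
  cand <- cand[prom >= min_prominence]
  if (length(cand) == 0) return(empty)
  cand <- cand[order(rs[cand], decreasing = TRUE)]

  events <- empty
  claimed <- rep(FALSE, length(rs))
  for (i in cand) {
    if (claimed[i]) next
    level <- 1 + 0.1 * (rs[i] - 1)
    lo <- i; while (lo > 1 && rs[lo - 1] >= level) lo <- lo - 1
    hi <- i; while (hi < length(rs) && rs[hi + 1] >= level) hi <- hi + 1
    claimed[lo:hi] <- TRUE
    width <- r$time_s[hi] - r$time_s[lo]
    if (width < min_width) next
    t_peak <- centroid_time(r$time_s, rs, lo, hi, baseline = 1)
    t340 <- centroid_time(trace$time_s, s340, lo, hi,
                          baseline = min(s340[lo:hi]))
    t380 <- centroid_time(trace$time_s, -s380, lo, hi,
                          baseline = min(-s380[lo:hi]))
    if (abs(t340 - t_peak) > coincidence_tol) next
    if (abs(t380 - t_peak) > coincidence_tol) next
    events <- rbind(events, data.frame(
      peak_time_s = t_peak, peak_r = rs[i], width_s = width,
      left_s = r$time_s[lo], right_s = r$time_s[hi],
      t_f340_s = t340, t_f380_s = t380))
  }
  events[order(events$peak_time_s), , drop = FALSE]
}

#' Detect qualifying activation events above a threshold
#'
#' A candidate transient (see [find_candidate_events()]) qualifies as an
#' activation event when its smoothed peak R exceeds `r_threshold`. Events
#' at or after a detected rupture time are discarded.
#'
#' @inheritParams find_candidate_events
#' @param r_threshold Classification threshold R_T.
#' @param rupture_time Optional rupture time (s); events from this time on
#'   are dropped.
#' @return Data frame of events as in [find_candidate_events()].
#' @export
detect_activation_peaks <- function(r, trace, r_threshold, min_width = 30,
                                    min_prominence = 0.2, coincidence_tol = 2,
                                    rupture_time = NULL,
                                    smooth_window_s = 4) {
  if (r_threshold < 0) stop("r_threshold must be >= 0", call. = FALSE)
  if (!is.null(rupture_time) && !is.na(rupture_time)) {
    # analyse only the pre-rupture record (with a small guard before the
    # drop) so the dual-channel collapse cannot bias peak/dip localisation
    keep <- trace$time_s < rupture_time - 2.5
    trace <- trace[keep, , drop = FALSE]
    r <- r[keep, , drop = FALSE]
  }
  ev <- find_candidate_events(r, trace, min_width, min_prominence,
                              coincidence_tol, smooth_window_s)
  ev <- ev[ev$peak_r > r_threshold, , drop = FALSE]
  if (!is.null(rupture_time) && !is.na(rupture_time))
    ev <- ev[ev$peak_time_s < rupture_time, , drop = FALSE]
  ev
}

#' Detect membrane rupture in a dual-channel trace
#'
#' Rupture shows as a rapid simultaneous decrease of both channels (the dye
#' diffuses out) followed by a flat ratio. The detector returns the earliest
#' time at which both smoothed channels drop by at least `drop_fraction`
#' within `drop_window_s`, and the ratio R is flat (SD below `flat_sd`) over
#' the following `flat_window_s`. A single-channel drop (e.g. the F380 dip
#' of an activation transient) is not rupture.
#'
#' @param trace A `dual_channel_trace`.
#' @param r Optional matching [normalize_ratio()] result (recomputed if
#'   missing).
#' @param drop_fraction Minimum relative drop of both channels.
#' @param drop_window_s Window (s) over which the drop must occur.
#' @param flat_window_s Length (s) of the trailing-record window over which
#'   R must be flat after the drop.
#' @param flat_sd Maximum SD of R over the flatness window.
#' @param smooth_window_s Channel smoothing window (s).
#' @return Rupture time (s, midpoint of the drop window) or `NA` if none.
#' @export
detect_rupture <- function(trace, r = NULL, drop_fraction = 0.5,
                           drop_window_s = 5, flat_window_s = 20,
                           flat_sd = 0.05, smooth_window_s = 2) {
  if (is.null(r)) r <- normalize_ratio(trace)
  dt <- stats::median(diff(trace$time_s))
  w <- samples_for(smooth_window_s, dt)
  s340 <- moving_average(trace$f340, w)
  s380 <- moving_average(trace$f380, w)
  lag <- max(1L, round(drop_window_s / dt))
  n <- length(s340)
  if (n <= lag) return(NA_real_)
  i <- seq_len(n - lag)
  dropped <- s340[i + lag] / s340[i] <= 1 - drop_fraction &
    s380[i + lag] / s380[i] <= 1 - drop_fraction
  t_max <- max(trace$time_s)
  for (idx in which(dropped)) {
    t_end <- trace$time_s[idx + lag]
    # flatness is judged on the trailing end of the record: once the dye has
    # diffused out, R stays flat, even if an ongoing transient was truncated
    flat_start <- max(t_end, t_max - flat_window_s)
    flat <- r$r[trace$time_s > flat_start]
    if (length(flat) >= 5 && stats::sd(flat) < flat_sd)
      return(trace$time_s[idx] + drop_window_s / 2)
  }
  NA_real_
}

#' Classify one cell as responsive or unresponsive
#'
#' A cell is responsive when at least one qualifying activation event occurs
#' before membrane rupture. The first event is assigned to the most recent
#' indentation whose start precedes the event peak and whose window (down
#' and up travel plus the dwell) contains it; the cell's activation depth is
#' that step's indentation depth.
#'
#' @param trace A `dual_channel_trace`.
#' @param train An [build_train()] indentation train covering the trace.
#' @param depths A [depth_map()] for the train (or `tmax_mean` to build one).
#' @param r_threshold Classification threshold R_T.
#' @param tmax_mean Average maximal cell thickness (um), used when `depths`
#'   is missing.
#' @param baseline_end Baseline window end (s) for [normalize_ratio()].
#' @param ... Further arguments passed to [detect_activation_peaks()].
#' @return One-row data frame: `cell_id`, `group`, `responsive`,
#'   `activation_index`, `activation_delta_um`, `activation_time_s`,
#'   `peak_r` (first event), `max_peak_r` (largest event), `rupture_time_s`.
#' @export
classify_cell <- function(trace, train, depths = NULL, r_threshold = 2.5,
                          tmax_mean = NULL, baseline_end = 10, ...) {
  if (is.null(depths)) {
    if (is.null(tmax_mean))
      stop("supply either a depth map or tmax_mean", call. = FALSE)
    depths <- depth_map(train, tmax_mean)
  }
  r <- normalize_ratio(trace, baseline_end)
  rupture <- detect_rupture(trace, r)
  events <- detect_activation_peaks(r, trace, r_threshold,
                                    rupture_time = rupture, ...)
  cfg <- attr(train, "config")
  responsive <- nrow(events) > 0
  act_idx <- NA_integer_; act_delta <- NA_real_
  act_time <- NA_real_; peak_r <- NA_real_
  max_peak <- if (responsive) max(events$peak_r) else NA_real_
  if (responsive) {
    ev <- events[1, ]
    act_time <- ev$peak_time_s
    peak_r <- ev$peak_r
    window_ok <- train$t_start_s <= act_time &
      act_time <= train$t_start_s + 2 * train$dt_s + cfg$dwell
    if (any(window_ok)) {
      act_idx <- max(train$index[window_ok])
      act_delta <- depths$delta_um[match(act_idx, depths$index)]
    } else {
      warning("activation event at t = ", round(act_time, 1),
              " s not attributable to any indentation window", call. = FALSE)
    }
  }
  data.frame(cell_id = attr(trace, "cell_id") %||% NA_character_,
             group = attr(trace, "group") %||% NA_character_,
             responsive = responsive,
             activation_index = act_idx,
             activation_delta_um = act_delta,
             activation_time_s = act_time,
             peak_r = peak_r,
             max_peak_r = max_peak,
             rupture_time_s = rupture)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify every cell of a cohort
#'
#' @param traces A `trace_cohort` or list of `dual_channel_trace` objects.
#' @inheritParams classify_cell
#' @return Data frame with one row per cell (see [classify_cell()]).
#' @export
classify_cohort <- function(traces, train, depths = NULL, r_threshold = 2.5,
                            tmax_mean = NULL, ...) {
  out <- do.call(rbind, lapply(traces, classify_cell, train = train,
                               depths = depths, r_threshold = r_threshold,
                               tmax_mean = tmax_mean, ...))
  rownames(out) <- NULL
  out
}
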