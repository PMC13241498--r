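#' Preprocess a raw respiration trace
#'
#' Band-pass filters the signal with a third-order Butterworth filter
#' (high-pass 0.03 Hz, low-pass 6 Hz), applied forward and backward
#' (zero-phase) so that respiration phase is not distorted, resamples to
#' `fs_out`, and converts to z-scores over the whole recording.
#'
#' @param trace Data frame with columns `time_s` and `value`, uniformly
#'   sampled.
#' @param fs_out Output sampling rate, Hz (default 100).
#' @param highpass,lowpass Band edges, Hz.
#' @return Tibble `(time_s, value)` at `fs_out` Hz, mean 0 and SD 1.
#' @export
#' @examples
#' raw <- tibble::tibble(time_s = seq(0, 60, by = 0.01),
#'                       value = sin(2 * pi * 0.25 * seq(0, 60, by = 0.01)))
#' clean <- preprocess_respiration(raw)
#' c(mean(clean$value), sd(clean$value))
preprocess_respiration <- function(trace, fs_out = 100, highpass = 0.03, lowpass = 6) {
  check_trace(trace)
  fs_in <- trace_fs(trace)
  v <- trace$value
  if (any(is.na(v))) abort("respiration trace contains missing samples")
  if (sd(v) < 1e-12) abort("signal has no variance; cannot z-score")
  v <- v - mean(v) # avoid a step response of the slow high-pass
  nyq <- fs_in / 2
  if (lowpass < nyq) {
    v <- signal::filtfilt(signal::butter(3, lowpass / nyq, type = "low"), v)
  }
  v <- signal::filtfilt(signal::butter(3, highpass / nyq, type = "high"), v)
  t_out <- seq(trace$time_s[1], trace$time_s[length(v)], by = 1 / fs_out)
  v <- approx(trace$time_s, v, xout = t_out)$y
  s <- sd(v)
  if (!is.finite(s) || s < 1e-12) abort("signal has no variance after filtering; cannot z-score")
  tibble(time_s = t_out, value = (v - mean(v)) / s)
}

#' Detect respiration cycles from a cleaned trace
#'
#' Local maxima of the z-scored signal exceeding `peak_threshold` (z = 0.5)
#' become inhalation peaks; maxima closer than `min_separation` to a larger
#' one are suppressed. Each cycle spans trough-to-trough around its peak:
#' the inspiration onset is the signal minimum before the peak and the
#' expiration end the minimum after it. A fixed-length waveform snippet
#' (`window` s centred on the peak, edge-padded with `NA`) is stored for
#' atypical-cycle scoring. Near-zero-slope plateaus (breathing pauses,
#' where phase is ill-defined) are detected and recorded as an attribute
#' `"pauses"`; [assign_phase()] leaves them unassigned.
#'
#' @param clean Z-scored trace from [preprocess_respiration()].
#' @param peak_threshold Minimum peak height in SD units.
#' @param min_separation Minimum peak spacing, seconds.
#' @param window Waveform snippet length, seconds.
#' @param pause_slope_frac Fraction of the cycle's maximum absolute slope
#'   below which a sample counts as plateau.
#' @param pause_min_duration Minimum plateau duration to classify as a
#'   pause, seconds.
#' @return Tibble with columns `peak_time`, `inspiration_onset`,
#'   `expiration_end`, `duration`, `is_atypical` (all `FALSE` here) and the
#'   list-column `waveform`; attribute `"pauses"` holds a tibble of pause
#'   intervals `(start, end)`. Zero rows if no peak exceeds the threshold.
#' @export
detect_cycles <- function(clean, peak_threshold = 0.5, min_separation = 1.5,
                          window = 7, pause_slope_frac = 0.05,
                          pause_min_duration = 0.25) {
  check_trace(clean)
  fs <- trace_fs(clean)
  v <- clean$value
  t <- clean$time_s
  n <- length(v)
  empty <- tibble(peak_time = numeric(), inspiration_onset = numeric(),
                  expiration_end = numeric(), duration = numeric(),
                  is_atypical = logical(), waveform = list())
  attr(empty, "pauses") <- tibble(start = numeric(), end = numeric())

  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  cand <- which(is_max & v > peak_threshold)
  if (length(cand) == 0) return(empty)

  # greedy suppression: keep the larger of any pair closer than min_separation
  cand <- cand[order(v[cand], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(t[i] - t[kept]) >= min_separation)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  peaks <- refine_extremum(t, v, kept, fs)

  # troughs: minimum between consecutive peaks (and before first / after last)
  bounds <- c(1L, kept, n)
  trough_idx <- map_int(seq_len(length(kept) + 1), function(j) {
    lo <- bounds[j]; hi <- bounds[j + 1]
    lo + which.min(v[lo:hi]) - 1L
  })
  onset <- refine_extremum(t, v, trough_idx[seq_along(kept)], fs)
  end <- refine_extremum(t, v, trough_idx[seq_along(kept) + 1], fs)
  onset <- pmin(onset, peaks - 1 / fs)
  end <- pmax(end, peaks + 1 / fs)

  half <- round(window / 2 * fs)
  waveforms <- map(kept, function(i) {
    idx <- (i - half):(i + half)
    w <- rep(NA_real_, length(idx))
    ok <- idx >= 1 & idx <= n
    w[ok] <- v[idx[ok]]
    w
  })

  cycles <- tibble(peak_time = peaks, inspiration_onset = onset,
                   expiration_end = end, duration = end - onset,
                   is_atypical = FALSE, waveform = waveforms)
  attr(cycles, "pauses") <- detect_pauses(t, v, cycles, fs, pause_slope_frac,
                                          pause_min_duration)
  cycles
}

# Sub-sample extremum localisation: a local quadratic fit around each
# candidate sample suppresses residual noise jitter at the flat top of a
# breath, where the raw argmax wanders.
refine_extremum <- function(t, v, idx, fs, half_s = 0.35) {
  half <- max(2L, round(half_s * fs))
  n <- length(v)
  map_dbl(idx, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    x <- t[lo:hi] - t[i]; y <- v[lo:hi]
    fit <- stats::lm.fit(cbind(1, x, x^2), y)
    a2 <- fit$coefficients[3]; a1 <- fit$coefficients[2]
    if (!is.finite(a2) || a2 == 0) return(t[i])
    vertex <- -a1 / (2 * a2)
    if (abs(vertex) > half_s) return(t[i])
    t[i] + vertex
  })
}

# Plateau (breathing-pause) intervals: runs where |slope| stays below
# pause_slope_frac of the cycle's own peak slope for longer than
# pause_min_duration, inside a cycle but away from the peak/trough samples
# themselves being the only reason for a small slope is handled by the run
# length requirement.
detect_pauses <- function(t, v, cycles, fs, slope_frac, min_dur) {
  out <- list()
  slope <- c(0, diff(v)) * fs
  for (k in seq_len(nrow(cycles))) {
    i0 <- which.min(abs(t - cycles$inspiration_onset[k]))
    i1 <- which.min(abs(t - cycles$expiration_end[k]))
    if (i1 <= i0) next
    s <- abs(slope[i0:i1])
    thr <- slope_frac * max(s)
    r <- rle(s < thr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values & r$lengths / fs > min_dur)) {
      out[[length(out) + 1]] <- c(t[i0 + starts[j] - 1], t[i0 + ends[j] - 1])
    }
  }
  if (length(out) == 0) return(tibble(start = numeric(), end = numeric()))
  m <- do.call(rbind, out)
  tibble(start = m[, 1], end = m[, 2])
}

#' Reject atypical respiration cycles
#'
#' Scores each cycle by the mean squared distance of its fixed-length
#' waveform to the centroid (pointwise mean) of all waveforms, excluding
#' edge-padded missing samples pairwise. Cycles whose score exceeds the
#' across-cycle mean by more than three standard deviations are flagged
#' `is_atypical` and excluded from phase assignment.
#'
#' @param cycles Cycle table from [detect_cycles()].
#' @param n_sd Rejection threshold in SDs of the score distribution.
#' @return The cycle table with `is_atypical` updated (attributes kept).
#'   With fewer than 5 cycles the table is passed through with a warning.
#' @export
reject_atypical_cycles <- function(cycles, n_sd = 3) {
  if (nrow(cycles) < 5) {
    warn("fewer than 5 cycles; atypical-cycle rejection skipped")
    return(cycles)
  }
  w <- do.call(rbind, cycles$waveform)
  centroid <- colMeans(w, na.rm = TRUE)
  score <- rowMeans((w - matrix(centroid, nrow(w), ncol(w), byrow = TRUE))^2,
                    na.rm = TRUE)
  s <- sd(score)
  thr <- mean(score) + n_sd * s
  flag <- if (is.finite(s) && s > 0) score > thr else rep(FALSE, length(score))
  cycles$is_atypical <- flag
  cycles
}

#' Assign linear respiration phase to each sample
#'
#' Within each kept (non-atypical) cycle the phase is a linear function of
#' time anchored at the physiologically meaningful reference points: 0 at
#' the inhalation peak and pi at the exhalation trough. The descending
#' (expiration) half maps onto `[0, pi)` and the ascending (inspiration)
#' half onto `[pi, 2*pi)`. Samples inside breathing-pause plateaus, inside
#' atypical cycles, or outside any cycle remain unassigned (`NA`).
#'
#' @param clean Z-scored trace from [preprocess_respiration()].
#' @param cycles Cycle table from [detect_cycles()] /
#'   [reject_atypical_cycles()].
#' @return Tibble `(time_s, phase)` on the same grid as `clean`, with
#'   `phase` in `[0, 2*pi)` or `NA` where unassigned.
#' @export
assign_phase <- function(clean, cycles) {
  check_trace(clean)
  t <- clean$time_s
  phase <- rep(NA_real_, length(t))
  kept <- cycles[!cycles$is_atypical, , drop = FALSE]
  for (k in seq_len(nrow(kept))) {
    pk <- kept$peak_time[k]; on <- kept$inspiration_onset[k]; en <- kept$expiration_end[k]
    if (on < pk) {
      i <- t >= on & t < pk
      phase[i] <- pi + pi * (t[i] - on) / (pk - on)
    }
    if (en > pk) {
      i <- t >= pk & t <= en
      phase[i] <- pi * (t[i] - pk) / (en - pk)
    }
  }
  pauses <- attr(cycles, "pauses")
  if (!is.null(pauses) && nrow(pauses) > 0) {
    for (k in seq_len(nrow(pauses))) {
      phase[t >= pauses$start[k] & t <= pauses$end[k]] <- NA_real_
    }
  }
  tibble(time_s = t, phase = wrap_phase(phase))
}

#' Respiration frequency preceding events
#'
#' For each event time, the mean instantaneous frequency (1/duration) of
#' the last `n_cycles` completed, non-atypical cycles whose peak precedes
#' the event.
#'
#' @param event_times Numeric vector of event times, seconds.
#' @param cycles Cycle table from [detect_cycles()].
#' @param n_cycles Number of preceding cycles to average (default 2).
#' @return Numeric vector of frequencies in Hz; `NA` where fewer than
#'   `n_cycles` cycles precede the event.
#' @export
#' @examples
#' cyc <- tibble::tibble(peak_time = c(2, 6), inspiration_onset = c(0, 4),
#'                       expiration_end = c(4, 8), duration = c(4, 4),
#'                       is_atypical = FALSE, waveform = list(NULL, NULL))
#' respiration_frequency_before(10, cyc) # 0.25 Hz
respiration_frequency_before <- function(event_times, cycles, n_cycles = 2) {
  kept <- cycles[!cycles$is_atypical & cycles$duration > 0, , drop = FALSE]
  map_dbl(event_times, function(te) {
    prior <- kept$duration[kept$peak_time < te]
    if (length(prior) < n_cycles) return(NA_real_)
    mean(1 / tail(prior, n_cycles))
  })
}

#' Full respiration preprocessing chain
#'
#' Convenience wrapper: filter + z-score, cycle detection, atypical-cycle
#' rejection, and phase assignment.
#'
#' @param trace Raw respiration trace `(time_s, value)`.
#' @param ... Passed to [detect_cycles()].
#' @return List with `clean` (trace), `cycles`, and `phase`.
#' @export
respiration_pipeline <- function(trace, ...) {
  clean <- preprocess_respiration(trace)
  cycles <- reject_atypical_cycles(detect_cycles(clean, ...))
  list(clean = clean, cycles = cycles, phase = assign_phase(clean, cycles))
}

# --- internal trace helpers -------------------------------------------------

check_trace <- function(trace) {
  if (!is.data.frame(trace) || !all(c("time_s", "value") %in% names(trace))) {
    abort("expected a data frame with columns time_s and value")
  }
  if (nrow(trace) < 2) abort("trace must contain at least 2 samples")
  invisible(trace)
}

trace_fs <- function(trace) {
  dt <- median(diff(trace$time_s))
  if (!is.finite(dt) || dt <= 0) abort("time_s must be strictly increasing")
  1 / dt
}
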