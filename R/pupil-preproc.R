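#' Interpolate blink gaps in a pupil trace
#'
#' Missing runs (blinks) are first extended by a guard margin on each side —
#' eyelid-closure ramps contaminate neighbouring samples — and then replaced
#' by linear interpolation between the flanking valid samples. Leading and
#' trailing missing runs are filled with the nearest valid value.
#'
#' @param trace Data frame `(time_s, value)`; blinks are `NA` values.
#' @param guard Guard margin, seconds (default 0.1).
#' @return Tibble `(time_s, value)` with no missing samples.
#' @export
#' @examples
#' tr <- tibble::tibble(time_s = 0:2, value = c(1, NA, 3))
#' interpolate_blinks(tr, guard = 0)$value
interpolate_blinks <- function(trace, guard = 0.1) {
  check_trace(trace)
  v <- trace$value
  if (all(is.na(v))) abort("trace is entirely missing; nothing to interpolate")
  fs <- trace_fs(trace)
  pad <- round(guard * fs)
  miss <- is.na(v)
  if (pad > 0 && any(miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      lo <- max(1, starts[j] - pad); hi <- min(length(v), ends[j] + pad)
      miss[lo:hi] <- TRUE
    }
    v[miss] <- NA_real_
  }
  if (any(is.na(v))) {
    ok <- which(!is.na(v))
    v <- approx(trace$time_s[ok], v[ok], xout = trace$time_s, rule = 2)$y
  }
  tibble(time_s = trace$time_s, value = v)
}

#' Remove slow exponential drift from a pupil trace
#'
#' Fits `a * exp(b * t) + c` by least squares over the whole recording and
#' subtracts the fit. If the nonlinear fit does not converge, falls back to
#' a linear detrend with a warning.
#'
#' @param trace Blink-free trace `(time_s, value)`.
#' @return Tibble `(time_s, value)` of residuals; the fit parameters are
#'   attached as attribute `"fit"` (named vector `a`, `b`, `c`, plus
#'   `method`).
#' @export
detrend_exponential <- function(trace) {
  check_trace(trace)
  t <- trace$time_s - trace$time_s[1]
  v <- trace$value
  if (any(is.na(v))) abort("detrending requires a blink-free (interpolated) trace")
  # The model is linear in (a, c) given b, so profile the sum of squares
  # over the decay rate alone: always converges, no start values needed.
  span <- max(t[length(t)], 1)
  profile_fit <- function(b) {
    basis <- exp(b * t)
    stats::lm.fit(cbind(basis, 1), v)
  }
  sse <- function(b) sum(profile_fit(b)$residuals^2)
  opt <- tryCatch(
    stats::optimize(sse, interval = c(-20 / span, 2 / span), tol = 1e-12),
    error = function(e) NULL
  )
  if (!is.null(opt)) {
    b_hat <- opt$minimum
    pf <- profile_fit(b_hat)
    pars <- c(a = unname(pf$coefficients[1]), b = b_hat,
              c = unname(pf$coefficients[2]))
    trend <- pars[["a"]] * exp(pars[["b"]] * t) + pars[["c"]]
    method <- "exponential"
  } else {
    warn("exponential detrend did not converge; falling back to linear detrend")
    lf <- lm(v ~ t)
    trend <- unname(predict(lf))
    pars <- c(a = unname(coef(lf)[2]), b = 0, c = unname(coef(lf)[1]))
    method <- "linear"
  }
  out <- tibble(time_s = trace$time_s, value = v - trend)
  attr(out, "fit") <- c(as.list(pars), method = method)
  out
}

#' Low-pass filter, resample, and z-score a pupil trace
#'
#' Zero-phase third-order Butterworth low-pass at `lowpass` Hz, resampling
#' to `fs_out`, then z-scoring within the recording (the within-participant
#' normalisation used by all downstream models).
#'
#' @param trace Detrended trace `(time_s, value)`.
#' @param lowpass Cutoff frequency, Hz (default 8).
#' @param fs_out Output sampling rate, Hz (default 100).
#' @return Tibble `(time_s, value)` at `fs_out` Hz with mean 0, SD 1.
#' @export
filter_and_resample <- function(trace, lowpass = 8, fs_out = 100) {
  check_trace(trace)
  fs_in <- trace_fs(trace)
  v <- trace$value
  if (any(is.na(v))) abort("filtering requires a blink-free (interpolated) trace")
  nyq <- fs_in / 2
  if (lowpass < nyq) {
    v <- signal::filtfilt(signal::butter(3, lowpass / nyq, type = "low"), v)
  }
  t_out <- seq(trace$time_s[1], trace$time_s[length(v)], by = 1 / fs_out)
  v <- approx(trace$time_s, v, xout = t_out)$y
  s <- sd(v)
  if (!is.finite(s) || s < 1e-12) abort("signal has no variance; cannot z-score")
  tibble(time_s = t_out, value = (v - mean(v)) / s)
}

#' Full pupil preprocessing chain
#'
#' Interpolate blinks, remove exponential drift, low-pass filter, resample
#' and z-score, in that order.
#'
#' @param trace Raw pupil trace `(time_s, value)` with `NA` blinks.
#' @param guard Blink guard margin, seconds.
#' @param lowpass Low-pass cutoff, Hz.
#' @param fs_out Output rate, Hz.
#' @return Cleaned z-scored tibble `(time_s, value)`.
#' @export
pupil_pipeline <- function(trace, guard = 0.1, lowpass = 8, fs_out = 100) {
  trace |>
    interpolate_blinks(guard = guard) |>
    detrend_exponential() |>
    filter_and_resample(lowpass = lowpass, fs_out = fs_out)
}

#' Cut event-locked epochs from a continuous series
#'
#' Extracts rows of samples on a fixed time grid (default -4 to +4 s at
#' 100 Hz, 801 samples) around each event. Events whose window is not fully
#' inside the recording are dropped and counted. Works for both pupil
#' traces (column `value`) and phase series (column `phase`; unassigned
#' samples are carried through as `NA`).
#'
#' @param series Data frame with `time_s` and either `value` or `phase`.
#' @param event_times Numeric vector of event times, seconds.
#' @param half_window Half window length, seconds (default 4).
#' @param fs Grid rate, Hz (default 100; the series must be sampled at this
#'   rate).
#' @return An object of class `epoch_set`: list with `data` (events x time
#'   matrix), `time_s` (grid of lags), `event_times` (kept events),
#'   `dropped` (count), and `kind` (`"value"` or `"phase"`).
#' @export
epoch_around_events <- function(series, event_times,
                                half_window = EPOCH_HALF_WINDOW, fs = EPOCH_FS) {
  kind <- if ("phase" %in% names(series)) "phase" else "value"
  if (!all(c("time_s", kind) %in% names(series))) {
    abort("expected a data frame with time_s and a value or phase column")
  }
  v <- series[[kind]]
  t0 <- series$time_s[1]
  n <- length(v)
  offsets <- round(seq(-half_window, half_window, by = 1 / fs) * fs)
  center <- round((event_times - t0) * fs) + 1
  ok <- center + offsets[1] >= 1 & center + offsets[length(offsets)] <= n
  if (!any(ok)) abort("no event has a full window inside the recording")
  idx <- outer(center[ok], offsets, `+`)
  structure(
    list(data = matrix(v[idx], nrow = sum(ok)),
         time_s = offsets / fs,
         event_times = event_times[ok],
         dropped = sum(!ok),
         kind = kind),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epoch(s) x %d timepoint(s) (%s), %d event(s) dropped at edges\n",
              nrow(x$data), ncol(x$data), x$kind, x$dropped))
  invisible(x)
}

#' @rdname epoch_around_events
#' @param x An `epoch_set`.
#' @param ... Unused.
#' @export
tidy.epoch_set <- function(x, ...) {
  tibble(
    event = rep(seq_len(nrow(x$data)), times = ncol(x$data)),
    time_s = rep(x$time_s, each = nrow(x$data)),
    value = as.vector(x$data)
  )
}

#' Event-locked average of an epoch set
#'
#' @param epochs An `epoch_set` (of kind `"value"`).
#' @return Tibble `(time_s, mean, sem, n)`.
#' @export
epoch_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  m <- epochs$data
  n <- colSums(!is.na(m))
  tibble(time_s = epochs$time_s,
         mean = colMeans(m, na.rm = TRUE),
         sem = apply(m, 2, sd, na.rm = TRUE) / sqrt(pmax(n, 1)),
         n = n)
}
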