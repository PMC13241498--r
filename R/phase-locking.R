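#' Time-resolved phase-locking value
#'
#' For each epoch timepoint, the length of the mean resultant vector of the
#' unit phase vectors across epochs:
#' `PLV(t) = |1/N * sum_i exp(1i * phi_i(t))|`.
#' Epochs with unassigned phase at a timepoint are excluded there;
#' timepoints with fewer than `min_epochs` assigned epochs yield `NA`. The
#' PLV is biased upward at small epoch counts (expected value
#' `sqrt(pi)/2/sqrt(N)` under uniform phases), which is why [ppc_timecourse()]
#' is reported alongside as an unbiased effect size.
#'
#' @param epochs An [epoch_around_events()] result holding phases.
#' @param min_epochs Minimum assigned epochs per timepoint (default 2).
#' @return Object of class `plv_result`: tibble `(time_s, plv, n)`.
#' @export
plv_timecourse <- function(epochs, min_epochs = 2) {
  stopifnot(inherits(epochs, "epoch_set"))
  ph <- epochs$data
  n <- as.integer(colSums(!is.na(ph)))
  re <- colMeans(cos(ph), na.rm = TRUE)
  im <- colMeans(sin(ph), na.rm = TRUE)
  plv <- sqrt(re^2 + im^2)
  plv[n < min_epochs] <- NA_real_
  structure(tibble(time_s = epochs$time_s, plv = plv, n = n),
            class = c("plv_result", "tbl_df", "tbl", "data.frame"))
}

#' Time-resolved pairwise phase consistency
#'
#' The mean cosine of phase differences over all unordered epoch pairs:
#' `PPC(t) = 2/(n(n-1)) * sum_{i<j} cos(theta_i(t) - theta_j(t))`.
#' Computed through the algebraic identity
#' `PPC = (n * PLV^2 - 1)/(n - 1)`, which equals the pairwise sum exactly
#' but costs O(n) per timepoint. Unlike the PLV, the PPC is unbiased in the
#' number of epochs (expected 0 under uniform phases) and can be compared
#' across datasets as an effect size.
#'
#' @inheritParams plv_timecourse
#' @return Object of class `ppc_result`: tibble `(time_s, ppc, n)`.
#' @export
ppc_timecourse <- function(epochs, min_epochs = 2) {
  plv <- plv_timecourse(epochs, min_epochs = min_epochs)
  ppc <- (plv$n * plv$plv^2 - 1) / (plv$n - 1)
  ppc[plv$n < min_epochs] <- NA_real_
  structure(tibble(time_s = plv$time_s, ppc = ppc, n = plv$n),
            class = c("ppc_result", "tbl_df", "tbl", "data.frame"))
}

#' Epoch-averaged (circular mean) phase time course
#'
#' The argument of the epoch-mean resultant vector at each timepoint, in
#' `[0, 2*pi)` — one participant's average respiration phase around the
#' event.
#'
#' @inheritParams plv_timecourse
#' @return Tibble `(time_s, mean_phase, n)`.
#' @export
participant_mean_phase <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  ph <- epochs$data
  n <- colSums(!is.na(ph))
  mp <- wrap_phase(atan2(colMeans(sin(ph), na.rm = TRUE),
                         colMeans(cos(ph), na.rm = TRUE)))
  mp[n < 1] <- NA_real_
  tibble(time_s = epochs$time_s, mean_phase = mp, n = n)
}

#' Group-level PLV test against a circular-shift surrogate null
#'
#' Computes the within-participant PLV time course around each
#' participant's events and the group average, then builds a null
#' distribution by circularly shifting each participant's continuous phase
#' series by an independent uniform offset, re-cutting epochs at the
#' original event times, and recording the *maximum* of the group-average
#' PLV over the whole grid on each iteration (maximum-statistic correction
#' for multiple comparisons over time). The 95th and 99th percentiles of
#' the maxima give the p < 0.05 and p < 0.01 thresholds; windows where the
#' observed group PLV exceeds them are reported.
#'
#' Internally the shift-and-re-epoch loop is evaluated through one FFT
#' cross-correlation of the complex phase series with the event indicator
#' per participant, which gives the resultant sums at every possible shift
#' at once; this is numerically identical to explicit shifting.
#'
#' @param data Nested tibble with one row per participant and list-columns
#'   `phase` (tibbles `(time_s, phase)`) and `events` (numeric vectors of
#'   event times, or tibbles with a `time_s` column).
#' @param n_shifts Number of surrogate iterations (default 4000).
#' @param half_window,fs Epoch grid (default +-4 s at 100 Hz).
#' @param min_epochs Minimum assigned epochs per participant per timepoint.
#' @return Object of class `plv_surrogate`: list with `group` (tibble
#'   `time_s, plv_mean, plv_sem, n_participants`), `participant_plv`
#'   (participants x time matrix), `thresholds` (named: `p05`, `p01`),
#'   `windows` (tibble `level, start, end`), `null_maxima`, `n_shifts`.
#' @export
plv_surrogate_test <- function(data, n_shifts = 4000,
                               half_window = EPOCH_HALF_WINDOW, fs = EPOCH_FS,
                               min_epochs = 2) {
  stopifnot(is.data.frame(data), all(c("phase", "events") %in% names(data)))
  if (n_shifts < 1) abort("n_shifts must be >= 1")
  grid <- round(seq(-half_window, half_window, by = 1 / fs) * fs)
  n_t <- length(grid)

  prep <- map(seq_len(nrow(data)), function(i) {
    ph <- data$phase[[i]]
    ev <- data$events[[i]]
    if (is.data.frame(ev)) ev <- ev$time_s
    L <- nrow(ph)
    t0 <- ph$time_s[1]
    e <- round((ev - t0) * fs) + 1
    e <- e[e + grid[1] >= 1 & e + grid[n_t] <= L]
    if (length(e) < min_epochs) return(NULL)
    z <- exp(1i * ph$phase)
    z[is.na(z)] <- 0 + 0i
    a <- as.numeric(!is.na(ph$phase))
    ind <- numeric(L)
    for (j in e) ind[j] <- ind[j] + 1
    find <- Conj(fft(ind))
    # S[l] = sum_j z[e_j + l], A[l] = sum_j assigned[e_j + l], lags 0..L-1
    S <- fft(fft(z) * find, inverse = TRUE) / L
    A <- round(Re(fft(fft(a + 0i) * find, inverse = TRUE) / L))
    list(S = S, A = A, L = L)
  })
  prep <- prep[!map_lgl(prep, is.null)]
  if (length(prep) == 0) abort("no participant has enough usable events")

  plv_at_shift <- function(p, shift) {
    idx <- ((shift + grid) %% p$L) + 1
    n <- p$A[idx]
    out <- Mod(p$S[idx]) / n
    out[n < min_epochs] <- NA_real_
    out
  }

  obs <- do.call(rbind, map(prep, plv_at_shift, shift = 0))
  group <- colMeans(obs, na.rm = TRUE)
  group_sem <- apply(obs, 2, sd, na.rm = TRUE) / sqrt(colSums(!is.na(obs)))

  maxima <- map_dbl(seq_len(n_shifts), function(k) {
    g <- colMeans(do.call(rbind, map(prep, function(p) {
      plv_at_shift(p, sample.int(p$L, 1) - 1)
    })), na.rm = TRUE)
    max(g, na.rm = TRUE)
  })
  thr <- quantile(maxima, c(0.95, 0.99), names = FALSE)

  time_s <- grid / fs
  windows <- bind_rows(
    runs_to_windows(group > thr[1], time_s, "p<0.05"),
    runs_to_windows(group > thr[2], time_s, "p<0.01")
  )
  structure(
    list(group = tibble(time_s = time_s, plv_mean = group, plv_sem = group_sem,
                        n_participants = colSums(!is.na(obs))),
         participant_plv = obs,
         thresholds = c(p05 = thr[1], p01 = thr[2]),
         windows = windows,
         null_maxima = maxima,
         n_shifts = n_shifts),
    class = "plv_surrogate"
  )
}

# contiguous TRUE runs -> (level, start, end) rows
runs_to_windows <- function(flag, time_s, level) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (length(keep) == 0) {
    return(tibble(level = character(), start = numeric(), end = numeric()))
  }
  tibble(level = level, start = time_s[starts[keep]], end = time_s[ends[keep]])
}

#' @export
print.plv_surrogate <- function(x, ...) {
  cat(sprintf("<plv_surrogate> %d participant(s), %d surrogate shift(s)\n",
              nrow(x$participant_plv), x$n_shifts))
  cat(sprintf("  thresholds: p<0.05 at %.4f, p<0.01 at %.4f; observed max %.4f\n",
              x$thresholds[["p05"]], x$thresholds[["p01"]],
              max(x$group$plv_mean, na.rm = TRUE)))
  if (nrow(x$windows) > 0) {
    for (i in seq_len(nrow(x$windows))) {
      cat(sprintf("  %s window: %.2f to %.2f s\n", x$windows$level[i],
                  x$windows$start[i], x$windows$end[i]))
    }
  } else cat("  no suprathreshold windows\n")
  invisible(x)
}

#' @rdname plv_surrogate_test
#' @param x A `plv_surrogate` object.
#' @param ... Unused.
#' @export
tidy.plv_surrogate <- function(x, ...) x$group

#' @rdname plv_surrogate_test
#' @export
glance.plv_surrogate <- function(x, ...) {
  tibble(n_participants = nrow(x$participant_plv),
         n_shifts = x$n_shifts,
         threshold_p05 = x$thresholds[["p05"]],
         threshold_p01 = x$thresholds[["p01"]],
         max_group_plv = max(x$group$plv_mean, na.rm = TRUE),
         n_windows_p05 = sum(x$windows$level == "p<0.05"),
         n_windows_p01 = sum(x$windows$level == "p<0.01"))
}
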