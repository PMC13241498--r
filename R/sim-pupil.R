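#' Simulate a pupil-size trace
#'
#' The trace is the sum of (i) a slow exponential baseline drift
#' `a*exp(b*t) + c`, (ii) one biphasic kernel per reversal event — a
#' Gaussian constriction lobe centred before the report and a Gaussian
#' dilation lobe after it, (iii) a cosine modulation by respiration phase
#' with amplitude `pupil_resp_gain` (largest at peak inhalation, i.e.
#' expiration onset; smallest at the exhalation trough, i.e. inspiration
#' onset), and (iv) white noise. Blinks are inserted as runs of `NA` at
#' `blink_rate` per minute with lognormal durations.
#'
#' @param config A [sim_config()].
#' @param events Reversal events from [simulate_reversals()] (or any tibble
#'   with a `time_s` column); may have zero rows.
#' @param resp Ground-truth respiration object or `(time_s, phase)` tibble;
#'   used for the respiratory modulation.
#' @param participant Participant index (random stream).
#' @return Tibble `(time_s, value)` at `config$fs` Hz; blink samples are `NA`.
#' @export
simulate_pupil <- function(config, events, resp, participant = 1L) {
  validate_sim_config(config)
  phase_df <- if (is.data.frame(resp)) resp else resp$phase
  set.seed(participant_seed(config, participant, stream = 3L))
  t <- phase_df$time_s
  fs <- config$fs

  dr <- config$pupil_drift
  value <- dr[[1]] * exp(dr[[2]] * t) + dr[[3]]
  value <- value + config$pupil_resp_gain * cos(phase_df$phase)

  if (nrow(events) > 0) {
    value <- value + pupil_kernel_sum(t, events$time_s, config$pupil_kernel)
  }
  if (config$noise_sd > 0) value <- value + rnorm(length(t), 0, config$noise_sd)

  if (config$blink_rate > 0) {
    total_min <- (max(t) - min(t)) / 60
    n_blinks <- rpois(1, config$blink_rate * total_min)
    if (n_blinks > 0) {
      onset <- runif(n_blinks, min(t), max(t))
      p <- lognormal_from_moments(config$blink_duration_mean, config$blink_duration_mean / 3)
      dur <- rlnorm(n_blinks, p$meanlog, p$sdlog)
      for (j in seq_len(n_blinks)) {
        value[t >= onset[j] & t < onset[j] + dur[j]] <- NA_real_
      }
    }
  }
  tibble(time_s = t, value = value)
}

#' Evaluate the biphasic event-locked pupil kernel
#'
#' @param lag Numeric vector of lags relative to the event, seconds.
#' @param kernel Kernel specification as in [sim_config()]:
#'   list of `constriction` and `dilation`, each `c(amplitude, peak, width)`.
#' @return Kernel value at each lag.
#' @export
#' @examples
#' k <- sim_config()$pupil_kernel
#' pupil_kernel_value(c(-0.5, 1.0), k)
pupil_kernel_value <- function(lag, kernel) {
  g <- function(p) p[["amplitude"]] * exp(-(lag - p[["peak"]])^2 / (2 * p[["width"]]^2))
  g(kernel$constriction) + g(kernel$dilation)
}

# Sum of kernels over events, evaluated on the full time grid.
pupil_kernel_sum <- function(t, event_times, kernel) {
  out <- numeric(length(t))
  # kernels are negligible beyond ~8 s; restrict to a local window per event
  half <- 8
  for (te in event_times) {
    i <- which(t >= te - half & t <= te + half)
    out[i] <- out[i] + pupil_kernel_value(t[i] - te, kernel)
  }
  out
}
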