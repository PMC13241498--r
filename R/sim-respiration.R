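#' Simulate a respiration trace with known phase
#'
#' Generates back-to-back respiration cycles covering the whole session
#' (trials plus inter-trial intervals). Each cycle is a phase-warped cosine:
#' the ground-truth phase advances linearly from 0 at the inhalation peak
#' through pi at the exhalation trough (expiration) and back to 2*pi at the
#' next peak (inspiration), with inspiration occupying
#' `inspiration_fraction` of the cycle in time. The trace value is
#' `cos(phase)` plus white noise, so ground-truth phase is exact by
#' construction and downstream phase estimation can be scored against it.
#'
#' Cycle durations are lognormal, moment matched to
#' `resp_cycle_mean`/`resp_cycle_sd`; `resp_cycle_sd = 0` gives identical
#' cycles.
#'
#' @param config A [sim_config()].
#' @param participant Participant index (determines the random stream).
#' @return A list with
#'   * `trace`: tibble `(time_s, value)` at `config$fs` Hz,
#'   * `phase`: tibble `(time_s, phase)` of ground-truth phase in `[0, 2*pi)`,
#'   * `cycles`: tibble `(peak_time, trough_time, duration)` of ground-truth
#'     cycle boundaries (peak-to-peak cycles; trough = expiration end).
#' @export
#' @examples
#' resp <- simulate_respiration(sim_config(n_trials = 1, seed = 2), 1)
#' nrow(resp$cycles)
simulate_respiration <- function(config, participant = 1L) {
  validate_sim_config(config)
  total <- session_duration(config)
  set.seed(participant_seed(config, participant, stream = 1L))

  # draw cycle durations until the session is covered
  if (config$resp_cycle_sd == 0) {
    n_cycles <- ceiling(total / config$resp_cycle_mean) + 2L
    durations <- rep(config$resp_cycle_mean, n_cycles)
  } else {
    p <- lognormal_from_moments(config$resp_cycle_mean, config$resp_cycle_sd)
    durations <- numeric(0)
    while (sum(durations) < total + 2 * config$resp_cycle_mean) {
      durations <- c(durations, rlnorm(32, p$meanlog, p$sdlog))
    }
  }
  peaks <- cumsum(c(0, durations))
  keep <- peaks[-length(peaks)] < total
  durations <- durations[keep]
  peaks <- peaks[seq_len(sum(keep))]
  troughs <- peaks + (1 - config$inspiration_fraction) * durations

  t <- seq(0, total, by = 1 / config$fs)
  t <- t[t < total]
  phase <- true_phase_at(t, peaks, troughs, durations)
  value <- cos(phase)
  if (config$noise_sd > 0) value <- value + rnorm(length(value), 0, config$noise_sd)

  list(
    trace = tibble(time_s = t, value = value),
    phase = tibble(time_s = t, phase = phase),
    cycles = tibble(peak_time = peaks, trough_time = troughs, duration = durations)
  )
}

# Piecewise-linear ground-truth phase at arbitrary times. Expiration
# (peak -> trough) maps to [0, pi), inspiration (trough -> next peak) to
# [pi, 2*pi). Times beyond the last cycle are extrapolated from the last one.
true_phase_at <- function(t, peaks, troughs, durations) {
  ends <- peaks + durations
  idx <- findInterval(t, peaks)
  idx[idx < 1] <- 1L
  idx[idx > length(peaks)] <- length(peaks)
  pk <- peaks[idx]; tr <- troughs[idx]; en <- ends[idx]
  in_exp <- t < tr
  ph <- ifelse(in_exp,
               pi * (t - pk) / (tr - pk),
               pi + pi * (t - tr) / (en - tr))
  wrap_phase(ph)
}
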