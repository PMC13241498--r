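#' Simulate perceptual reversal reports
#'
#' Generates alternating left/right percepts within each trial. Dominance
#' durations are lognormal with percept-dependent parameters. If
#' `coupling_kappa > 0`, each tentative reversal time is jittered to the
#' nearest time whose respiration phase equals a draw from
#' `von Mises(coupling_mu, coupling_kappa)`, so reversal phases follow the
#' von Mises distribution exactly (their expected pairwise phase
#' consistency is the squared Bessel ratio `(I1(k)/I0(k))^2`) while the
#' marginal duration distribution is approximately preserved (the jitter
#' is bounded by about one respiration cycle). Events falling outside
#' trial windows are dropped.
#'
#' Each event is labelled with the *new* percept (the interpretation the
#' observer switched to). The first report of a trial has no preceding
#' stability; the last has no subsequent stability.
#'
#' @param config A [sim_config()].
#' @param resp A ground-truth respiration object from
#'   [simulate_respiration()] (its `phase` component is used), or a tibble
#'   `(time_s, phase)`.
#' @param participant Participant index (random stream).
#' @return Tibble with columns `participant`, `trial`, `time_s`, `percept`
#'   (`"left"`/`"right"`), `reversal_number` (within-recording ordinal),
#'   `true_phase` (ground-truth respiration phase at the report),
#'   `stability_preceding`, `stability_subsequent` (seconds, `NA` at trial
#'   edges).
#' @export
simulate_reversals <- function(config, resp, participant = 1L) {
  validate_sim_config(config)
  phase_df <- if (is.data.frame(resp)) resp else resp$phase
  stopifnot(all(c("time_s", "phase") %in% names(phase_df)))
  unwrapped <- unwrap_for_interp(phase_df$phase)
  phase_at <- function(t) {
    approx(phase_df$time_s, unwrapped, xout = t, rule = 2)$y %% (2 * pi)
  }
  # jitter a tentative time to the nearest sample (after t_min) whose phase
  # matches psi; the search window spans ~3 cycles so a near-exact match
  # always exists
  jitter_to_phase <- function(t_c, psi, t_min,
                              max_jitter = 1.5 * config$resp_cycle_mean) {
    i0 <- which.min(abs(phase_df$time_s - t_c))
    half <- round(max_jitter * config$fs)
    idx <- max(1, i0 - half):min(nrow(phase_df), i0 + half)
    idx <- idx[phase_df$time_s[idx] > t_min]
    if (length(idx) == 0) return(t_c)
    d <- abs(circ_dist(phase_df$phase[idx], psi))
    # among near-exact phase matches prefer the one closest in time
    cand <- idx[d <= min(d, na.rm = TRUE) + 1e-6]
    cand[which.min(abs(phase_df$time_s[cand] - t_c))] |>
      (\(i) phase_df$time_s[i])()
  }
  set.seed(participant_seed(config, participant, stream = 2L))

  draw_duration <- function(percept) {
    if (percept == "left") {
      rlnorm(1, config$stability_meanlog_left, config$stability_sdlog_left)
    } else {
      rlnorm(1, config$stability_meanlog_right, config$stability_sdlog_right)
    }
  }

  windows <- trial_windows(config)
  out <- vector("list", nrow(windows))
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    percept <- sample(c("left", "right"), 1)
    t_now <- w$start
    times <- numeric(0); percepts <- character(0)
    repeat {
      # duration of holding the current percept; the event switches away from it
      d <- draw_duration(percept)
      cand <- t_now + d
      if (config$coupling_kappa > 0) {
        psi <- rvonmises(1, config$coupling_mu, config$coupling_kappa)
        cand <- jitter_to_phase(cand, psi, t_min = t_now + 0.1)
      }
      if (cand >= w$end) break
      percept <- if (percept == "left") "right" else "left"
      times <- c(times, cand); percepts <- c(percepts, percept)
      t_now <- cand
    }
    out[[k]] <- tibble(trial = w$trial, time_s = times, percept = percepts)
  }
  ev <- bind_rows(out)
  if (nrow(ev) == 0) {
    return(tibble(participant = integer(), trial = integer(), time_s = numeric(),
                  percept = character(), reversal_number = integer(),
                  true_phase = numeric(), stability_preceding = numeric(),
                  stability_subsequent = numeric()))
  }
  ev |>
    mutate(participant = as.integer(participant),
           reversal_number = row_number(),
           true_phase = phase_at(.data$time_s)) |>
    compute_stabilities() |>
    select("participant", "trial", "time_s", "percept", "reversal_number",
           "true_phase", "stability_preceding", "stability_subsequent")
}

# Unwrap a sawtooth phase series so linear interpolation is valid between
# samples (phase increases by < pi between adjacent 100 Hz samples).
unwrap_for_interp <- function(phase) {
  d <- diff(phase)
  d[is.na(d)] <- 0
  jumps <- cumsum(c(0, ifelse(d < -pi, 2 * pi, ifelse(d > pi, -2 * pi, 0))))
  phase + jumps
}
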