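#' Lognormal parameters from a target mean and SD
#'
#' Moment matching: `sdlog^2 = log(1 + (sd/mean)^2)`,
#' `meanlog = log(mean) - sdlog^2 / 2`.
#'
#' @param mean,sd Target arithmetic mean and standard deviation (`> 0`).
#' @return Named list with `meanlog` and `sdlog`.
#' @export
#' @examples
#' p <- lognormal_from_moments(4.73, 1.79)
#' exp(p$meanlog + p$sdlog^2 / 2) # recovers 4.73
lognormal_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Simulation configuration for a synthetic reversal-task recording
#'
#' Bundles all ground-truth parameters of the synthetic data generator:
#' the task layout (continuous viewing trials separated by rest), lognormal
#' percept-dominance durations with percept-dependent means, respiration
#' cycles with inspiration shorter than expiration, optional von Mises
#' coupling of reversal times to respiration phase, a biphasic event-locked
#' pupil kernel (constriction before the report, dilation after), pupil
#' covariation with respiration phase, and blink gaps.
#'
#' Defaults emulate a typical bistable-figure (Necker cube) session: 75 s
#' trials, left percept held 4.73 +/- 1.79 s vs right 3.16 +/- 1.23 s
#' (lognormal, moment matched), respiration cycles 3.76 +/- 0.73 s with
#' inspiration occupying 1.71/3.76 of the cycle.
#'
#' @param n_participants,n_trials Counts.
#' @param trial_duration,iti Trial length and inter-trial interval, seconds.
#' @param stability_mean_left,stability_sd_left Mean/SD (s) of left-percept
#'   dominance durations; converted to lognormal parameters internally.
#' @param stability_mean_right,stability_sd_right Same for the right percept.
#' @param resp_cycle_mean,resp_cycle_sd Respiration cycle duration moments, s.
#' @param inspiration_fraction Fraction of each cycle spent inspiring, in (0,1).
#' @param coupling_kappa Von Mises concentration of reversal-time phase
#'   coupling; 0 disables coupling.
#' @param coupling_mu Preferred respiration phase of reversals, `[0, 2*pi)`.
#' @param pupil_kernel List with `constriction` and `dilation` components,
#'   each `c(amplitude, peak, width)` in (z units, s, s). The constriction
#'   lobe is centred before the reversal, the dilation lobe after.
#' @param pupil_resp_gain Amplitude of the cosine modulation of pupil size by
#'   respiration phase (maximum at peak inhalation / expiration onset).
#' @param pupil_drift `c(a, b, c)` of the slow baseline drift `a*exp(b*t)+c`.
#' @param noise_sd White-noise SD added to both traces (signal units).
#' @param blink_rate Blinks per minute.
#' @param blink_duration_mean Mean blink duration, seconds.
#' @param fs Sampling rate of generated traces, Hz.
#' @param seed Integer seed; fully determines all generated data.
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 2, n_trials = 2, seed = 1)
sim_config <- function(n_participants = 20,
                       n_trials = 8,
                       trial_duration = 75,
                       iti = 15,
                       stability_mean_left = 4.73,
                       stability_sd_left = 1.79,
                       stability_mean_right = 3.16,
                       stability_sd_right = 1.23,
                       resp_cycle_mean = 3.76,
                       resp_cycle_sd = 0.73,
                       inspiration_fraction = 1.71 / 3.76,
                       coupling_kappa = 0,
                       coupling_mu = pi,
                       pupil_kernel = list(
                         constriction = c(amplitude = -0.3, peak = -0.5, width = 0.4),
                         dilation = c(amplitude = 0.4, peak = 1.0, width = 0.6)
                       ),
                       pupil_resp_gain = 0.2,
                       pupil_drift = c(a = 0.5, b = -0.002, c = 0),
                       noise_sd = 0.1,
                       blink_rate = 15,
                       blink_duration_mean = 0.15,
                       fs = 100,
                       seed = 1L) {
  left <- lognormal_from_moments(stability_mean_left, stability_sd_left)
  right <- lognormal_from_moments(stability_mean_right, stability_sd_right)
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_trials = as.integer(n_trials),
    trial_duration = trial_duration,
    iti = iti,
    stability_meanlog_left = left$meanlog,
    stability_sdlog_left = left$sdlog,
    stability_meanlog_right = right$meanlog,
    stability_sdlog_right = right$sdlog,
    resp_cycle_mean = resp_cycle_mean,
    resp_cycle_sd = resp_cycle_sd,
    inspiration_fraction = inspiration_fraction,
    coupling_kappa = coupling_kappa,
    coupling_mu = wrap_phase(coupling_mu),
    pupil_kernel = pupil_kernel,
    pupil_resp_gain = pupil_resp_gain,
    pupil_drift = pupil_drift,
    noise_sd = noise_sd,
    blink_rate = blink_rate,
    blink_duration_mean = blink_duration_mean,
    fs = fs,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_participants < 1 || n_trials < 1) abort("need at least one participant and one trial")
    if (trial_duration <= 0 || iti < 0) abort("trial_duration must be > 0 and iti >= 0")
    if (resp_cycle_mean <= 0 || resp_cycle_sd < 0) abort("respiration cycle moments must be positive")
    if (inspiration_fraction <= 0 || inspiration_fraction >= 1) {
      abort("inspiration_fraction must lie strictly between 0 and 1")
    }
    if (coupling_kappa < 0) abort("coupling_kappa must be >= 0")
    if (noise_sd < 0 || blink_rate < 0 || blink_duration_mean <= 0) {
      abort("noise_sd and blink_rate must be >= 0, blink_duration_mean > 0")
    }
    if (fs <= 0) abort("fs must be > 0")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d participant(s), %d trial(s) of %g s (+%g s rest), fs = %g Hz, seed = %d\n",
              x$n_participants, x$n_trials, x$trial_duration, x$iti, x$fs, x$seed))
  cat(sprintf("  respiration: %g +/- %g s per cycle, inspiration fraction %.3f\n",
              x$resp_cycle_mean, x$resp_cycle_sd, x$inspiration_fraction))
  cat(sprintf("  phase coupling: kappa = %g, mu = %.2f rad\n", x$coupling_kappa, x$coupling_mu))
  invisible(x)
}

# Deterministic per-participant sub-seed derived from the global seed.
participant_seed <- function(cfg, participant, stream = 0L) {
  as.integer((as.numeric(cfg$seed) * 10007 + participant * 101 + stream) %% 2147483646) + 1L
}

# Trial window table for a config: one row per trial, absolute seconds.
trial_windows <- function(cfg) {
  start <- (seq_len(cfg$n_trials) - 1) * (cfg$trial_duration + cfg$iti)
  tibble(trial = seq_len(cfg$n_trials), start = start, end = start + cfg$trial_duration)
}

session_duration <- function(cfg) {
  cfg$n_trials * (cfg$trial_duration + cfg$iti)
}
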