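test_that("config validation rejects impossible settings", {
  expect_error(sim_config(trial_duration = -1), "trial_duration")
  expect_error(sim_config(coupling_kappa = -0.5), "coupling_kappa")
  expect_error(sim_config(inspiration_fraction = 1.2), "inspiration_fraction")
  expect_error(sim_config(resp_cycle_mean = 0), "cycle")
})

test_that("lognormal moment matching recovers the target moments", {
  p <- lognormal_from_moments(4.73, 1.79)
  expect_equal(exp(p$meanlog + p$sdlog^2 / 2), 4.73, tolerance = 1e-12)
  v <- (exp(p$sdlog^2) - 1) * exp(2 * p$meanlog + p$sdlog^2)
  expect_equal(sqrt(v), 1.79, tolerance = 1e-12)
  # Monte-Carlo check of the left-percept dominance mean
  set.seed(1)
  x <- rlnorm(1e4, p$meanlog, p$sdlog)
  expect_lt(abs(mean(x) - 4.73) / 4.73, 0.05)
})

test_that("respiration generator honours degenerate and default cycle stats", {
  cfg0 <- sim_config(n_participants = 1, n_trials = 1, resp_cycle_sd = 0, seed = 3)
  r0 <- simulate_respiration(cfg0, 1)
  expect_true(all(abs(r0$cycles$duration - cfg0$resp_cycle_mean) < 1e-12))

  cfg <- sim_config(n_participants = 1, n_trials = 1, seed = 5)
  r <- simulate_respiration(cfg, 1)
  n_in_trial <- sum(r$cycles$peak_time < cfg$trial_duration)
  expect_gte(n_in_trial, 75 / 3.76 - 2)
  expect_lte(n_in_trial, 75 / 3.76 + 2)
  # inspiration occupies the configured fraction of each cycle
  frac <- 1 - (r$cycles$trough_time - r$cycles$peak_time) / r$cycles$duration
  expect_equal(frac, rep(cfg$inspiration_fraction, nrow(r$cycles)),
               tolerance = 1e-10)
  # value is cos(phase) plus noise
  expect_lt(sd(r$trace$value - cos(r$phase$phase)), 2 * cfg$noise_sd)
})

test_that("identical seeds reproduce bit-identical data", {
  cfg <- small_study_config(seed = 17)
  a <- simulate_participant(cfg, 1)
  b <- simulate_participant(cfg, 1)
  expect_identical(a$respiration, b$respiration)
  expect_identical(a$pupil, b$pupil)
  expect_identical(a$events, b$events)
  # different participants get independent streams
  c1 <- simulate_participant(cfg, 2)
  expect_false(identical(a$respiration$value, c1$respiration$value))
})

test_that("reversal phases follow the requested von Mises coupling", {
  ppc_events <- function(kappa, seed) {
    cfg <- sim_config(n_participants = 1, n_trials = 4, seed = seed,
                      coupling_kappa = kappa)
    r <- simulate_respiration(cfg, 1)
    ev <- simulate_reversals(cfg, r, 1)
    ppc_brute(ev$true_phase)
  }
  # null coupling: phases ~ uniform
  null_vals <- vapply(1:6, function(s) ppc_events(0, s), numeric(1))
  expect_lt(abs(mean(null_vals)), 0.03)
  # kappa = 2: squared Bessel ratio oracle
  v2 <- mean(vapply(1:6, function(s) ppc_events(2, s), numeric(1)))
  expect_equal(v2, von_mises_resultant(2)^2, tolerance = 0.12)
  # monotone in kappa, averaged over seeds
  kappas <- c(0, 0.5, 1, 2, 4)
  means <- vapply(kappas, function(k) {
    mean(vapply(1:20, function(s) ppc_events(k, s + 100), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("duration sampling is recovered by a lognormal fit", {
  cfg <- sim_config(n_participants = 2, n_trials = 60, seed = 9)
  durs <- unlist(lapply(1:2, function(p) {
    r <- simulate_respiration(cfg, p)
    ev <- simulate_reversals(cfg, r, p)
    # durations of the left percept end at events labelled 'right'
    ev$stability_preceding[ev$percept == "right"]
  }))
  durs <- durs[!is.na(durs)]
  expect_gt(length(durs), 1000)
  f <- fitdistrplus::fitdist(durs, "lnorm")
  est <- f$estimate; se <- f$sd
  expect_lt(abs(est[["meanlog"]] - cfg$stability_meanlog_left), 3 * se[["meanlog"]])
  expect_lt(abs(est[["sdlog"]] - cfg$stability_sdlog_left), 3 * se[["sdlog"]])
})

test_that("pupil trace decomposes into its planted components", {
  cfg <- sim_config(n_participants = 1, n_trials = 1, noise_sd = 0,
                    blink_rate = 0, pupil_resp_gain = 0, seed = 4)
  r <- simulate_respiration(cfg, 1)
  ev <- tibble::tibble(time_s = 40)
  pu <- simulate_pupil(cfg, ev, r, 1)
  dr <- cfg$pupil_drift
  baseline <- dr[[1]] * exp(dr[[2]] * pu$time_s) + dr[[3]]
  kern <- pu$value - baseline
  expect_equal(kern, pupil_kernel_value(pu$time_s - 40, cfg$pupil_kernel),
               tolerance = 1e-10)

  # pure respiratory modulation: perfect correlation with cos(phase)
  cfg2 <- sim_config(n_participants = 1, n_trials = 1, noise_sd = 0,
                     blink_rate = 0, pupil_resp_gain = 0.3, seed = 4)
  pu2 <- simulate_pupil(cfg2, ev[0, ], r, 1)
  resid <- pu2$value - baseline
  expect_equal(cor(resid, cos(r$phase$phase)), 1, tolerance = 1e-10)
})

test_that("blink gaps appear as missing runs at roughly the configured rate", {
  cfg <- sim_config(n_participants = 1, n_trials = 2, seed = 8)
  p <- simulate_participant(cfg, 1)
  miss <- is.na(p$pupil$value)
  expect_gt(sum(miss), 0)
  r <- rle(miss)
  n_runs <- sum(r$values)
  session_minutes <- cfg$n_trials * (cfg$trial_duration + cfg$iti) / 60
  expect_gt(n_runs, 0.3 * cfg$blink_rate * session_minutes)
  expect_lt(n_runs, 2.5 * cfg$blink_rate * session_minutes)
})

test_that("a study round-trips through plain-text files", {
  cfg <- sim_config(n_participants = 2, n_trials = 1, seed = 21)
  study <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_true(file.exists(file.path(dir, "resp_01.tsv")))
  back <- read_study(dir)
  expect_length(back, 2)
  expect_equal(back[[1]]$respiration$value, study[[1]]$respiration$value,
               tolerance = 1e-12)
  expect_equal(nrow(back[[2]]$events), nrow(study[[2]]$events))
  expect_equal(back[[1]]$truth$cycles$peak_time, study[[1]]$truth$cycles$peak_time,
               tolerance = 1e-9)
})
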