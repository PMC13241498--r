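sinusoid_trace <- function(freq = 0.25, duration = 75, fs = 100, offset = 0) {
  t <- seq(0, duration, by = 1 / fs)
  tibble::tibble(time_s = t, value = sin(2 * pi * freq * t) + offset)
}

test_that("preprocessing z-scores, removes DC, and preserves peak timing", {
  tr <- sinusoid_trace(duration = 600)
  out <- preprocess_respiration(tr)
  expect_lt(abs(mean(out$value)), 1e-10)
  expect_lt(abs(sd(out$value) - 1), 1e-10)

  # constant offset is removed by the high-pass: same interior output
  # (the slow high-pass has edge transients over ~1/cutoff seconds)
  out_off <- preprocess_respiration(sinusoid_trace(duration = 600, offset = 5))
  i <- out$time_s > 60 & out$time_s < 540
  expect_lt(max(abs(out$value[i] - out_off$value[i])), 1e-2)

  # peak times survive zero-phase filtering within one sample
  peaks_in <- tr$time_s[which(diff(sign(diff(tr$value))) == -2) + 1]
  peaks_out <- out$time_s[which(diff(sign(diff(out$value))) == -2) + 1]
  interior <- peaks_in > 60 & peaks_in < 540
  matched <- vapply(peaks_in[interior],
                    function(p) min(abs(peaks_out - p)), numeric(1))
  expect_lt(max(matched), 0.011)

  expect_error(preprocess_respiration(
    tibble::tibble(time_s = seq(0, 50, 0.01), value = 1)), "variance")
})

test_that("preprocessing is idempotent in the passband", {
  cfg <- sim_config(n_participants = 1, n_trials = 4, seed = 42)
  raw <- simulate_respiration(cfg, 1)$trace
  once <- preprocess_respiration(raw)
  twice <- preprocess_respiration(once)
  # interior samples (away from edge transients of the 0.03 Hz high-pass);
  # tolerances reflect the z-score renormalisation after refiltering
  i <- once$time_s > 30 & once$time_s < max(once$time_s) - 30
  expect_lt(max(abs(once$value[i] - twice$value[i])), 0.05)
  expect_lt(mean(abs(once$value[i] - twice$value[i])), 0.01)
})

test_that("cycle detection finds sinusoid peaks and applies the z threshold", {
  clean <- preprocess_respiration(sinusoid_trace())
  cycles <- detect_cycles(clean)
  expect_gte(nrow(cycles), 18)
  expect_lte(nrow(cycles), 19)
  gaps <- diff(cycles$peak_time)
  expect_true(all(abs(gaps - 4) < 0.011))

  # all maxima below z = 0.5: nothing detected
  flat <- clean
  flat$value <- flat$value * 0.4 / max(flat$value)
  expect_identical(nrow(detect_cycles(flat)), 0L)
})

test_that("detected peaks match ground truth on simulated data", {
  cfg <- small_study_config()
  p <- simulate_participant(cfg, 1)
  rp <- respiration_pipeline(p$respiration)
  d <- vapply(rp$cycles$peak_time,
              function(pt) min(abs(pt - p$truth$cycles$peak_time)), numeric(1))
  expect_gte(mean(d < 0.15), 0.95)
})

test_that("atypical-cycle rejection flags exactly the deviant waveform", {
  w <- cos(2 * pi * seq(0, 1, length.out = 701))
  base <- tibble::tibble(
    peak_time = seq(0, by = 4, length.out = 51),
    inspiration_onset = seq(0, by = 4, length.out = 51) - 2,
    expiration_end = seq(0, by = 4, length.out = 51) + 2,
    duration = 4, is_atypical = FALSE,
    waveform = c(rep(list(w), 50), list(-w))
  )
  out <- reject_atypical_cycles(base)
  expect_identical(which(out$is_atypical), 51L)

  # identical waveforms: zero score spread, nothing rejected
  all_same <- base
  all_same$waveform <- rep(list(w), 51)
  expect_false(any(reject_atypical_cycles(all_same)$is_atypical))

  expect_warning(reject_atypical_cycles(base[1:3, ]), "fewer than 5")
})

test_that("phase anchors sit at the signal extrema and interpolate linearly", {
  clean <- preprocess_respiration(sinusoid_trace(freq = 0.25))
  cycles <- detect_cycles(clean)
  phase <- assign_phase(clean, cycles)
  # phase 0 at peaks, pi at troughs (interior cycles)
  for (k in 2:(nrow(cycles) - 1)) {
    i_peak <- which.min(abs(phase$time_s - cycles$peak_time[k]))
    d0 <- abs(circ_dist(phase$phase[i_peak], 0))
    expect_lt(d0, 0.05)
    i_trough <- which.min(abs(phase$time_s - cycles$expiration_end[k]))
    expect_lt(abs(circ_dist(phase$phase[i_trough], pi)), 0.05)
    # temporal midpoint of inspiration maps to 3*pi/2 (and of expiration to pi/2)
    mid_exp <- (cycles$peak_time[k] + cycles$expiration_end[k]) / 2
    i_mid <- which.min(abs(phase$time_s - mid_exp))
    expect_lt(abs(circ_dist(phase$phase[i_mid], pi / 2)), 0.05)
  }
  # assigned phases lie in [0, 2*pi) and increase within cycle halves
  ph <- phase$phase[!is.na(phase$phase)]
  expect_true(all(ph >= 0 & ph < 2 * pi))
})

test_that("assigned phase tracks simulated ground truth", {
  cfg <- small_study_config()
  for (pid in 1:2) {
    p <- simulate_participant(cfg, pid)
    rp <- respiration_pipeline(p$respiration)
    est <- rp$phase$phase
    tru <- p$truth$phase$phase[seq_along(est)]
    ok <- !is.na(est)
    expect_gt(mean(ok), 0.8)
    expect_lt(mean(abs(circ_dist(est[ok], tru[ok]))), 0.25)
  }
})

test_that("pre-event respiration frequency averages the last cycles", {
  cyc <- tibble::tibble(
    peak_time = c(2, 6), inspiration_onset = c(0, 4),
    expiration_end = c(4, 8), duration = c(4, 4),
    is_atypical = FALSE, waveform = list(NULL, NULL))
  expect_equal(respiration_frequency_before(10, cyc), 0.25)
  cyc$duration <- c(3, 5)
  expect_equal(respiration_frequency_before(10, cyc), (1 / 3 + 1 / 5) / 2)
  # too few prior cycles -> missing
  expect_true(is.na(respiration_frequency_before(1, cyc)))
  expect_true(is.na(respiration_frequency_before(4, cyc, n_cycles = 2)))
})

test_that("one- and two-cycle frequency estimates agree on smooth data", {
  cfg <- sim_config(n_participants = 1, n_trials = 4, seed = 31)
  p <- simulate_participant(cfg, 1)
  rp <- respiration_pipeline(p$respiration)
  f2 <- respiration_frequency_before(p$events$time_s, rp$cycles, n_cycles = 2)
  f1 <- respiration_frequency_before(p$events$time_s, rp$cycles, n_cycles = 1)
  ok <- !is.na(f1) & !is.na(f2)
  expect_gt(cor(f1[ok], f2[ok]), 0.6)
})
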