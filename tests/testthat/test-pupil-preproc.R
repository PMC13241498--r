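test_that("blink interpolation is linear, guarded, and an identity without gaps", {
  tr <- tibble::tibble(time_s = c(0, 1, 2), value = c(1, NA, 3))
  expect_equal(interpolate_blinks(tr, guard = 0)$value, c(1, 2, 3))

  no_gap <- tibble::tibble(time_s = 0:5, value = as.numeric(1:6))
  expect_equal(interpolate_blinks(no_gap)$value, no_gap$value)

  # guard margin consumes neighbouring samples before interpolating
  t <- seq(0, 10, by = 0.01)
  v <- sin(t)
  v[t >= 5 & t <= 5.2] <- NA
  contaminated <- v
  contaminated[t >= 4.95 & t < 5] <- 99 # eyelid ramp artefact
  out <- interpolate_blinks(tibble::tibble(time_s = t, value = contaminated),
                            guard = 0.1)
  expect_true(all(abs(out$value - sin(t)) < 0.1))

  # leading/trailing gaps take the nearest valid value
  lead_gap <- tibble::tibble(time_s = 0:4, value = c(NA, NA, 5, 6, NA))
  expect_equal(interpolate_blinks(lead_gap, guard = 0)$value, c(5, 5, 5, 6, 6))

  expect_error(interpolate_blinks(tibble::tibble(time_s = 0:2, value = rep(NA_real_, 3))),
               "entirely missing")
})

test_that("blink interpolation stays close to the uncorrupted trace", {
  cfg <- small_study_config()
  p_clean <- simulate_participant(sim_config(n_participants = 2, n_trials = 2,
                                             seed = 42, blink_rate = 0), 1)
  p_blink <- simulate_participant(cfg, 1)
  blinked <- is.na(p_blink$pupil$value)
  out <- interpolate_blinks(p_blink$pupil)
  rms <- sqrt(mean((out$value[blinked] - p_clean$pupil$value[blinked])^2))
  expect_lt(rms, 3 * cfg$noise_sd)
})

test_that("exponential detrend recovers an exact exponential and degenerates safely", {
  t <- seq(0, 120, by = 0.02)
  tr <- tibble::tibble(time_s = t, value = 2 * exp(-0.01 * t) + 5)
  out <- detrend_exponential(tr)
  expect_lt(max(abs(out$value)), 1e-6)
  fit <- attr(out, "fit")
  expect_equal(fit$a, 2, tolerance = 1e-4)
  expect_equal(fit$b, -0.01, tolerance = 1e-4)

  # a zero-mean sinusoid is nearly untouched (exponential ~ constant)
  t2 <- seq(0, 600, by = 0.02)
  s <- tibble::tibble(time_s = t2, value = sin(2 * pi * 0.5 * t2))
  outs <- detrend_exponential(s)
  expect_lt(sqrt(mean((outs$value - s$value)^2)) / sqrt(mean(s$value^2)), 0.01)
})

test_that("low-pass response passes 2 Hz, rejects 20 Hz, and z-scores", {
  t <- seq(0, 30, by = 1 / 500)
  tr2 <- tibble::tibble(time_s = t, value = sin(2 * pi * 2 * t))
  out2 <- filter_and_resample(tr2)
  expect_lt(abs(mean(out2$value)), 1e-10)
  expect_lt(abs(sd(out2$value) - 1), 1e-10)

  # attenuation measured through the filter alone (no z-score): apply the
  # same filter via signal:: as an oracle and compare passband/stopband gain
  gain <- function(freq) {
    x <- sin(2 * pi * freq * t)
    y <- signal::filtfilt(signal::butter(3, 8 / 250, type = "low"), x)
    keep <- t > 2 & t < 28
    sqrt(mean(y[keep]^2) / mean(x[keep]^2))
  }
  expect_gt(gain(2), 0.98)
  expect_lt(gain(20), 0.2)
})

test_that("epoching uses a fixed grid, drops edge events, and is linear", {
  t <- seq(0, 200, by = 0.01)
  tr <- tibble::tibble(time_s = t, value = sin(t))
  ep <- epoch_around_events(tr, c(100, 2, 150))
  expect_identical(ep$dropped, 1L)
  expect_identical(dim(ep$data), c(2L, 801L))
  expect_equal(ep$time_s[c(1, 801)], c(-4, 4))
  expect_equal(ep$event_times, c(100, 150))
  # kept + dropped = total
  expect_identical(length(ep$event_times) + ep$dropped, 3L)
  # row content: samples 96..104 s
  expect_equal(ep$data[1, ], sin(seq(96, 104, by = 0.01)), tolerance = 1e-12)

  # linearity
  tr2 <- tibble::tibble(time_s = t, value = cos(2 * t))
  both <- tibble::tibble(time_s = t, value = tr$value + tr2$value)
  e1 <- epoch_around_events(tr, c(50, 100))
  e2 <- epoch_around_events(tr2, c(50, 100))
  eb <- epoch_around_events(both, c(50, 100))
  expect_equal(eb$data, e1$data + e2$data, tolerance = 1e-12)

  # phase series carry NA through
  ph <- tibble::tibble(time_s = t, phase = ifelse(t < 99, NA, 1))
  eph <- epoch_around_events(ph, 100)
  expect_true(anyNA(eph$data))
  expect_identical(eph$kind, "phase")

  expect_error(epoch_around_events(tr, 2), "no event")
})

test_that("event-locked average recovers the planted pupil kernel", {
  # widely spaced events isolate the kernel from neighbouring responses;
  # amplitudes are measured against the epoch-average's own tail baseline
  # (the detrend constant absorbs the mean level of event-locked activity)
  cfg <- sim_config(n_participants = 1, n_trials = 1, trial_duration = 2100,
                    iti = 0, seed = 6)
  r <- simulate_respiration(cfg, 1)
  ev <- tibble::tibble(time_s = seq(10, 2080, by = 8))
  expect_gte(nrow(ev), 200)
  pu <- simulate_pupil(cfg, ev, r, 1)
  cleaned <- detrend_exponential(interpolate_blinks(pu))
  avg <- epoch_average(epoch_around_events(cleaned, ev$time_s))
  base <- mean(avg$mean[abs(avg$time_s) >= 3])
  pre <- avg$time_s < 0 & avg$time_s > -2
  post <- avg$time_s > 0 & avg$time_s < 2
  t_min <- avg$time_s[pre][which.min(avg$mean[pre])]
  t_max <- avg$time_s[post][which.max(avg$mean[post])]
  k <- cfg$pupil_kernel
  expect_lt(abs(t_min - k$constriction[["peak"]]), 0.2)
  expect_lt(abs(t_max - k$dilation[["peak"]]), 0.2)
  a_min <- min(avg$mean[pre]) - base
  a_max <- max(avg$mean[post]) - base
  expect_lt(abs(a_min - pupil_kernel_value(k$constriction[["peak"]], k)) /
              abs(pupil_kernel_value(k$constriction[["peak"]], k)), 0.15)
  expect_lt(abs(a_max - pupil_kernel_value(k$dilation[["peak"]], k)) /
              abs(pupil_kernel_value(k$dilation[["peak"]], k)), 0.15)
})

test_that("reversal-locked pupil shows constriction before and dilation after", {
  cfg <- sim_config(n_participants = 1, n_trials = 16, seed = 61)
  p <- simulate_participant(cfg, 1)
  iso <- clean_epochs(p$events, purity_half_window = 2)
  expect_gte(nrow(iso), 200)
  cleaned <- detrend_exponential(interpolate_blinks(p$pupil))
  avg <- epoch_average(epoch_around_events(cleaned, iso$time_s))
  base <- mean(avg$mean)
  pre <- avg$time_s < 0 & avg$time_s > -2
  post <- avg$time_s > 0 & avg$time_s < 2
  expect_lt(min(avg$mean[pre]), base) # negative extremum before the reversal
  expect_gt(max(avg$mean[post]), base) # positive extremum after it
  expect_lt(avg$time_s[pre][which.min(avg$mean[pre])], 0)
  expect_gt(avg$time_s[post][which.max(avg$mean[post])], 0)
})
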