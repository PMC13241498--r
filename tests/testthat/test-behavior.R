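test_that("stabilities are within-trial successive differences", {
  ev <- tibble::tibble(participant = 1, trial = 1, time_s = c(10, 14, 19),
                       percept = c("left", "right", "left"))
  out <- compute_stabilities(ev)
  expect_equal(out$stability_preceding, c(NA, 4, 5))
  expect_equal(out$stability_subsequent, c(4, 5, NA))

  # single event in a trial: both stabilities missing
  single <- tibble::tibble(participant = 1, trial = 2, time_s = 7, percept = "left")
  outs <- compute_stabilities(single)
  expect_true(is.na(outs$stability_preceding) && is.na(outs$stability_subsequent))

  # cross-trial gaps are never measured
  two_trials <- tibble::tibble(participant = 1, trial = c(1, 2),
                               time_s = c(74, 91), percept = c("left", "right"))
  outt <- compute_stabilities(two_trials)
  expect_true(all(is.na(outt$stability_preceding)))

  # same interior gaps: preceding and subsequent means agree
  ev2 <- tibble::tibble(participant = 1, trial = 1, time_s = cumsum(runif(20, 2, 6)),
                        percept = rep(c("left", "right"), 10))
  o <- compute_stabilities(ev2)
  expect_equal(mean(o$stability_preceding, na.rm = TRUE),
               mean(o$stability_subsequent, na.rm = TRUE))
})

test_that("distribution fitting selects the generating family and matches a closed form", {
  set.seed(1)
  x <- rlnorm(1000, 1.2, 0.6)
  fits <- fit_interval_distributions(x)
  expect_identical(fits$family[1], "lognormal")
  expect_equal(fits$aic, aic_from_loglik(fits$loglik, fits$k), tolerance = 1e-12)

  set.seed(2)
  y <- rexp(1000, rate = 0.3)
  fy <- fit_interval_distributions(y)
  expect_true(fy$family[1] %in% c("exponential", "gamma"))

  # closed-form normal MLE oracle
  z <- c(1, 2, 3, 4, 5)
  zz <- rep(z, 5) # >= 20 samples required
  fz <- fit_interval_distributions(zz)
  s2 <- mean((zz - mean(zz))^2)
  ll <- sum(stats::dnorm(zz, mean(zz), sqrt(s2), log = TRUE))
  norm_row <- fz[fz$family == "normal", ]
  expect_equal(norm_row$loglik, ll, tolerance = 1e-6)
  expect_equal(norm_row$aic, 4 - 2 * ll, tolerance = 1e-6)

  expect_error(fit_interval_distributions(c(-1, rep(2, 30))), "positive")
  expect_error(fit_interval_distributions(runif(5)), "at least 20")
})

test_that("exclusion bounds are strict on 'more than' and 'fewer than'", {
  counts <- tibble::tibble(participant = 1:5,
                           n_reversals = c(119, 120, 500, 900, 1000))
  out <- apply_exclusions(counts)
  expect_equal(out$kept, c(FALSE, TRUE, TRUE, TRUE, FALSE))

  # tallies raw event tables too
  ev <- tibble::tibble(participant = rep(1:2, c(130, 30)),
                       time_s = seq_len(160))
  out2 <- apply_exclusions(ev)
  expect_equal(out2$kept, c(TRUE, FALSE))
})

test_that("epoch cleaning keeps only isolated events and nests monotonically", {
  ev <- tibble::tibble(participant = 1, trial = 1, time_s = c(10, 11, 20),
                       percept = c("l", "r", "l"))
  kept <- clean_epochs(ev, purity_half_window = 2)
  expect_equal(kept$time_s, 20)
  expect_identical(attr(kept, "dropped"), 2L)

  spaced <- tibble::tibble(participant = 1, trial = 1,
                           time_s = seq(0, 50, by = 5), percept = "l")
  expect_identical(nrow(clean_epochs(spaced, 2)), nrow(spaced))

  set.seed(3)
  rand <- tibble::tibble(participant = 1, trial = 1,
                         time_s = sort(runif(100, 0, 300)), percept = "l")
  sizes <- vapply(c(0.5, 1, 2, 4), function(w) nrow(clean_epochs(rand, w)),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("exclusion and epoch cleaning commute", {
  set.seed(4)
  ev <- tibble::tibble(
    participant = rep(1:3, c(150, 100, 60)),
    trial = 1,
    time_s = c(sort(runif(150, 0, 600)), sort(runif(100, 0, 600)),
               sort(runif(60, 0, 600))),
    percept = "l")
  a <- clean_epochs(ev[ev$participant %in%
                         apply_exclusions(ev, 100, 900)$participant[
                           apply_exclusions(ev, 100, 900)$kept], ], 2)
  keptp <- apply_exclusions(ev, 100, 900)
  b_all <- clean_epochs(ev, 2)
  b <- b_all[b_all$participant %in% keptp$participant[keptp$kept], ]
  expect_equal(a$time_s, b$time_s)
})

test_that("group tests match the closed-form paired t and handle degeneracy", {
  s <- tibble::tibble(
    mean_stability_left = c(4.2, 5.1, 3.9, 4.8, 5.6),
    mean_stability_right = c(3.1, 3.5, 3.2, 2.9, 3.8),
    n_first_half = c(30, 40, 25, 35, 45),
    n_second_half = c(28, 42, 27, 33, 44),
    n_reversals = c(58, 82, 52, 68, 89),
    peak_coherence = c(0.2, 0.4, 0.15, 0.3, 0.45))
  out <- group_behavior_tests(s)
  t_oracle <- paired_t_brute(s$mean_stability_left, s$mean_stability_right)
  expect_equal(out$statistic[out$test == "stability_left_vs_right"], t_oracle,
               tolerance = 1e-12)
  # counts and coherence here are perfectly linearly related
  expect_equal(abs(out$estimate[out$test == "count_vs_peak_coherence"]),
               cor(s$n_reversals, s$peak_coherence), tolerance = 1e-12)

  s_id <- s
  s_id$mean_stability_right <- s_id$mean_stability_left
  out2 <- group_behavior_tests(s_id)
  expect_equal(out2$statistic[out2$test == "stability_left_vs_right"], 0)
  expect_equal(out2$p_value[out2$test == "stability_left_vs_right"], 1)

  expect_error(group_behavior_tests(s[1:3, ]), "at least 5")
})
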