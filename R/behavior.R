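#' Fill percept stabilities from reversal times
#'
#' Within each participant and trial, the preceding stability of an event
#' is the interval since the previous report and the subsequent stability
#' the interval until the next one. Intervals never span trials, so the
#' first event of a trial has a missing preceding stability and the last a
#' missing subsequent one. Non-alternating consecutive percept labels are
#' kept but counted in the `"non_alternating"` attribute.
#'
#' @param events Data frame with at least `participant`, `trial`, `time_s`,
#'   `percept`.
#' @return The events tibble with `stability_preceding` and
#'   `stability_subsequent` columns (seconds).
#' @export
#' @examples
#' ev <- tibble::tibble(participant = 1, trial = 1, time_s = c(10, 14, 19),
#'                      percept = c("left", "right", "left"))
#' compute_stabilities(ev)$stability_preceding
compute_stabilities <- function(events) {
  stopifnot(all(c("trial", "time_s", "percept") %in% names(events)))
  grouping <- intersect(c("participant", "trial"), names(events))
  out <- events |>
    as_tibble() |>
    group_by(across(dplyr::all_of(grouping))) |>
    arrange(.data$time_s, .by_group = TRUE) |>
    mutate(stability_preceding = .data$time_s - lag(.data$time_s),
           stability_subsequent = lead(.data$time_s) - .data$time_s) |>
    ungroup()
  non_alt <- out |>
    group_by(across(dplyr::all_of(grouping))) |>
    summarise(n = sum(.data$percept == lag(.data$percept), na.rm = TRUE),
              .groups = "drop")
  attr(out, "non_alternating") <- sum(non_alt$n)
  out
}

#' Fit candidate distributions to dominance durations
#'
#' Maximum-likelihood fits of gamma, lognormal, Weibull, exponential, and
#' normal families to a sample of positive durations; candidates are
#' ranked by AIC (`2k - 2 log L`; `k = 1` for the exponential, 2 for the
#' rest).
#'
#' @param durations Numeric vector of positive durations, length >= 20.
#' @return Object of class `interval_fits`: tibble `(family, loglik, k,
#'   aic, rank)` sorted by AIC, with the fitted parameter vectors in the
#'   list-column `params`.
#' @export
fit_interval_distributions <- function(durations) {
  durations <- durations[!is.na(durations)]
  if (length(durations) < 20) abort("need at least 20 durations to fit distributions")
  if (any(durations <= 0)) abort("durations must be strictly positive")
  families <- c(gamma = "gamma", lognormal = "lnorm", weibull = "weibull",
                exponential = "exp", normal = "norm")
  fits <- imap(families, function(dist, fam) {
    f <- tryCatch(
      suppressWarnings(fitdistrplus::fitdist(durations, dist, method = "mle")),
      error = function(e) NULL
    )
    if (is.null(f)) return(NULL)
    k <- length(f$estimate)
    ll <- f$loglik
    tibble(family = fam, params = list(f$estimate), loglik = ll, k = k,
           aic = aic_from_loglik(ll, k))
  })
  out <- bind_rows(fits) |>
    arrange(.data$aic) |>
    mutate(rank = row_number())
  structure(out, class = c("interval_fits", class(out)))
}

#' @export
print.interval_fits <- function(x, ...) {
  cat(sprintf("<interval_fits> best family: %s (AIC %.1f)\n", x$family[1], x$aic[1]))
  NextMethod()
}

#' Apply participant-level reversal-count exclusions
#'
#' Keeps participants reporting at least `min_count` and at most
#' `max_count` reversals. The bounds themselves are kept (exclusion is
#' strictly "more than" / "fewer than").
#'
#' @param counts Data frame with `participant` and `n_reversals`, or a
#'   reversal-event data frame (counts are then tallied per participant).
#' @param min_count,max_count Inclusive bounds (defaults 120 and 900).
#' @return Tibble `(participant, n_reversals, kept)`.
#' @export
#' @examples
#' apply_exclusions(tibble::tibble(participant = 1:3,
#'                                 n_reversals = c(119, 120, 901)))
apply_exclusions <- function(counts, min_count = 120, max_count = 900) {
  if (!"n_reversals" %in% names(counts)) {
    stopifnot("participant" %in% names(counts))
    counts <- counts |>
      group_by(.data$participant) |>
      summarise(n_reversals = n(), .groups = "drop")
  }
  counts |>
    as_tibble() |>
    mutate(kept = .data$n_reversals >= min_count & .data$n_reversals <= max_count)
}

#' Keep only temporally isolated reversals
#'
#' Drops events that have any other event of the same participant within
#' `purity_half_window` seconds, so that event-locked epochs are free of
#' neighbouring reports.
#'
#' @param events Reversal data frame with `participant` and `time_s`.
#' @param purity_half_window Half window, seconds (default 2).
#' @return The subset tibble of isolated events; the number dropped is in
#'   attribute `"dropped"`.
#' @export
clean_epochs <- function(events, purity_half_window = 2) {
  stopifnot(all(c("time_s") %in% names(events)))
  grouping <- intersect("participant", names(events))
  out <- events |>
    as_tibble() |>
    group_by(across(dplyr::all_of(grouping))) |>
    arrange(.data$time_s, .by_group = TRUE) |>
    mutate(.iso = (is.na(lag(.data$time_s)) |
                     .data$time_s - lag(.data$time_s) > purity_half_window) &
                  (is.na(lead(.data$time_s)) |
                     lead(.data$time_s) - .data$time_s > purity_half_window)) |>
    ungroup()
  kept <- out |> filter(.data$.iso) |> select(-".iso")
  attr(kept, "dropped") <- nrow(out) - nrow(kept)
  kept
}

#' Across-participant behavioural tests
#'
#' Paired t-test of mean left- vs right-percept stability, paired t-test of
#' first- vs second-half reversal counts (a drift check), and the Pearson
#' correlation between each participant's total reversal count and their
#' peak within-participant phase coherence (if supplied).
#'
#' @param summaries Data frame with one row per participant and columns
#'   `mean_stability_left`, `mean_stability_right`, `n_first_half`,
#'   `n_second_half`, `n_reversals`, and optionally `peak_coherence`.
#' @return Tibble `(test, estimate, statistic, p_value, n)` with one row
#'   per performed test.
#' @export
group_behavior_tests <- function(summaries) {
  if (nrow(summaries) < 5) abort("need at least 5 participants for group tests")
  out <- list()
  paired_t <- function(a, b, label) {
    d <- a - b
    if (sd(d) == 0) {
      # degenerate: identical samples give t = 0, p = 1
      st <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      return(tibble(test = label, estimate = mean(d), statistic = st,
                    p_value = if (st == 0) 1 else 0, n = length(d)))
    }
    tt <- t.test(a, b, paired = TRUE)
    tibble(test = label, estimate = unname(tt$estimate),
           statistic = unname(tt$statistic), p_value = tt$p.value,
           n = length(d))
  }
  out$stability <- paired_t(summaries$mean_stability_left,
                            summaries$mean_stability_right,
                            "stability_left_vs_right")
  if (all(c("n_first_half", "n_second_half") %in% names(summaries))) {
    out$halves <- paired_t(summaries$n_first_half, summaries$n_second_half,
                           "reversals_first_vs_second_half")
  }
  if ("peak_coherence" %in% names(summaries)) {
    ct <- cor.test(summaries$n_reversals, summaries$peak_coherence)
    out$coherence <- tibble(test = "count_vs_peak_coherence",
                            estimate = unname(ct$estimate),
                            statistic = unname(ct$statistic),
                            p_value = ct$p.value, n = nrow(summaries))
  }
  bind_rows(out)
}
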