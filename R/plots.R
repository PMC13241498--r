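#' Plot a group PLV time course with surrogate thresholds
#'
#' Group-average event-locked phase locking (mean +/- SEM) with the
#' maximum-statistic surrogate thresholds for p < 0.05 and p < 0.01 as
#' horizontal lines and suprathreshold windows shaded.
#'
#' @param object A `plv_surrogate` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plv_surrogate <- function(object, ...) {
  g <- object$group
  p <- ggplot(g, aes(x = .data$time_s, y = .data$plv_mean)) +
    geom_ribbon(aes(ymin = .data$plv_mean - .data$plv_sem,
                    ymax = .data$plv_mean + .data$plv_sem), alpha = 0.25) +
    geom_line() +
    geom_hline(yintercept = object$thresholds[["p05"]],
               linetype = "dashed", colour = "grey40") +
    geom_hline(yintercept = object$thresholds[["p01"]],
               linetype = "dotted", colour = "black") +
    geom_vline(xintercept = 0, colour = "grey70") +
    labs(x = "Time from reversal (s)", y = "Phase-locking value",
         title = "Event-locked respiration phase locking",
         subtitle = "dashed: p < 0.05 threshold, dotted: p < 0.01 (max-corrected)") +
    theme_minimal()
  if (nrow(object$windows) > 0) {
    p <- p + geom_rect(data = object$windows,
                       aes(xmin = .data$start, xmax = .data$end),
                       ymin = -Inf, ymax = Inf, alpha = 0.15,
                       fill = "steelblue", inherit.aes = FALSE)
  }
  p
}

#' Plot per-timepoint PLV or PPC
#'
#' @param object A `plv_result` or `ppc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plv_result <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s, y = .data$plv)) +
    geom_line() + geom_vline(xintercept = 0, colour = "grey70") +
    labs(x = "Time from event (s)", y = "PLV") + theme_minimal()
}

#' @rdname autoplot.plv_result
#' @export
autoplot.ppc_result <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s, y = .data$ppc)) +
    geom_line() +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_vline(xintercept = 0, colour = "grey70") +
    labs(x = "Time from event (s)", y = "Pairwise phase consistency") +
    theme_minimal()
}

#' Plot a cluster permutation test result
#'
#' Point-wise t statistic with significant clusters shaded.
#'
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_result <- function(object, ...) {
  p <- ggplot(object$pointwise, aes(x = .data$time_s, y = .data$t)) +
    geom_line() +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_vline(xintercept = 0, colour = "grey70") +
    labs(x = "Time from reversal (s)", y = "t statistic",
         title = "Event-locked trace vs. baseline") +
    theme_minimal()
  sig <- object$clusters[object$clusters$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    p <- p + geom_rect(data = sig,
                       aes(xmin = .data$start_s, xmax = .data$end_s),
                       ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick",
                       inherit.aes = FALSE)
  }
  p
}

#' Plot time-resolved model evidence
#'
#' Per-predictor AIC difference (reduced minus full) over epoch time, with
#' the 95% and 99% evidence levels (AIC differences of 6 and 9.2).
#'
#' @param object A `model_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_comparison <- function(object, ...) {
  ggplot(object$comparisons,
         aes(x = .data$time_s, y = .data$delta_aic, colour = .data$predictor)) +
    geom_line() +
    geom_hline(yintercept = 6, linetype = "dashed", colour = "grey40") +
    geom_hline(yintercept = 9.2, linetype = "dotted", colour = "black") +
    geom_vline(xintercept = 0, colour = "grey70") +
    labs(x = "Time from reversal (s)", y = expression(Delta * "AIC"),
         colour = "Predictor",
         title = sprintf("Model evidence for predictors of %s", object$dependent),
         subtitle = "dashed: ~95% Akaike weight, dotted: >99%") +
    theme_minimal()
}

#' Histogram of dominance durations with the best-fitting density
#'
#' @param durations Numeric vector of positive durations (s).
#' @param fits An [fit_interval_distributions()] result (optional; fitted
#'   if missing).
#' @return A ggplot object.
#' @export
plot_duration_fit <- function(durations, fits = NULL) {
  durations <- durations[!is.na(durations)]
  if (is.null(fits)) fits <- fit_interval_distributions(durations)
  best <- fits$family[1]
  pars <- fits$params[[1]]
  dens_fun <- switch(best,
    gamma = function(x) stats::dgamma(x, pars[["shape"]], pars[["rate"]]),
    lognormal = function(x) stats::dlnorm(x, pars[["meanlog"]], pars[["sdlog"]]),
    weibull = function(x) stats::dweibull(x, pars[["shape"]], pars[["scale"]]),
    exponential = function(x) stats::dexp(x, pars[["rate"]]),
    normal = function(x) stats::dnorm(x, pars[["mean"]], pars[["sd"]])
  )
  xs <- seq(0.01, max(durations), length.out = 256)
  ggplot(tibble(durations = durations), aes(x = .data$durations)) +
    geom_histogram(aes(y = ggplot2::after_stat(density)), bins = 40,
                   fill = "grey80", colour = "grey50") +
    geom_line(data = tibble(x = xs, y = dens_fun(xs)),
              aes(x = .data$x, y = .data$y), colour = "firebrick") +
    labs(x = "Dominance duration (s)", y = "Density",
         title = sprintf("Best fit: %s", best)) +
    theme_minimal()
}

#' @rdname plv_timecourse
#' @param x A `plv_result`.
#' @param ... Unused.
#' @export
tidy.plv_result <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname ppc_timecourse
#' @param x A `ppc_result`.
#' @param ... Unused.
#' @export
tidy.ppc_result <- function(x, ...) as_tibble(unclass_result(x))

unclass_result <- function(x) {
  class(x) <- setdiff(class(x), c("plv_result", "ppc_result"))
  x
}
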