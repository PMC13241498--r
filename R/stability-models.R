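#' Akaike information criterion from a log-likelihood
#'
#' `AIC = 2k - 2 log L`.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters (`>= 1`).
#' @return Scalar AIC.
#' @export
#' @examples
#' aic_from_loglik(-10, 2) # 24
aic_from_loglik <- function(loglik, k) {
  stopifnot(k >= 1)
  2 * k - 2 * loglik
}

#' Two-model Akaike weight
#'
#' The conditional probability that the full model has more explanatory
#' power than the reduced model, given an AIC difference
#' `delta_aic = AIC(reduced) - AIC(full)`:
#' `w = 1 / (1 + exp(-delta_aic / 2))`. A difference of 9.2 corresponds to
#' a probability above 99%, a difference of 6 to about 95%.
#'
#' @param delta_aic AIC difference(s), reduced minus full.
#' @return Probability in (0, 1); 0.5 at `delta_aic = 0`.
#' @export
#' @examples
#' akaike_weight(c(0, 6, 9.2))
akaike_weight <- function(delta_aic) {
  1 / (1 + exp(-delta_aic / 2))
}

#' Build the time-resolved mixed-model design table
#'
#' One row per (reversal event, epoch timepoint) with all model variables:
#' percept stabilities normalised within participant by their mean and
#' log-transformed, respiration frequency z-scored within participant,
#' pupil size read from the within-participant z-scored cleaned trace at
#' the lagged time, respiration phase coded as its sine and cosine, and the
#' percept change as a two-level factor (destination percept). Events with
#' unassigned phase or missing pupil/frequency at a timepoint are dropped
#' at that timepoint. Participants with fewer than 2 usable events are
#' excluded.
#'
#' @param data Nested tibble with one row per participant and list-columns
#'   `events` (tibbles with `time_s`, `percept`, `reversal_number`,
#'   `stability_preceding`, `stability_subsequent`, `resp_freq`), `phase`
#'   (tibbles `(time_s, phase)`), and `pupil` (cleaned z-scored tibbles
#'   `(time_s, value)`; optional — omit the column to build a pupil-free
#'   design).
#' @param timepoints Epoch lags at which variables are sampled, seconds
#'   (default `seq(-4, 4, by = 0.2)`, 41 points).
#' @return Long tibble with columns `participant`, `reversal_number`,
#'   `time_s` (lag), `stability_preceding`, `stability_subsequent`
#'   (log mean-normalised), `resp_freq` (z), `pupil` (z; `NA` if no pupil
#'   data supplied), `sine`, `cosine`, `percept_change`.
#' @export
build_design_table <- function(data, timepoints = seq(-4, 4, by = 0.2)) {
  stopifnot(is.data.frame(data), all(c("events", "phase") %in% names(data)))
  has_pupil <- "pupil" %in% names(data)
  rows <- map(seq_len(nrow(data)), function(i) {
    ev <- data$events[[i]]
    if (is.null(ev) || nrow(ev) < 2) return(NULL)
    ph <- data$phase[[i]]
    pu <- if (has_pupil) data$pupil[[i]] else NULL
    pid <- if ("participant" %in% names(data)) data$participant[[i]]
           else if ("participant" %in% names(ev)) ev$participant[1] else i

    sp <- ev$stability_preceding / mean(ev$stability_preceding, na.rm = TRUE)
    ss <- ev$stability_subsequent / mean(ev$stability_subsequent, na.rm = TRUE)
    rf <- as.vector(scale(ev$resp_freq))

    sample_at <- function(df, col, times) {
      idx <- round((times - df$time_s[1]) * trace_fs(df)) + 1
      ok <- idx >= 1 & idx <= nrow(df)
      out <- rep(NA_real_, length(times))
      out[ok] <- df[[col]][idx[ok]]
      out
    }
    grid <- map(timepoints, function(lag) {
      tt <- ev$time_s + lag
      tibble(
        participant = pid,
        reversal_number = ev$reversal_number,
        time_s = lag,
        stability_preceding = log(sp),
        stability_subsequent = log(ss),
        resp_freq = rf,
        pupil = if (!is.null(pu)) sample_at(pu, "value", tt) else NA_real_,
        phase_at_t = sample_at(ph, "phase", tt),
        percept_change = if_else(ev$percept == "left", "right_to_left", "left_to_right")
      )
    })
    bind_rows(grid)
  })
  bind_rows(rows) |>
    mutate(sine = sin(.data$phase_at_t),
           cosine = cos(.data$phase_at_t),
           percept_change = factor(.data$percept_change,
                                   levels = c("right_to_left", "left_to_right"))) |>
    select(-"phase_at_t")
}

model_fixed_terms <- function(dependent) {
  switch(dependent,
    stability_preceding = c("resp_freq", "stability_subsequent", "pupil",
                            "percept_change", "sine", "cosine"),
    stability_subsequent = c("resp_freq", "stability_preceding", "pupil",
                             "percept_change", "sine", "cosine"),
    pupil = c("sine", "cosine", "resp_freq", "stability_preceding",
              "stability_subsequent", "percept_change"),
    abort(sprintf("unknown dependent variable '%s'", dependent))
  )
}

#' Time-resolved mixed-model comparison
#'
#' At each epoch timepoint, fits a full linear mixed model (maximum
#' likelihood, random intercepts for participant and reversal number) of
#' the chosen dependent variable on all remaining variables, plus one
#' reduced model per tested predictor with that predictor removed.
#' Respiration phase is tested by removing its sine and cosine terms
#' jointly, because its predictive power is shared between them. Evidence
#' per predictor is quantified as `delta_aic = AIC(reduced) - AIC(full)`
#' and the corresponding two-model Akaike weight; the full model's slopes,
#' standard errors, t-values, and normal-approximation p-values are also
#' returned.
#'
#' Maximum likelihood (not REML) is required for AIC comparisons across
#' fixed-effect structures. Timepoints where a fit fails to converge yield
#' missing values.
#'
#' @param design Design table from [build_design_table()].
#' @param dependent One of `"stability_preceding"`, `"stability_subsequent"`,
#'   `"pupil"`.
#' @param predictors Predictors to test by removal; default: respiration
#'   phase (sine + cosine jointly) plus every other fixed term. Use
#'   `"phase"` to denote the joint sine/cosine test.
#' @param min_rows Minimum complete rows per timepoint (default 50).
#' @return Object of class `model_comparison`: list with `comparisons`
#'   (tibble `dependent, predictor, time_s, aic_full, aic_reduced,
#'   delta_aic, akaike_weight, n`), `coefficients` (tibble `time_s, term,
#'   estimate, se, statistic, p_value`), and `dependent`.
#' @export
fit_stability_models <- function(design, dependent = "stability_preceding",
                                 predictors = NULL, min_rows = 50) {
  fixed <- model_fixed_terms(dependent)
  if (all(is.na(design$pupil)) && "pupil" %in% fixed) {
    fixed <- setdiff(fixed, "pupil")
  }
  if (is.null(predictors)) {
    predictors <- c("phase", setdiff(fixed, c("sine", "cosine")))
  }
  drop_terms <- function(pred) if (pred == "phase") c("sine", "cosine") else pred

  form <- function(terms) {
    stats::as.formula(paste(
      dependent, "~", paste(terms, collapse = " + "),
      "+ (1 | participant) + (1 | reversal_number)"
    ))
  }
  fit_one <- function(f, d) {
    tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(f, data = d, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))
      )),
      error = function(e) NULL
    )
  }

  timepoints <- sort(unique(design$time_s))
  comp <- list(); coefs <- list()
  used <- unique(c(dependent, fixed, "participant", "reversal_number"))
  for (tp in timepoints) {
    d <- design[design$time_s == tp, used, drop = FALSE]
    d <- d[complete.cases(d), , drop = FALSE]
    if (nrow(d) < min_rows) next
    full <- fit_one(form(fixed), d)
    if (is.null(full)) next
    aic_full <- AIC(full)
    fe <- lme4::fixef(full)
    se <- sqrt(diag(as.matrix(stats::vcov(full))))
    tv <- fe / se
    coefs[[length(coefs) + 1]] <- tibble(
      time_s = tp, term = names(fe), estimate = unname(fe), se = unname(se),
      statistic = unname(tv), p_value = 2 * pnorm(-abs(unname(tv)))
    )
    for (pred in predictors) {
      red_terms <- setdiff(fixed, drop_terms(pred))
      red <- fit_one(form(if (length(red_terms)) red_terms else "1"), d)
      aic_red <- if (is.null(red)) NA_real_ else AIC(red)
      comp[[length(comp) + 1]] <- tibble(
        dependent = dependent, predictor = pred, time_s = tp,
        aic_full = aic_full, aic_reduced = aic_red,
        delta_aic = aic_red - aic_full,
        akaike_weight = akaike_weight(aic_red - aic_full),
        n = nrow(d)
      )
    }
  }
  structure(
    list(comparisons = bind_rows(comp), coefficients = bind_rows(coefs),
         dependent = dependent),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> dependent: %s, %d timepoint(s)\n",
              x$dependent, length(unique(x$comparisons$time_s))))
  if (nrow(x$comparisons) > 0) {
    best <- x$comparisons |>
      group_by(.data$predictor) |>
      summarise(max_delta_aic = max(.data$delta_aic, na.rm = TRUE),
                .groups = "drop")
    for (i in seq_len(nrow(best))) {
      cat(sprintf("  %-22s max delta AIC = %7.2f (weight %.3f)\n",
                  best$predictor[i], best$max_delta_aic[i],
                  akaike_weight(best$max_delta_aic[i])))
    }
  }
  invisible(x)
}

#' @rdname fit_stability_models
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @export
tidy.model_comparison <- function(x, ...) x$comparisons

#' @rdname fit_stability_models
#' @export
glance.model_comparison <- function(x, ...) {
  x$comparisons |>
    group_by(dependent = .data$dependent, predictor = .data$predictor) |>
    summarise(max_delta_aic = max(.data$delta_aic, na.rm = TRUE),
              time_of_max = .data$time_s[which.max(.data$delta_aic)],
              max_akaike_weight = akaike_weight(max(.data$delta_aic, na.rm = TRUE)),
              .groups = "drop")
}

#' Table of fixed-effect estimates at the timepoint of maximal evidence
#'
#' For each tested predictor, reports the full-model slope, SE, t and
#' p-value at the timepoint where its AIC evidence peaks.
#'
#' @param x A `model_comparison`.
#' @return Tibble `(dependent, predictor, time_s, delta_aic, akaike_weight,
#'   term, estimate, se, statistic, p_value)`.
#' @export
peak_effect_table <- function(x) {
  stopifnot(inherits(x, "model_comparison"))
  g <- glance(x)
  bind_rows(map(seq_len(nrow(g)), function(i) {
    pred <- g$predictor[i]; tp <- g$time_of_max[i]
    terms <- if (pred == "phase") c("sine", "cosine") else pred
    cc <- x$coefficients |>
      filter(.data$time_s == tp, grepl(paste(terms, collapse = "|"), .data$term))
    if (nrow(cc) == 0) return(NULL)
    tibble(dependent = x$dependent, predictor = pred, time_s = tp,
           delta_aic = g$max_delta_aic[i], akaike_weight = g$max_akaike_weight[i],
           term = cc$term, estimate = cc$estimate, se = cc$se,
           statistic = cc$statistic, p_value = cc$p_value)
  }))
}
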