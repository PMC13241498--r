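#' Run the full analysis pipeline on simulated or loaded data
#'
#' Orchestrates simulation, respiration and pupil preprocessing,
#' behavioural quality control, event-locked phase locking with its
#' surrogate null, the cluster-based permutation test of the event-locked
#' pupil trace, and the time-resolved mixed-model comparison. Every tunable
#' is surfaced as an argument with the analysis defaults (peak threshold
#' z = 0.5, 3 SD atypical-cycle rejection, +-4 s epochs, 0.2 s model grid,
#' 4000 surrogate shifts, 20000 permutations, +-2 s purity window,
#' 120/900 reversal-count bounds).
#'
#' @param config A [sim_config()] describing the synthetic study, or a
#'   `sim_study` / [read_study()] result to analyse directly.
#' @param stages Character vector of stages to run after simulation; any of
#'   `"phase_locking"`, `"pupil"`, `"models"`. Behavioural QC always runs.
#'   When `"pupil"` is disabled, model comparisons involving pupil size are
#'   skipped and flagged in the report.
#' @param n_shifts Surrogate iterations for the PLV null.
#' @param n_permutations Sign-flip permutations for the cluster test.
#' @param model_timepoints Lags (s) for the mixed-model grid.
#' @param model_dependents Dependent variables to model.
#' @param purity_half_window Isolation window for epoch cleaning, seconds.
#' @param exclusion_bounds Min/max reversal counts kept, `c(120, 900)`.
#' @param outdir Optional output directory for TSV/JSON reports.
#' @return List of class `resplock_report` with elements `qc`, `behavior`,
#'   `phase_locking`, `ppc`, `pupil_cluster`, `models`, and `settings`.
#' @export
run_pipeline <- function(config = sim_config(),
                         stages = c("phase_locking", "pupil", "models"),
                         n_shifts = 4000,
                         n_permutations = 20000,
                         model_timepoints = seq(-4, 4, by = 0.2),
                         model_dependents = c("stability_preceding",
                                              "stability_subsequent", "pupil"),
                         purity_half_window = 2,
                         exclusion_bounds = c(120, 900),
                         outdir = NULL) {
  study <- if (inherits(config, "sim_study")) config else {
    set.seed(config$seed)
    simulate_study(config)
  }
  do_pupil <- "pupil" %in% stages
  do_plv <- "phase_locking" %in% stages
  do_models <- "models" %in% stages

  # --- preprocessing -------------------------------------------------------
  proc <- map(study, function(p) {
    resp <- respiration_pipeline(p$respiration)
    pupil <- if (do_pupil) pupil_pipeline(p$pupil) else NULL
    events <- p$events |>
      mutate(resp_freq = respiration_frequency_before(.data$time_s, resp$cycles))
    list(participant = p$participant, resp = resp, pupil = pupil, events = events)
  })

  # --- behavioural QC ------------------------------------------------------
  all_events <- bind_rows(map(proc, "events"))
  counts <- apply_exclusions(all_events, exclusion_bounds[1], exclusion_bounds[2])
  kept_ids <- counts$participant[counts$kept]
  proc <- proc[map_int(proc, "participant") %in% kept_ids]
  all_events <- all_events |> filter(.data$participant %in% kept_ids)
  isolated <- clean_epochs(all_events, purity_half_window)

  pooled_fits <- fit_interval_distributions(
    na.omit(all_events$stability_preceding))
  summaries <- all_events |>
    group_by(.data$participant) |>
    summarise(
      mean_stability_left = mean(.data$stability_preceding[.data$percept == "right"], na.rm = TRUE),
      mean_stability_right = mean(.data$stability_preceding[.data$percept == "left"], na.rm = TRUE),
      n_first_half = sum(.data$trial <= max(.data$trial) / 2),
      n_second_half = sum(.data$trial > max(.data$trial) / 2),
      n_reversals = n(), .groups = "drop")

  qc <- list(
    counts = counts,
    n_kept_participants = length(kept_ids),
    n_events_total = nrow(all_events),
    n_events_isolated = nrow(isolated),
    isolated_fraction = nrow(isolated) / max(nrow(all_events), 1)
  )

  # --- phase locking -------------------------------------------------------
  plv <- NULL; ppc_tbl <- NULL; peak_coh <- NULL
  if (do_plv && length(proc) >= 2) {
    nested <- tibble(
      participant = map_int(proc, "participant"),
      phase = map(proc, ~ .x$resp$phase),
      events = map(proc, ~ .x$events$time_s)
    )
    plv <- plv_surrogate_test(nested, n_shifts = n_shifts)
    ppc_tbl <- bind_rows(map(proc, function(p) {
      ep <- epoch_around_events(p$resp$phase, p$events$time_s)
      ppc_timecourse(ep) |> mutate(participant = p$participant)
    }))
    # within-participant coherence at the group-level peak time
    peak_t <- plv$group$time_s[which.max(plv$group$plv_mean)]
    peak_coh <- tibble(
      participant = map_int(proc, "participant"),
      peak_coherence = plv$participant_plv[, which.max(plv$group$plv_mean)]
    )
    summaries <- left_join(summaries, peak_coh, by = "participant")
  }
  behavior <- list(pooled_fits = pooled_fits,
                   group_tests = group_behavior_tests(summaries),
                   summaries = summaries)

  # --- event-locked pupil --------------------------------------------------
  cluster <- NULL
  if (do_pupil && length(proc) >= 5) {
    pm <- map(proc, function(p) {
      ep <- epoch_around_events(p$pupil, p$events$time_s)
      colMeans(ep$data, na.rm = TRUE)
    })
    mat <- do.call(rbind, pm)
    grid <- seq(-EPOCH_HALF_WINDOW, EPOCH_HALF_WINDOW, by = 1 / EPOCH_FS)
    cluster <- cluster_permutation_test(mat, time_s = grid,
                                        n_permutations = n_permutations)
  }

  # --- mixed models --------------------------------------------------------
  models <- NULL; skipped <- character()
  if (do_models) {
    nested <- tibble(
      participant = map_int(proc, "participant"),
      events = map(proc, "events"),
      phase = map(proc, ~ .x$resp$phase)
    )
    if (do_pupil) nested$pupil <- map(proc, "pupil")
    design <- build_design_table(nested, timepoints = model_timepoints)
    deps <- model_dependents
    if (!do_pupil && "pupil" %in% deps) {
      deps <- setdiff(deps, "pupil")
      skipped <- c(skipped, "pupil (pupil stage disabled)")
    }
    models <- map(deps, ~ fit_stability_models(design, dependent = .x))
    names(models) <- deps
  }

  report <- structure(
    list(qc = qc, behavior = behavior, phase_locking = plv, ppc = ppc_tbl,
         pupil_cluster = cluster, models = models,
         settings = list(stages = stages, n_shifts = n_shifts,
                         n_permutations = n_permutations,
                         model_timepoints = model_timepoints,
                         purity_half_window = purity_half_window,
                         exclusion_bounds = exclusion_bounds,
                         skipped = skipped)),
    class = "resplock_report"
  )
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.resplock_report <- function(x, ...) {
  cat("<resplock_report>\n")
  cat(sprintf("  participants kept: %d; reversals: %d (%.0f%% isolated at +-%g s)\n",
              x$qc$n_kept_participants, x$qc$n_events_total,
              100 * x$qc$isolated_fraction, x$settings$purity_half_window))
  cat(sprintf("  best-fitting duration distribution: %s\n",
              x$behavior$pooled_fits$family[1]))
  if (!is.null(x$phase_locking)) print(x$phase_locking)
  if (!is.null(x$ppc)) {
    g <- x$ppc |> group_by(.data$participant) |>
      summarise(m = mean(.data$ppc, na.rm = TRUE), .groups = "drop")
    cat(sprintf("  mean PPC across participants: %.4f +/- %.4f (SEM)\n",
                mean(g$m), sd(g$m) / sqrt(nrow(g))))
  }
  if (!is.null(x$pupil_cluster)) print(x$pupil_cluster)
  if (!is.null(x$models)) for (m in x$models) print(m)
  invisible(x)
}

#' Write a pipeline report to TSV/JSON files
#'
#' @param report A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(n_kept_participants = report$qc$n_kept_participants,
         n_events_total = report$qc$n_events_total,
         n_events_isolated = report$qc$n_events_isolated,
         isolated_fraction = report$qc$isolated_fraction,
         counts = report$qc$counts),
    file.path(outdir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
  wtsv(report$behavior$pooled_fits |> select(-"params"), "interval_fits.tsv")
  wtsv(report$behavior$group_tests, "group_tests.tsv")
  if (!is.null(report$phase_locking)) {
    g <- report$phase_locking$group |>
      mutate(thr05 = report$phase_locking$thresholds[["p05"]],
             thr01 = report$phase_locking$thresholds[["p01"]])
    wtsv(g, "plv_group.tsv")
  }
  if (!is.null(report$ppc)) wtsv(report$ppc, "ppc_participants.tsv")
  if (!is.null(report$pupil_cluster)) wtsv(tidy(report$pupil_cluster), "clusters.tsv")
  if (!is.null(report$models)) {
    wtsv(bind_rows(map(report$models, tidy)), "model_comparison.tsv")
    wtsv(bind_rows(map(report$models, peak_effect_table)), "table1_style.tsv")
  }
  results <- list(
    qc = report$qc[c("n_kept_participants", "n_events_total", "n_events_isolated")],
    best_duration_family = report$behavior$pooled_fits$family[1],
    phase_locking = if (!is.null(report$phase_locking)) glance(report$phase_locking),
    pupil_cluster = if (!is.null(report$pupil_cluster)) glance(report$pupil_cluster),
    models = if (!is.null(report$models)) bind_rows(map(report$models, glance)),
    skipped = report$settings$skipped
  )
  jsonlite::write_json(results, file.path(outdir, "results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(outdir)
}
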