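#' Simulate one participant's full recording
#'
#' @param config A [sim_config()].
#' @param participant Participant index.
#' @return A list with elements `respiration` (tibble `time_s, value`),
#'   `pupil` (tibble `time_s, value`, `NA` during blinks), `events`
#'   (reversal tibble), `truth` (list of ground-truth `phase` tibble and
#'   `cycles` tibble), and `participant`.
#' @export
simulate_participant <- function(config, participant = 1L) {
  resp <- simulate_respiration(config, participant)
  events <- simulate_reversals(config, resp, participant)
  pupil <- simulate_pupil(config, events, resp, participant)
  list(participant = as.integer(participant),
       respiration = resp$trace,
       pupil = pupil,
       events = events,
       truth = list(phase = resp$phase, cycles = resp$cycles))
}

#' Simulate a multi-participant study
#'
#' Applies [simulate_participant()] for `config$n_participants` independent
#' random streams derived from the single global seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_study`: one [simulate_participant()] result
#'   per participant.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_participants = 2, n_trials = 1, seed = 7))
#' length(study)
simulate_study <- function(config) {
  validate_sim_config(config)
  out <- map(seq_len(config$n_participants), ~ simulate_participant(config, .x))
  structure(out, class = "sim_study", config = config)
}

#' @export
print.sim_study <- function(x, ...) {
  cfg <- attr(x, "config")
  n_ev <- sum(map_int(x, ~ nrow(.x$events)))
  cat(sprintf("<sim_study> %d participant(s), %d reversal(s) total, seed = %d\n",
              length(x), n_ev, cfg$seed))
  invisible(x)
}

#' Write a simulated study to plain-text files
#'
#' Emits, per participant, `resp_<id>.tsv` and `pupil_<id>.tsv` with columns
#' `(time_s, value)`, `events_<id>.tsv` with `(time_s, percept, trial)`, and
#' `ground_truth_<id>.json` with cycle boundaries and true phases.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (p in study) {
    id <- p$participant
    utils::write.table(p$respiration, file.path(dir, sprintf("resp_%02d.tsv", id)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(p$pupil, file.path(dir, sprintf("pupil_%02d.tsv", id)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(p$events[, c("time_s", "percept", "trial")],
                       file.path(dir, sprintf("events_%02d.tsv", id)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(cycles = p$truth$cycles, phase = p$truth$phase),
      file.path(dir, sprintf("ground_truth_%02d.json", id)),
      digits = NA, dataframe = "columns"
    )
  }
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory containing the per-participant TSV/JSON files.
#' @return A `sim_study`-like list (without the `config` attribute); the
#'   `truth` element is present only if ground-truth sidecars exist.
#' @export
read_study <- function(dir) {
  ids <- sort(unique(sub("^resp_(\\d+)\\.tsv$", "\\1",
                         basename(Sys.glob(file.path(dir, "resp_*.tsv"))))))
  if (length(ids) == 0) abort(sprintf("no resp_<id>.tsv files found in %s", dir))
  read_tsv0 <- function(f) as_tibble(utils::read.delim(f))
  out <- map(ids, function(id) {
    events <- read_tsv0(file.path(dir, sprintf("events_%s.tsv", id))) |>
      mutate(participant = as.integer(id), reversal_number = row_number()) |>
      compute_stabilities()
    truth <- NULL
    gt <- file.path(dir, sprintf("ground_truth_%s.json", id))
    if (file.exists(gt)) {
      j <- jsonlite::read_json(gt, simplifyVector = TRUE)
      truth <- list(phase = as_tibble(j$phase), cycles = as_tibble(j$cycles))
    }
    list(participant = as.integer(id),
         respiration = read_tsv0(file.path(dir, sprintf("resp_%s.tsv", id))),
         pupil = read_tsv0(file.path(dir, sprintf("pupil_%s.tsv", id))),
         events = events,
         truth = truth)
  })
  structure(out, class = "sim_study")
}
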