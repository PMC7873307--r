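# Plain-text serialization of session bundles and analysis tables:
# trial tables and summaries as CSV, ground truth and parameters as JSON,
# configuration snapshots as YAML.

TRIAL_COLUMNS <- c("session_id", "block_id", "block_type",
                   "trial_index_in_block", "object_left", "object_right",
                   "chosen_action", "chosen_object", "reward",
                   "reaction_time", "reversal_trial")

#' Write a trial table to CSV
#'
#' Serializes the behavioural trial table with its documented column set
#' (extra columns such as the agent's value traces are kept).
#'
#' @param trials Trial table data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols)) {
    stop("trial table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Reads a CSV written by [write_trial_table()] and validates the trial-table
#' invariants: required columns present, one reversal trial per block within
#' 30..50, trial indices 1..n without gaps, and chosen object consistent with
#' chosen action and the object placement.
#'
#' @param path CSV path.
#' @return Validated trial table data.frame.
#' @export
read_trial_table <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols)) {
    stop("trial table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_trial_table(trials)
  trials
}

#' Validate trial-table invariants
#'
#' Checks block structure (contiguous 1..n trial indices, a single reversal
#' trial within the allowed range per block) and the consistency of chosen
#' object, chosen action and object placement on every trial.
#'
#' @param trials Trial table.
#' @param reversal_range Allowed inclusive reversal range.
#' @return `trials`, invisibly; errors describe the first violated invariant.
#' @export
validate_trial_table <- function(trials, reversal_range = c(30L, 50L)) {
  for (b in split(trials, paste(trials$session_id, trials$block_id))) {
    idx <- sort(b$trial_index_in_block)
    if (!identical(idx, seq_len(nrow(b)))) {
      stop("block ", b$block_id[1], ": trial indices do not cover 1..",
           nrow(b), " without gaps")
    }
    rev <- unique(b$reversal_trial)
    if (length(rev) != 1L || rev < reversal_range[1] || rev > reversal_range[2]) {
      stop("block ", b$block_id[1], ": needs exactly one reversal trial in ",
           reversal_range[1], "..", reversal_range[2])
    }
  }
  side_obj <- ifelse(trials$chosen_action == "left",
                     trials$object_left, trials$object_right)
  if (!all(side_obj == trials$chosen_object)) {
    stop("chosen_object inconsistent with chosen_action and object placement")
  }
  if (!all(trials$reward %in% c(0, 1))) stop("reward must be 0/1")
  invisible(trials)
}

#' Write a session bundle to a directory
#'
#' Writes `trials.csv`, `ground_truth.json` (per-neuron tuning, coupling
#' spec, agent parameters, seed), a `config.yaml` snapshot, and — when the
#' session carries spike times — `spikes.csv` (`trial_id`, `neuron_id`,
#' `time_ms`). Binned tensors are not serialized; they are regenerated from
#' the seed or rebuilt from the spike times.
#'
#' @param session An `lpfc_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trial_table(session$trials, file.path(dir, "trials.csv"))
  truth <- session$truth
  truth$latents <- NULL
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- session$config
  cfg$layout <- as.list(cfg$layout)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  if (!is.null(session$spike_times)) {
    utils::write.csv(session$spike_times, file.path(dir, "spikes.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
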