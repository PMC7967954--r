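# CSV interchange schemas (version 1):
#   trials.csv     session_id, cell_id, trial_id, condition, direction,
#                  outcome, trial_start_s, stim_onset_s, change_time_s
#   spikes.csv     cell_id, trial_id, spike_time_s
#   injections.csv session_id, time_s, substance, concentration_mol_l,
#                  volume_nl
# plus manifest.json (schema_version) and, for generated data only,
# ground_truth.json with the per-cell true gains. Times are seconds as
# decimals on the session clock; change_time_s is relative to stimulus
# onset and empty for catch trials.

SCHEMA_VERSION <- 1L

TRIALS_COLS <- c("session_id", "cell_id", "trial_id", "condition",
                 "direction", "outcome", "trial_start_s", "stim_onset_s",
                 "change_time_s")
SPIKES_COLS <- c("cell_id", "trial_id", "spike_time_s")
INJECTIONS_COLS <- c("session_id", "time_s", "substance",
                     "concentration_mol_l", "volume_nl")

CONDITIONS <- c("attend-in", "attend-out", "attend-fix", "fix-only")
DIRECTIONS <- c("preferred", "null", "none")
OUTCOMES <- c("hit", "miss", "false-alarm", "abort")

schema_check <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("schema violation in %s: missing column(s) %s",
                 file, paste(missing, collapse = ", ")))
}

label_check <- function(values, allowed, file, column) {
  bad <- !values %in% allowed & !is.na(values)
  if (any(bad))
    stop(sprintf("schema violation in %s, column %s, row(s) %s: unknown label %s",
                 file, column,
                 paste(utils::head(which(bad), 5), collapse = ", "),
                 paste(utils::head(unique(values[bad]), 5), collapse = ", ")))
}

#' Validate a session's tables
#'
#' Checks schema columns, label vocabularies, cross-references (every spike
#' must belong to an existing trial), the fix-only/direction constraint, and
#' monotone injection times per session. Called by [read_session()]; can be
#' used directly on in-memory tables.
#'
#' @param trials,spikes,injections The three interchange tables.
#' @return Invisibly `TRUE`; errors name the offending file, row and column.
#' @export
validate_session <- function(trials, spikes, injections) {
  schema_check(trials, TRIALS_COLS, "trials.csv")
  schema_check(spikes, SPIKES_COLS, "spikes.csv")
  schema_check(injections, INJECTIONS_COLS, "injections.csv")
  label_check(trials$condition, CONDITIONS, "trials.csv", "condition")
  label_check(trials$direction, DIRECTIONS, "trials.csv", "direction")
  label_check(trials$outcome, OUTCOMES, "trials.csv", "outcome")
  if (anyDuplicated(trials$trial_id))
    stop("schema violation in trials.csv: duplicated trial_id")
  fix_bad <- trials$condition == "fix-only" & trials$direction != "none"
  if (any(fix_bad))
    stop(sprintf("schema violation in trials.csv, row(s) %s: fix-only trials must have direction 'none'",
                 paste(utils::head(which(fix_bad), 5), collapse = ", ")))
  orphans <- setdiff(unique(spikes$trial_id), trials$trial_id)
  if (length(orphans))
    stop(sprintf("spikes.csv references unknown trial_id(s): %s",
                 paste(utils::head(orphans, 5), collapse = ", ")))
  if (nrow(injections)) {
    for (sid in unique(injections$session_id)) {
      ts <- injections$time_s[injections$session_id == sid]
      if (length(ts) > 1 && any(diff(ts) <= 0))
        stop(sprintf("schema violation in injections.csv: times for session %s not strictly increasing", sid))
    }
  }
  invisible(TRUE)
}

#' Write a session to an interchange directory
#'
#' Writes `trials.csv`, `spikes.csv`, `injections.csv`, a `manifest.json`
#' carrying the schema version, and — when the session carries generator
#' ground truth — `ground_truth.json` with each cell's true gains for
#' recovery tests.
#'
#' @param session An `attnpharm_session` (from [generate_session()] or
#'   [read_session()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(session$spikes, file.path(dir, "spikes.csv"),
                   row.names = FALSE)
  utils::write.csv(session$injections, file.path(dir, "injections.csv"),
                   row.names = FALSE)
  manifest <- list(schema_version = SCHEMA_VERSION,
                   package = "attnpharm",
                   package_version = as.character(utils::packageVersion("attnpharm")),
                   seed = session$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(session$ground_truth))
    jsonlite::write_json(session$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         dataframe = "rows", pretty = TRUE, digits = NA)
  invisible(dir)
}

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and validate a session directory
#'
#' Loads the three interchange CSVs, rejects unknown schema versions, and
#' cross-validates the tables with [validate_session()]. A
#' `ground_truth.json`, when present, is attached.
#'
#' @param dir Directory containing `trials.csv`, `spikes.csv`,
#'   `injections.csv` and optionally `manifest.json` / `ground_truth.json`.
#' @return An object of class `attnpharm_session`.
#' @export
read_session <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path)
    if (!identical(as.integer(manifest$schema_version), SCHEMA_VERSION))
      stop("unknown schema version: ", manifest$schema_version,
           " (this package reads version ", SCHEMA_VERSION, ")")
  }
  trials <- read_csv_strict(file.path(dir, "trials.csv"))
  spikes <- read_csv_strict(file.path(dir, "spikes.csv"))
  injections <- read_csv_strict(file.path(dir, "injections.csv"))
  validate_session(trials, spikes, injections)
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::fromJSON(truth_path) else NULL
  structure(list(trials = trials, spikes = spikes, injections = injections,
                 ground_truth = truth, config = NULL, seed = NA_integer_),
            class = "attnpharm_session")
}

#' Assign blocks across all sessions of a dataset
#'
#' Builds a [session_timeline()] per session from the injection table and
#' applies [assign_blocks()], so multi-session datasets (one cell per
#' session) get consistent labels.
#'
#' @param trials Trial table with `session_id`, `trial_id`, `trial_start_s`.
#' @param injections Injection table (`session_id`, `time_s`).
#' @param latency Block-boundary latency in seconds (default 150).
#' @param cycle_gap Gap that separates injection cycles (default twice the
#'   latency).
#' @return Character vector of block labels aligned with `trials` rows.
#' @export
assign_blocks_all <- function(trials, injections, latency = 150,
                              cycle_gap = 2 * latency) {
  block <- character(nrow(trials))
  for (sid in unique(trials$session_id)) {
    sel <- trials$session_id == sid
    tl <- session_timeline(injections$time_s[injections$session_id == sid],
                           latency = latency, cycle_gap = cycle_gap)
    block[sel] <- as.character(assign_blocks(trials[sel, , drop = FALSE], tl)$block)
  }
  block
}
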