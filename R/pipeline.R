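#' Run configuration
#'
#' Collects everything needed for a reproducible end-to-end run. Exactly one
#' input source must be given: either `input_dir` (an interchange directory,
#' see [read_session()]) or `generator` (a list of [generator_config()]
#' arguments for a simulated dataset).
#'
#' @param input_dir Directory with `trials.csv` / `spikes.csv` /
#'   `injections.csv`, or `NULL` to simulate.
#' @param generator List of arguments for [generator_config()], or `NULL`.
#' @param outdir Output directory for result tables and the run log.
#' @param window_ms Analysis window in ms after stimulus onset.
#' @param latency_s Block-boundary latency in seconds.
#' @param alpha Significance level used by every test.
#' @param substance_filter,concentration_filter Optional restriction to
#'   sessions whose injections match the given substance and/or concentration
#'   (mol/l), e.g. to rerun the analysis at the highest concentration only.
#' @param seed Integer seed controlling all randomness of the run.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, generator = NULL,
                       outdir = "attnpharm-out", window_ms = c(300, 800),
                       latency_s = 150, alpha = 0.05,
                       substance_filter = NULL, concentration_filter = NULL,
                       seed = 1L) {
  if (is.null(input_dir) == is.null(generator))
    stop("exactly one of input_dir or generator must be given")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  seed <- as.integer(seed)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file holds the fields of [run_config()]; entries in `...` override
#' file values (command-line override mechanism used by the CLI script).
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file contents.
#' @return Object of class `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  vals <- vals[names(vals) %in% names(formals(run_config))]
  do.call(run_config, vals)
}

filter_sessions <- function(session, substance = NULL, concentration = NULL) {
  inj <- session$injections
  keep <- rep(TRUE, nrow(inj))
  if (!is.null(substance)) keep <- keep & inj$substance == substance
  if (!is.null(concentration))
    keep <- keep & abs(inj$concentration_mol_l - concentration) < 1e-12
  sids <- unique(inj$session_id[keep])
  session$trials <- session$trials[session$trials$session_id %in% sids, , drop = FALSE]
  session$spikes <- session$spikes[session$spikes$trial_id %in%
                                     session$trials$trial_id, , drop = FALSE]
  session$injections <- inj[inj$session_id %in% sids, , drop = FALSE]
  if (!is.null(session$ground_truth))
    session$ground_truth <- session$ground_truth[
      session$ground_truth$session_id %in% sids, , drop = FALSE]
  session
}

#' Run the full analysis pipeline
#'
#' Generation (or loading) and validation of the session tables, per-trial
#' window rates, block segmentation, the two-stage inclusion report, per-cell
#' modulation indices, and the population summary — written as CSV tables
#' plus a human-readable markdown report and a run log sufficient to
#' reproduce the run (config echo, seed, package version, per-stage counts).
#'
#' @param config A [run_config()], or a path to a YAML file holding one.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results (`session`, `rates`,
#'   `inclusion`, `indices`, `population`, `psth`) and `outdir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  info <- function(...) if (!quiet) message(sprintf(...))
  log_lines <- character(0)
  log <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    info("%s", line)
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$generator)) {
    gcfg <- do.call(generator_config, config$generator)
    session <- generate_session(gcfg, seed = config$seed)
    write_session(session, file.path(config$outdir, "input"))
    log("simulated %d cells (%d trials, %d spikes), seed %d",
        nrow(session$ground_truth), nrow(session$trials),
        nrow(session$spikes), config$seed)
  } else {
    session <- read_session(config$input_dir)
    log("loaded %s: %d trials, %d spikes", config$input_dir,
        nrow(session$trials), nrow(session$spikes))
  }
  validate_session(session$trials, session$spikes, session$injections)

  if (!is.null(config$substance_filter) || !is.null(config$concentration_filter)) {
    n0 <- length(unique(session$trials$cell_id))
    session <- filter_sessions(session, config$substance_filter,
                               config$concentration_filter)
    log("substance/concentration filter kept %d of %d cells",
        length(unique(session$trials$cell_id)), n0)
    if (nrow(session$trials) == 0) stop("filter removed every session")
  }

  rt <- window_rates(session$trials, session$spikes, config$window_ms)
  rt$block <- assign_blocks_all(session$trials, session$injections,
                                latency = config$latency_s)
  rt$subject <- sub("-.*$", "", rt$session_id)
  log("block assignment: %s",
      paste(names(table(rt$block)), table(rt$block), sep = "=", collapse = ", "))

  n_all <- nrow(rt)
  rt_hits <- rt[rt$outcome == "hit", , drop = FALSE]
  log("outcome filter: %d of %d trials are hits", nrow(rt_hits), n_all)

  inclusion <- inclusion_report(rt_hits, alpha = config$alpha)
  log("criterion 1: %d of %d cells pass; injection effect: %s",
      sum(inclusion$pass), nrow(inclusion),
      paste(names(table(inclusion$injection_effect)),
            table(inclusion$injection_effect), sep = "=", collapse = ", "))

  indices <- modulation_indices(rt_hits)
  substance <- if (nrow(session$injections))
    session$injections$substance[1] else "none"
  indices_out <- cbind(substance = substance, indices)
  population <- summarize_population(indices, inclusion, alpha = config$alpha)
  psth <- psth_table(rt_hits, session$spikes)

  utils::write.csv(inclusion, file.path(config$outdir, "inclusion_report.csv"),
                   row.names = FALSE)
  utils::write.csv(indices_out, file.path(config$outdir, "indices.csv"),
                   row.names = FALSE)
  utils::write.csv(population, file.path(config$outdir, "population_results.csv"),
                   row.names = FALSE)
  utils::write.csv(psth, file.path(config$outdir, "psth.csv"),
                   row.names = FALSE)

  report <- c(population_report(population, substance), "",
              "## Inclusion funnel", "",
              sprintf("- cells analyzed: %d", nrow(inclusion)),
              sprintf("- passing criterion 1: %d", sum(inclusion$pass)),
              sprintf("- significant injection effect: %d (increase %d, decrease %d)",
                      sum(inclusion$injection_effect != "none"),
                      sum(inclusion$injection_effect == "increase"),
                      sum(inclusion$injection_effect == "decrease")))
  writeLines(report, file.path(config$outdir, "run_report.md"))

  cfg_echo <- config
  cfg_echo$generator <- NULL
  writeLines(c(
    sprintf("attnpharm %s", as.character(utils::packageVersion("attnpharm"))),
    sprintf("seed: %d", config$seed),
    "config:",
    strsplit(yaml::as.yaml(lapply(unclass(config), function(x)
      if (is.null(x)) NA else x)), "\n")[[1]],
    "stages:", paste0("  ", log_lines)
  ), file.path(config$outdir, "run_log.txt"))

  invisible(list(session = session, rates = rt, inclusion = inclusion,
                 indices = indices_out, population = population, psth = psth,
                 outdir = config$outdir))
}
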