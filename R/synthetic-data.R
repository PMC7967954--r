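# Synthetic spike-train sessions with known attention gain and injection
# effect. One cell per session; each session runs a control block, an
# injection block delimited by periodic injection events, and a recovery
# block. Spiking is homogeneous Poisson within trial epochs (pre-stimulus
# vs. stimulus) with piecewise-constant rates, the simplest model under
# which the attentional index has a closed-form expectation (g-1)/(g+1)
# for a multiplicative gain g on a common baseline.

STIM_ONSET_S <- 0.15 + 0.15 + 0.35  # fixation delay + cue + inter-stimulus interval

trial_types <- function() {
  data.frame(
    condition = c("attend-in", "attend-out", "attend-fix", "attend-fix",
                  "fix-only"),
    direction = c("preferred", "preferred", "preferred", "null", "none"),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic session generator
#'
#' Defaults emulate the study conditions of a cholinergic pressure-injection
#' experiment in extrastriate cortex: a preferred-stimulus sensory response
#' around 20 spikes/s, a multiplicative spatial-attention gain of 1.25
#' (index 0.111, i.e. 25% rate increase), direction-selective responses
#' (null-direction rate well below preferred), low fixation-only activity,
#' injections once per minute, and a sign-mixed multiplicative injection
#' effect in which roughly 40% of cells are affected with slightly more
#' decreases than increases.
#'
#' @param n_cells Number of cells (one session each).
#' @param baseline_rate Preferred-stimulus response with attention directed
#'   away (spikes/s); must be positive.
#' @param attention_gain Multiplier applied to `baseline_rate` in attend-in
#'   trials; must be positive.
#' @param attention_gain_injection Attention gain during the injection-effect
#'   period; `NULL` (default) means unchanged from `attention_gain`. Setting
#'   it different from `attention_gain` simulates a substance that alters
#'   attentional modulation, for power analyses.
#' @param null_rate Response to the null motion direction (spikes/s).
#' @param fix_only_rate Activity with only the fixation point shown, also the
#'   pre-stimulus background rate of every trial (spikes/s).
#' @param injection_mixture Named proportions (`increase`, `decrease`,
#'   `none`) of cells whose rates are multiplied by the respective injection
#'   gain; must sum to 1.
#' @param injection_gains Named multipliers (`increase` > 1, `decrease` < 1)
#'   applied to all epoch rates of affected cells during the injection-effect
#'   period.
#' @param injection_times Optional explicit injection times (s from session
#'   start, strictly increasing). Default `NULL` places injections
#'   automatically every `injection_interval_s` so that each block receives
#'   exactly `trials_per_condition_per_block` trials per trial type.
#' @param injection_interval_s Spacing of automatic injections (s).
#' @param effect_latency_s Delay between the first injection and the onset of
#'   the drug effect (s). The effect is a step function: rates switch at
#'   `first injection + effect_latency_s` and switch back at
#'   `last injection + washout_s`.
#' @param washout_s Persistence of the effect after the last injection (s).
#' @param trials_per_condition_per_block Trials per trial type per block.
#' @param catch_fraction Proportion of trials with no target change,
#'   allocated as an exact per-type floor count, not by coin flips.
#' @param change_window_ms Target-change window, within \[200, 2500\] ms
#'   after stimulus onset.
#' @param iti_s Inter-trial interval (s).
#' @param response_window_s Time allowed after the change before the trial
#'   ends (s); also guarantees spiking covers the full analysis window.
#' @param abort_fraction Proportion of trials marked `abort` (excluded by
#'   analysis); default 0 so generated sessions contain hits only.
#' @param substance,concentration_mol_l,volume_nl Injection metadata.
#' @param subjects Subject labels cycled across cells (cross-subject pooling
#'   checks need at least two).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_cells = 20,
                             baseline_rate = 20,
                             attention_gain = 1.25,
                             attention_gain_injection = NULL,
                             null_rate = 8,
                             fix_only_rate = 5,
                             injection_mixture = c(increase = 0.18,
                                                   decrease = 0.22,
                                                   none = 0.60),
                             injection_gains = c(increase = 1.5,
                                                 decrease = 0.6),
                             injection_times = NULL,
                             injection_interval_s = 60,
                             effect_latency_s = 150,
                             washout_s = 150,
                             trials_per_condition_per_block = 15,
                             catch_fraction = 0.1,
                             change_window_ms = c(200, 2500),
                             iti_s = 1.5,
                             response_window_s = 0.6,
                             abort_fraction = 0,
                             substance = "scopolamine",
                             concentration_mol_l = 0.1,
                             volume_nl = 4,
                             subjects = c("P", "O")) {
  cfg <- structure(as.list(environment()), class = "generator_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (n_cells < 1) stop("configuration error: n_cells must be at least 1")
    if (baseline_rate <= 0 || null_rate <= 0 || fix_only_rate <= 0)
      stop("configuration error: all rates must be positive")
    if (attention_gain <= 0)
      stop("configuration error: attention_gain must be positive")
    if (!is.null(attention_gain_injection) && attention_gain_injection <= 0)
      stop("configuration error: attention_gain_injection must be positive")
    if (catch_fraction < 0 || catch_fraction > 1)
      stop("configuration error: catch_fraction must be in [0, 1]")
    if (abort_fraction < 0 || abort_fraction >= 1)
      stop("configuration error: abort_fraction must be in [0, 1)")
    if (length(change_window_ms) != 2 ||
        change_window_ms[1] < 200 || change_window_ms[2] > 2500 ||
        diff(change_window_ms) <= 0)
      stop("configuration error: change window must lie within [200, 2500] ms")
    if (!setequal(names(injection_mixture), c("increase", "decrease", "none")) ||
        any(injection_mixture < 0) ||
        abs(sum(injection_mixture) - 1) > 1e-8)
      stop("configuration error: injection mixture proportions must be named ",
           "increase/decrease/none and sum to 1")
    if (injection_gains[["increase"]] <= 1 || injection_gains[["decrease"]] >= 1 ||
        injection_gains[["decrease"]] <= 0)
      stop("configuration error: injection gains must satisfy increase > 1, ",
           "0 < decrease < 1")
    if (!is.null(injection_times)) {
      if (length(injection_times) < 1 ||
          (length(injection_times) > 1 && any(diff(injection_times) <= 0)))
        stop("configuration error: injection times must be strictly increasing")
    }
    if (trials_per_condition_per_block < 1)
      stop("configuration error: need at least 1 trial per condition per block")
    if (effect_latency_s <= 0 || washout_s <= 0 || injection_interval_s <= 0)
      stop("configuration error: timing parameters must be positive")
  })
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic session generator configuration\n")
  cat(sprintf("  %d cells; %d trials/condition/block; attention gain %g\n",
              x$n_cells, x$trials_per_condition_per_block, x$attention_gain))
  cat(sprintf("  baseline %g, null %g, fix-only %g spikes/s\n",
              x$baseline_rate, x$null_rate, x$fix_only_rate))
  cat(sprintf("  injection mixture: %.0f%% increase (x%g), %.0f%% decrease (x%g), %.0f%% unaffected\n",
              100 * x$injection_mixture[["increase"]], x$injection_gains[["increase"]],
              100 * x$injection_mixture[["decrease"]], x$injection_gains[["decrease"]],
              100 * x$injection_mixture[["none"]]))
  invisible(x)
}

# Stable 31-bit string hash (djb2) so each cell draws from its own
# reproducible substream regardless of generation order.
stable_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  h
}

cell_seed <- function(seed, cell_id) {
  (seed + 1000003 * stable_hash(cell_id)) %% 2147483647
}

#' Generate trials of one condition
#'
#' Draws trial records for `n` trials of one condition. Target-change times
#' are uniform in the change window; catch trials (no change) are allocated
#' as an exact floor proportion of `n` at randomly chosen positions, so a
#' session with catch fraction 1/10 contains exactly 10% no-change trials
#' whenever `n` is a multiple of 10. All trials are hits unless
#' `abort_fraction` is positive. Uses the current RNG state.
#'
#' @param n Number of trials.
#' @param condition One of `"attend-in"`, `"attend-out"`, `"attend-fix"`,
#'   `"fix-only"`.
#' @param config A [generator_config()].
#' @param direction Motion direction, `"preferred"`, `"null"` or `"none"`
#'   (forced to `"none"` for fix-only trials).
#' @return Data frame: `condition`, `direction`, `outcome`, `stim_onset_s`,
#'   `change_time_s` (`NA` for catch trials), `duration_s`.
#' @export
generate_trials <- function(n, condition, config, direction = "preferred") {
  conds <- c("attend-in", "attend-out", "attend-fix", "fix-only")
  if (!condition %in% conds)
    stop("unknown condition label: ", condition)
  if (condition == "fix-only") direction <- "none"
  win <- config$change_window_ms / 1000
  change <- stats::runif(n, win[1], win[2])
  n_catch <- floor(n * config$catch_fraction)
  if (n_catch > 0) change[sample.int(n, n_catch)] <- NA_real_
  outcome <- rep("hit", n)
  if (config$abort_fraction > 0) {
    n_ab <- floor(n * config$abort_fraction)
    if (n_ab > 0) outcome[sample.int(n, n_ab)] <- "abort"
  }
  data.frame(
    condition = rep(condition, n), direction = rep(direction, n),
    outcome = outcome, stim_onset_s = rep(STIM_ONSET_S, n),
    change_time_s = change,
    duration_s = STIM_ONSET_S +
      ifelse(is.na(change), win[2], change) + config$response_window_s,
    stringsAsFactors = FALSE
  )
}

#' @rdname generate_trials
#' @export
generate_trial <- function(condition, config, direction = "preferred") {
  generate_trials(1L, condition, config, direction)
}

block_trials <- function(config) {
  tt <- trial_types()
  n <- config$trials_per_condition_per_block
  out <- do.call(rbind, lapply(seq_len(nrow(tt)), function(i)
    generate_trials(n, tt$condition[i], config, tt$direction[i])))
  out[sample.int(nrow(out)), , drop = FALSE]  # interleave conditions
}

stim_rate <- function(trials, config, g_att) {
  rate <- numeric(nrow(trials))
  rate[trials$condition == "attend-in"] <- config$baseline_rate * g_att
  rate[trials$condition == "attend-out"] <- config$baseline_rate
  fix <- trials$condition == "attend-fix"
  rate[fix & trials$direction == "preferred"] <- config$baseline_rate
  rate[fix & trials$direction == "null"] <- config$null_rate
  rate[trials$condition == "fix-only"] <- config$fix_only_rate
  rate
}

poisson_spikes <- function(trial_id, start_s, dur_s, rate) {
  start_s <- rep_len(start_s, length(rate))
  dur_s <- rep_len(dur_s, length(rate))
  counts <- stats::rpois(length(rate), rate * dur_s)
  tot <- sum(counts)
  if (tot == 0)
    return(data.frame(trial_id = character(0), spike_time_s = numeric(0),
                      stringsAsFactors = FALSE))
  data.frame(
    trial_id = rep(trial_id, counts),
    spike_time_s = rep(start_s, counts) + stats::runif(tot) * rep(dur_s, counts),
    stringsAsFactors = FALSE
  )
}

generate_cell_session <- function(i, config, g_inj, seed) {
  subj <- config$subjects[((i - 1) %% length(config$subjects)) + 1]
  cell_id <- sprintf("c%03d", i)
  session_id <- sprintf("%s-s%03d", subj, i)
  set.seed(cell_seed(seed, cell_id))

  lay <- function(tr, t0) {
    tr$trial_start_s <- t0 + cumsum(c(0, utils::head(tr$duration_s + config$iti_s, -1)))
    tr
  }

  if (is.null(config$injection_times)) {
    ctrl <- lay(block_trials(config), 0)
    first_inj <- max(ctrl$trial_start_s + ctrl$duration_s) + 2
    inj <- lay(block_trials(config), first_inj + config$effect_latency_s + config$iti_s)
    last_start <- max(inj$trial_start_s)
    k <- max(0, ceiling((last_start - config$effect_latency_s - first_inj) /
                          config$injection_interval_s))
    inj_times <- first_inj + (0:k) * config$injection_interval_s
    last_inj <- max(inj_times)
    rec <- lay(block_trials(config), last_inj + config$washout_s + config$iti_s)
    trials <- rbind(ctrl, inj, rec)
  } else {
    trials <- lay(do.call(rbind, replicate(3, block_trials(config),
                                           simplify = FALSE)), 0)
    inj_times <- config$injection_times
  }

  trials$session_id <- session_id
  trials$cell_id <- cell_id
  trials$trial_id <- sprintf("%s-t%04d", cell_id, seq_len(nrow(trials)))

  first_inj <- inj_times[1]
  last_inj <- inj_times[length(inj_times)]
  in_effect <- trials$trial_start_s > first_inj + config$effect_latency_s &
    trials$trial_start_s <= last_inj + config$washout_s

  base_stim <- stim_rate(trials, config, config$attention_gain)
  if (!is.null(config$attention_gain_injection)) {
    alt_stim <- stim_rate(trials, config, config$attention_gain_injection)
    base_stim[in_effect] <- alt_stim[in_effect]
  }
  mult <- ifelse(in_effect, g_inj, 1)
  pre_rate <- config$fix_only_rate * mult
  stim_rate_eff <- base_stim * mult

  spikes <- rbind(
    poisson_spikes(trials$trial_id, 0, trials$stim_onset_s, pre_rate),
    poisson_spikes(trials$trial_id, trials$stim_onset_s,
                   trials$duration_s - trials$stim_onset_s, stim_rate_eff)
  )
  spikes <- spikes[order(match(spikes$trial_id, trials$trial_id),
                         spikes$spike_time_s), , drop = FALSE]
  spikes <- data.frame(cell_id = cell_id, trial_id = spikes$trial_id,
                       spike_time_s = spikes$spike_time_s,
                       stringsAsFactors = FALSE)
  rownames(spikes) <- NULL

  injections <- data.frame(
    session_id = session_id, time_s = inj_times,
    substance = config$substance,
    concentration_mol_l = config$concentration_mol_l,
    volume_nl = config$volume_nl, stringsAsFactors = FALSE
  )
  trials <- trials[, c("session_id", "cell_id", "trial_id", "condition",
                       "direction", "outcome", "trial_start_s",
                       "stim_onset_s", "change_time_s")]
  rownames(trials) <- NULL
  list(trials = trials, spikes = spikes, injections = injections,
       subject = subj, session_id = session_id)
}

#' Generate a full synthetic dataset
#'
#' Generates one session per cell: a control block, periodic injections, an
#' injection block beginning after the effect latency, and a recovery block.
#' Spike counts in every epoch are Poisson with the condition rate times the
#' cell's injection gain while the injection effect is active. Per-cell
#' injection gains are drawn from the configured increase/decrease/none
#' mixture with exact (rounded) class counts. All randomness flows from
#' `seed`; each cell uses a substream derived by stable hashing of its id,
#' so identical `(config, seed)` pairs give byte-identical outputs.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return Object of class `attnpharm_session`: list with `trials`, `spikes`,
#'   and `injections` data frames (the three interchange tables),
#'   `ground_truth` (per-cell `g_att`, `g_inj`, effect class), `config`,
#'   `seed`.
#' @export
generate_session <- function(config, seed = 1L) {
  validate_config(config)
  set.seed(seed)
  n <- config$n_cells
  n_inc <- round(config$injection_mixture[["increase"]] * n)
  n_dec <- round(config$injection_mixture[["decrease"]] * n)
  if (n_inc + n_dec > n) n_dec <- n - n_inc
  classes <- sample(c(rep("increase", n_inc), rep("decrease", n_dec),
                      rep("none", n - n_inc - n_dec)))
  g_inj <- ifelse(classes == "increase", config$injection_gains[["increase"]],
                  ifelse(classes == "decrease",
                         config$injection_gains[["decrease"]], 1))

  cells <- lapply(seq_len(n), function(i)
    generate_cell_session(i, config, g_inj[i], seed))

  truth <- data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    session_id = vapply(cells, `[[`, character(1), "session_id"),
    subject = vapply(cells, `[[`, character(1), "subject"),
    g_att = config$attention_gain,
    g_att_injection = config$attention_gain_injection %||% config$attention_gain,
    g_inj = g_inj, class = classes, stringsAsFactors = FALSE
  )
  structure(
    list(trials = do.call(rbind, lapply(cells, `[[`, "trials")),
         spikes = do.call(rbind, lapply(cells, `[[`, "spikes")),
         injections = do.call(rbind, lapply(cells, `[[`, "injections")),
         ground_truth = truth, config = config, seed = seed),
    class = "attnpharm_session"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.attnpharm_session <- function(x, ...) {
  cat("Synthetic recording dataset\n")
  cat(sprintf("  %d cells, %d trials, %d spikes, %d injection events\n",
              nrow(x$ground_truth), nrow(x$trials), nrow(x$spikes),
              nrow(x$injections)))
  cat(sprintf("  injection-effect classes: %s\n",
              paste(names(table(x$ground_truth$class)),
                    table(x$ground_truth$class), sep = "=", collapse = ", ")))
  invisible(x)
}
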