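#' Firing rate of one spike train in an analysis window
#'
#' Counts spikes inside a half-open window `[start, end)` placed relative to
#' stimulus onset and divides by the window length. The default window,
#' 300-800 ms after stimulus onset, targets the sustained response and skips
#' the onset transient. A spike exactly at the window end is excluded.
#'
#' @param spike_times Numeric vector of spike timestamps (s, relative to trial
#'   start), sorted ascending.
#' @param stim_onset Stimulus onset time (s, relative to trial start).
#' @param window_ms Length-2 numeric, window start and end in ms after onset.
#' @return Firing rate in spikes/s.
#' @export
#' @examples
#' firing_rate_in_window(c(0.95, 1.0, 1.1, 1.2, 1.3), stim_onset = 0.65)
firing_rate_in_window <- function(spike_times, stim_onset,
                                  window_ms = c(300, 800)) {
  if (length(window_ms) != 2L || diff(window_ms) <= 0)
    stop("window must satisfy end > start")
  if (is.unsorted(spike_times))
    stop("spike timestamps must be sorted ascending")
  lo <- stim_onset + window_ms[1] / 1000
  hi <- stim_onset + window_ms[2] / 1000
  sum(spike_times >= lo & spike_times < hi) / ((window_ms[2] - window_ms[1]) / 1000)
}

#' Per-trial window-averaged firing rates
#'
#' Vectorized application of the analysis-window rate to every trial of a
#' session: each spike is matched to its trial, shifted to stimulus-onset
#' time, and counted into the trial's half-open window.
#'
#' @param trials Trial table (`trial_id`, `stim_onset_s`, ...).
#' @param spikes Spike table (`trial_id`, `spike_time_s`).
#' @param window_ms Analysis window in ms after stimulus onset.
#' @return `trials` with an added `rate` column (spikes/s).
#' @export
window_rates <- function(trials, spikes, window_ms = c(300, 800)) {
  if (length(window_ms) != 2L || diff(window_ms) <= 0)
    stop("window must satisfy end > start")
  idx <- match(spikes$trial_id, trials$trial_id)
  if (anyNA(idx))
    stop("spikes reference unknown trial_ids: ",
         paste(utils::head(unique(spikes$trial_id[is.na(idx)]), 5), collapse = ", "))
  rel <- spikes$spike_time_s - trials$stim_onset_s[idx]
  inwin <- rel >= window_ms[1] / 1000 & rel < window_ms[2] / 1000
  counts <- tabulate(idx[inwin], nbins = nrow(trials))
  out <- trials
  out$rate <- counts / ((window_ms[2] - window_ms[1]) / 1000)
  out
}

#' Peristimulus time histogram
#'
#' Pools spikes across trials, aligned to each trial's stimulus onset, and
#' bins them at `bin_width_ms`. Per-bin rate is the pooled spike count divided
#' by (number of trials x bin width), i.e. the trial-averaged firing rate in
#' spikes/s. Optional Gaussian smoothing is for display only; window-rate and
#' index computations never use smoothed values.
#'
#' @param trains List of numeric vectors, one per trial, spike timestamps in s
#'   relative to trial start.
#' @param onsets Numeric vector of stimulus onsets (s), one per trial.
#' @param bin_width_ms Bin width in ms (default 10).
#' @param range_ms Length-2 numeric, histogram range in ms relative to onset.
#' @param condition Optional condition label stored with the histogram.
#' @param smooth_ms Standard deviation of an optional Gaussian display filter
#'   (ms); 0 disables smoothing.
#' @return An object of class `psth`: list with `bin_edges` (s, relative to
#'   onset), `rate` (spikes/s per bin), `counts` (raw pooled counts),
#'   `n_trials`, `condition`.
#' @export
compute_psth <- function(trains, onsets, bin_width_ms = 10,
                         range_ms = c(-500, 1500), condition = NULL,
                         smooth_ms = 0) {
  if (length(trains) == 0L) stop("at least one trial is required")
  stopifnot(length(trains) == length(onsets))
  n <- length(trains)
  rel <- unlist(trains, use.names = FALSE) -
    rep(onsets, vapply(trains, length, integer(1)))
  edges <- seq(range_ms[1], range_ms[2], by = bin_width_ms) / 1000
  keep <- rel >= edges[1] & rel < edges[length(edges)]
  counts <- if (any(keep)) {
    bins <- findInterval(rel[keep], edges, rightmost.closed = FALSE)
    tabulate(bins, nbins = length(edges) - 1L)
  } else {
    integer(length(edges) - 1L)
  }
  rate <- counts / (n * bin_width_ms / 1000)
  if (smooth_ms > 0) {
    half <- ceiling(3 * smooth_ms / bin_width_ms)
    k <- stats::dnorm(seq(-half, half) * bin_width_ms, sd = smooth_ms)
    k <- k / sum(k)
    rate <- as.numeric(stats::filter(rate, k, sides = 2))
  }
  structure(
    list(bin_edges = edges, rate = rate, counts = counts, n_trials = n,
         condition = condition, bin_width_ms = bin_width_ms,
         smooth_ms = smooth_ms),
    class = "psth"
  )
}

#' @export
print.psth <- function(x, ...) {
  cat("PSTH", if (!is.null(x$condition)) paste0("(", x$condition, ")"), "\n")
  cat(sprintf("  %d trials, %d bins of %g ms, range [%g, %g] ms\n",
              x$n_trials, length(x$rate), x$bin_width_ms,
              1000 * x$bin_edges[1], 1000 * x$bin_edges[length(x$bin_edges)]))
  cat(sprintf("  peak rate %.1f spikes/s\n", max(x$rate, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.psth <- function(x, ...) {
  mid <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  plot(mid * 1000, x$rate, type = "s", xlab = "time from stimulus onset (ms)",
       ylab = "firing rate (spikes/s)",
       main = if (is.null(x$condition)) "PSTH" else x$condition, ...)
  abline(v = 0, lty = 3)
  invisible(x)
}

#' Condition-by-block PSTH table for a session
#'
#' Convenience wrapper building one PSTH per (condition, block) combination
#' from the session tables, returned in long format suitable for CSV export.
#'
#' @param trials Trial table including a `block` column (see [assign_blocks()]).
#' @param spikes Spike table.
#' @param bin_width_ms,range_ms Passed to [compute_psth()].
#' @param blocks Blocks to include (default control and injection).
#' @return Data frame: `condition`, `block`, `bin_start_ms`, `bin_end_ms`,
#'   `rate_sp_s`, `n_trials`.
#' @export
psth_table <- function(trials, spikes, bin_width_ms = 10,
                       range_ms = c(-500, 1500),
                       blocks = c("control", "injection")) {
  stopifnot("block" %in% names(trials))
  trials <- trials[trials$block %in% blocks, , drop = FALSE]
  sp_by_trial <- split(spikes$spike_time_s, spikes$trial_id)
  res <- list()
  for (cond in unique(trials$condition)) {
    for (blk in unique(trials$block[trials$condition == cond])) {
      tt <- trials[trials$condition == cond & trials$block == blk, ]
      trains <- sp_by_trial[as.character(tt$trial_id)]
      trains[vapply(trains, is.null, logical(1))] <- list(numeric(0))
      p <- compute_psth(trains, tt$stim_onset_s, bin_width_ms, range_ms,
                        condition = cond)
      nb <- length(p$rate)
      res[[length(res) + 1L]] <- data.frame(
        condition = cond, block = blk,
        bin_start_ms = 1000 * p$bin_edges[-(nb + 1L)],
        bin_end_ms = 1000 * p$bin_edges[-1L],
        rate_sp_s = p$rate, n_trials = p$n_trials,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, res)
}
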