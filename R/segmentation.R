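#' Session timeline of injection events
#'
#' Bundles the injection events of one recording session with the latency
#' used to delimit the drug block. The injection block starts with the first
#' trial occurring more than `latency` seconds after the first injection and
#' ends `latency` seconds after the last injection; the interval between the
#' first injection and the block start is a transition period excluded from
#' analysis. Sessions with repeated injection cycles are supported: injection
#' events separated by more than `cycle_gap` seconds are treated as separate
#' cycles, each delimited by the same rule, with recovery trials in between.
#'
#' @param injection_times Numeric vector of injection times (s from session
#'   start), strictly increasing. May be empty (no-injection session).
#' @param latency Seconds between an injection and the block boundary it
#'   defines (default 150).
#' @param cycle_gap Minimum gap (s) between consecutive injections that starts
#'   a new injection cycle. Defaults to twice the latency, so a gap long
#'   enough to contain a recovery period splits cycles.
#' @param substance,concentration_mol_l,volume_nl Optional metadata recycled
#'   across events.
#' @param session_span Optional session duration (s); trials beyond it are
#'   rejected by [assign_blocks()].
#' @return Object of class `session_timeline`.
#' @export
session_timeline <- function(injection_times = numeric(0), latency = 150,
                             cycle_gap = 2 * latency,
                             substance = NA_character_,
                             concentration_mol_l = NA_real_,
                             volume_nl = NA_real_,
                             session_span = NULL) {
  injection_times <- as.numeric(injection_times)
  if (length(injection_times) > 1 && any(diff(injection_times) <= 0))
    stop("injection times must be strictly increasing")
  if (latency <= 0) stop("latency must be positive")
  events <- data.frame(
    time_s = injection_times,
    substance = rep_len(substance, length(injection_times)),
    concentration_mol_l = rep_len(concentration_mol_l, length(injection_times)),
    volume_nl = rep_len(volume_nl, length(injection_times)),
    stringsAsFactors = FALSE
  )
  structure(
    list(events = events, latency = latency, cycle_gap = cycle_gap,
         session_span = session_span),
    class = "session_timeline"
  )
}

#' @export
print.session_timeline <- function(x, ...) {
  n <- nrow(x$events)
  cat(sprintf("Session timeline: %d injection event%s, latency %g s\n",
              n, if (n == 1) "" else "s", x$latency))
  if (n > 0)
    cat(sprintf("  first %g s, last %g s (%d cycle%s)\n",
                x$events$time_s[1], x$events$time_s[n],
                length(split_cycles(x$events$time_s, x$cycle_gap)),
                if (length(split_cycles(x$events$time_s, x$cycle_gap)) == 1) "" else "s"))
  invisible(x)
}

split_cycles <- function(times, cycle_gap) {
  if (length(times) == 0) return(list())
  brk <- cumsum(c(0, diff(times) > cycle_gap))
  unname(split(times, brk))
}

#' Assign trials to control, transition, injection and recovery blocks
#'
#' Applies the block rule to each trial's start time: trials before (or at)
#' the first injection are control; within each injection cycle, trials in
#' `(first, first + latency]` are transition (excluded from analysis), trials
#' in `(first + latency, last + latency]` are injection, and later trials are
#' recovery until the next cycle begins. With no injection events every trial
#' is control.
#'
#' @param trials Trial table with `trial_id` and `trial_start_s` columns.
#' @param timeline A [session_timeline()].
#' @return Data frame `trial_id`, `block` (factor levels control, transition,
#'   injection, recovery), one row per input trial, in input order.
#' @export
assign_blocks <- function(trials, timeline) {
  stopifnot(inherits(timeline, "session_timeline"))
  t <- trials$trial_start_s
  if (!is.null(timeline$session_span) && any(t > timeline$session_span))
    stop("trial start times beyond session span")
  lat <- timeline$latency
  cycles <- split_cycles(timeline$events$time_s, timeline$cycle_gap)
  block <- rep("control", length(t))
  if (length(cycles) > 0) {
    first1 <- cycles[[1]][1]
    block[t > first1] <- "recovery"
    for (cy in cycles) {
      f <- cy[1]; l <- cy[length(cy)]
      block[t > f & t <= f + lat] <- "transition"
      block[t > f + lat & t <= l + lat] <- "injection"
    }
  }
  data.frame(trial_id = trials$trial_id,
             block = factor(block, levels = c("control", "transition",
                                              "injection", "recovery")),
             stringsAsFactors = FALSE)
}

#' Data-quality inclusion check for one cell (criterion 1)
#'
#' A cell passes when (a) every task condition has at least `min_trials`
#' analyzable trials in the injection block, (b) its mean preferred-stimulus
#' firing rate in the control block reaches `min_rate` spikes/s, and (c) the
#' three sensory fixation conditions (preferred attend-fix, null attend-fix,
#' fix-only) differ in the control block by a Kruskal-Wallis test at level
#' `alpha`. Failures are reported with named reasons rather than errors, so a
#' population loop can tabulate the inclusion funnel.
#'
#' @param rates Per-trial rate table for one cell: columns `condition`,
#'   `direction`, `block`, `rate`, optionally `outcome`.
#' @param alpha Significance level for the sensory responsiveness test.
#' @param min_trials Minimum trials per task condition in the injection block.
#' @param min_rate Minimum control-block mean preferred-stimulus rate
#'   (spikes/s).
#' @param hits_only Restrict to hit trials first (default `TRUE`).
#' @return One-row data frame: `pass`, sub-flags `trial_count_ok`,
#'   `responsiveness_ok`, `sensory_ok`, the measured `min_condition_trials`,
#'   `mean_pref_rate`, `kw_stat`, `kw_p`, and a comma-separated `fail_reason`
#'   (empty when passing).
#' @export
check_criterion1 <- function(rates, alpha = 0.05, min_trials = 3,
                             min_rate = 7, hits_only = TRUE) {
  if (hits_only && "outcome" %in% names(rates))
    rates <- rates[rates$outcome == "hit", , drop = FALSE]
  key <- paste(rates$condition, rates$direction)
  task_keys <- c("attend-in preferred", "attend-out preferred",
                 "attend-fix preferred", "attend-fix null", "fix-only none")
  inj <- rates$block == "injection"
  n_inj <- vapply(task_keys, function(k) sum(inj & key == k), numeric(1))
  trial_count_ok <- all(n_inj >= min_trials)

  pref_ctrl <- rates$rate[rates$block == "control" &
                            key == "attend-fix preferred"]
  mean_pref <- if (length(pref_ctrl)) mean(pref_ctrl) else NA_real_
  responsiveness_ok <- !is.na(mean_pref) && mean_pref >= min_rate

  grp_keys <- c("attend-fix preferred", "attend-fix null", "fix-only none")
  ctrl <- rates[rates$block == "control" & key %in% grp_keys, , drop = FALSE]
  gk <- paste(ctrl$condition, ctrl$direction)
  kw_stat <- NA_real_; kw_p <- NA_real_
  if (length(unique(gk)) == 3L && all(table(gk) >= 2L)) {
    kw <- stats::kruskal.test(ctrl$rate, factor(gk))
    kw_stat <- unname(kw$statistic); kw_p <- kw$p.value
  }
  sensory_ok <- !is.na(kw_p) && kw_p < alpha

  reasons <- c(if (!trial_count_ok) "trial-count",
               if (!responsiveness_ok) "responsiveness",
               if (!sensory_ok) "sensory")
  data.frame(
    pass = trial_count_ok && responsiveness_ok && sensory_ok,
    trial_count_ok = trial_count_ok,
    responsiveness_ok = responsiveness_ok,
    sensory_ok = sensory_ok,
    min_condition_trials = min(n_inj),
    mean_pref_rate = mean_pref,
    kw_stat = kw_stat, kw_p = kw_p,
    fail_reason = paste(reasons, collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Classify the effect of the injected substance on one cell (criterion 2)
#'
#' Two-sided Wilcoxon rank-sum test comparing per-trial preferred-direction
#' attend-fix firing rates between the control and injection blocks. If the
#' test is significant at `alpha`, the sign of the median difference
#' (injection minus control) labels the cell `"increase"` or `"decrease"`;
#' equal medians with a significant test are resolved by the direction of the
#' rank-sum statistic. Samples with fewer than 2 trials yield `"none"` with a
#' warning.
#'
#' @param control_rates,injection_rates Numeric vectors of per-trial rates.
#' @param alpha Significance level (default 0.05).
#' @return List: `class` ("none", "increase" or "decrease"), `p`, `statistic`
#'   (Mann-Whitney U of the injection sample), `median_diff`.
#' @export
classify_injection_effect <- function(control_rates, injection_rates,
                                      alpha = 0.05) {
  n1 <- length(injection_rates); n2 <- length(control_rates)
  if (n1 < 2 || n2 < 2) {
    warning("fewer than 2 trials in a block; classification is 'none'")
    return(list(class = "none", p = NA_real_, statistic = NA_real_,
                median_diff = NA_real_))
  }
  ht <- rank_sum_test(injection_rates, control_rates)
  md <- stats::median(injection_rates) - stats::median(control_rates)
  cls <- "none"
  if (!is.na(ht$p) && ht$p < alpha) {
    dir <- if (md != 0) md else ht$statistic - n1 * n2 / 2
    cls <- if (dir > 0) "increase" else "decrease"
  }
  list(class = cls, p = ht$p, statistic = ht$statistic, median_diff = md)
}

#' Inclusion report for all cells of a dataset
#'
#' Runs [check_criterion1()] and [classify_injection_effect()] per cell and
#' stacks the results; cells failing criterion 1 are not classified
#' (`injection_effect = "none"`, no p-value), so significant injection effects
#' are only claimed for cells of adequate data quality.
#'
#' @param rates Per-trial rate table for all cells (needs `cell_id`,
#'   `condition`, `direction`, `block`, `rate`, optionally `outcome`).
#' @param alpha,min_trials,min_rate,hits_only Passed to the per-cell checks.
#' @return Data frame, one row per cell: criterion-1 columns plus
#'   `injection_effect`, `effect_p`, `effect_statistic`, `effect_median_diff`.
#' @export
inclusion_report <- function(rates, alpha = 0.05, min_trials = 3,
                             min_rate = 7, hits_only = TRUE) {
  if (hits_only && "outcome" %in% names(rates))
    rates <- rates[rates$outcome == "hit", , drop = FALSE]
  one <- function(r) {
    c1 <- check_criterion1(r, alpha, min_trials, min_rate, hits_only = FALSE)
    c1 <- cbind(data.frame(cell_id = r$cell_id[1], stringsAsFactors = FALSE), c1)
    if (c1$pass) {
      sel <- r$condition == "attend-fix" & r$direction == "preferred"
      eff <- classify_injection_effect(
        r$rate[sel & r$block == "control"],
        r$rate[sel & r$block == "injection"], alpha)
    } else {
      eff <- list(class = "none", p = NA_real_, statistic = NA_real_,
                  median_diff = NA_real_)
    }
    c1$injection_effect <- eff$class
    c1$effect_p <- eff$p
    c1$effect_statistic <- eff$statistic
    c1$effect_median_diff <- eff$median_diff
    c1
  }
  out <- do.call(rbind, lapply(split(rates, rates$cell_id), one))
  rownames(out) <- NULL
  out
}
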