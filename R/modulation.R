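#' Injection modulation index
#'
#' Normalized difference between the mean firing rate in the injection block
#' and the mean firing rate in the control block,
#' \eqn{\mathrm{IMI} = (R_2 - R_1)/(R_2 + R_1)}. Positive values indicate a
#' response enhancement due to the injected substance. The index is computed
#' separately for each task condition (attend-fix, attend-in, attend-out).
#'
#' @param r1 Control-block mean firing rate (spikes/s), non-negative.
#' @param r2 Injection-block mean firing rate (spikes/s), non-negative.
#' @return Dimensionless index in \eqn{[-1, 1]}. Vectorized.
#' @seealso [compute_ami()], [to_percent()]
#' @export
#' @examples
#' compute_imi(10, 20)  # 1/3
compute_imi <- function(r1, r2) {
  stopifnot(length(r1) == length(r2))
  if (any(r1 < 0 | r2 < 0, na.rm = TRUE))
    stop("firing rates must be non-negative")
  if (any(r1 + r2 == 0, na.rm = TRUE))
    stop("index undefined when both rates are zero")
  (r2 - r1) / (r2 + r1)
}

#' Attentional modulation index
#'
#' Normalized difference between the mean firing rate with attention directed
#' into the receptive field (attend-in, \eqn{Q_2}) and out of it (attend-out,
#' \eqn{Q_1}): \eqn{\mathrm{AMI} = (Q_2 - Q_1)/(Q_2 + Q_1)}. Positive values
#' indicate attentional enhancement; negative values suppression. Under a
#' multiplicative attention gain \eqn{g} on a common baseline
#' (\eqn{Q_2 = g Q_1}) the index equals \eqn{(g-1)/(g+1)}.
#'
#' @param q1 Attend-out mean firing rate (spikes/s), non-negative.
#' @param q2 Attend-in mean firing rate (spikes/s), non-negative.
#' @return Dimensionless index in \eqn{[-1, 1]}. Vectorized.
#' @export
#' @examples
#' compute_ami(8, 12)   # 0.2
#' g <- 1.25
#' compute_ami(10, 10 * g) == (g - 1) / (g + 1)
compute_ami <- function(q1, q2) {
  stopifnot(length(q1) == length(q2))
  if (any(q1 < 0 | q2 < 0, na.rm = TRUE))
    stop("firing rates must be non-negative")
  if (any(q1 + q2 == 0, na.rm = TRUE))
    stop("index undefined when both rates are zero")
  (q2 - q1) / (q2 + q1)
}

#' Convert a modulation index to a percent rate change
#'
#' Maps an index \eqn{x = (b - a)/(b + a)} to the equivalent percent increase
#' of \eqn{b} over \eqn{a}: \eqn{2x/(1 - x) \times 100 = 100 (b/a - 1)}.
#' Applied identically to attentional and injection indices.
#'
#' @param index Dimensionless index in \eqn{(-1, 1)}. Vectorized; `NA` passes
#'   through.
#' @return Percent change (e.g. `20.75` for +20.75%).
#' @export
#' @examples
#' to_percent(0.2)  # 50: attend-in rate is 150% of attend-out
to_percent <- function(index) {
  ok <- !is.na(index)
  if (any(index[ok] >= 1))
    stop("index of 1 corresponds to an infinite percent change")
  if (any(index[ok] <= -1))
    stop("index must be greater than -1")
  2 * index / (1 - index) * 100
}

#' Inverse of [to_percent()]
#'
#' @param percent Percent change, greater than -100.
#' @return Index in \eqn{(-1, 1)} such that `to_percent(percent_to_index(p)) == p`.
#' @export
percent_to_index <- function(percent) {
  if (any(percent <= -100, na.rm = TRUE))
    stop("percent change must be greater than -100")
  percent / (200 + percent)
}

block_condition_mean <- function(rates, block, condition, direction = NULL) {
  sel <- rates$block == block & rates$condition == condition
  if (!is.null(direction)) sel <- sel & rates$direction == direction
  if (!any(sel)) return(NA_real_)
  mean(rates$rate[sel])
}

safe_index <- function(a, b, f) {
  if (is.na(a) || is.na(b) || a + b == 0) return(NA_real_)
  f(a, b)
}

#' Per-cell modulation indices
#'
#' Computes, for every cell in a per-trial rate table, the block- and
#' condition-wise mean firing rates and the derived modulation indices:
#' the injection index for each condition (attend-fix and attend-in/out use
#' preferred-direction trials only), the attentional index for the control and
#' injection blocks, and their percent conversions. Rates entering the indices
#' are unweighted means of per-trial window rates.
#'
#' @param rates Per-trial rate table as returned by [window_rates()] with a
#'   `block` column added by [assign_blocks()] (columns `cell_id`, `condition`,
#'   `direction`, `outcome`, `block`, `rate`).
#' @param hits_only If `TRUE` (default) only trials with outcome `"hit"` enter
#'   the means.
#' @return A data frame with one row per cell: mean rates
#'   (`r_fix_control`, `r_fix_injection`, `q_out_control`, `q_in_control`,
#'   `q_out_injection`, `q_in_injection`), indices (`imi_fix`, `imi_in`,
#'   `imi_out`, `ami_control`, `ami_injection`) and percent conversions
#'   (`perc_ami_control`, `perc_ami_injection`). Indices whose defining rates
#'   are unavailable (no trials, or both rates zero) are `NA`.
#' @export
modulation_indices <- function(rates, hits_only = TRUE) {
  stopifnot(all(c("cell_id", "condition", "direction", "block", "rate") %in%
                  names(rates)))
  if (hits_only && "outcome" %in% names(rates))
    rates <- rates[rates$outcome == "hit", , drop = FALSE]

  one_cell <- function(r) {
    m <- function(block, condition, direction = NULL)
      block_condition_mean(r, block, condition, direction)
    r_fix1 <- m("control", "attend-fix", "preferred")
    r_fix2 <- m("injection", "attend-fix", "preferred")
    r_in1  <- m("control", "attend-in")
    r_in2  <- m("injection", "attend-in")
    r_out1 <- m("control", "attend-out")
    r_out2 <- m("injection", "attend-out")
    ami1 <- safe_index(r_out1, r_in1, compute_ami)
    ami2 <- safe_index(r_out2, r_in2, compute_ami)
    data.frame(
      cell_id = r$cell_id[1],
      r_fix_control = r_fix1, r_fix_injection = r_fix2,
      q_out_control = r_out1, q_in_control = r_in1,
      q_out_injection = r_out2, q_in_injection = r_in2,
      imi_fix = safe_index(r_fix1, r_fix2, compute_imi),
      imi_in  = safe_index(r_in1, r_in2, compute_imi),
      imi_out = safe_index(r_out1, r_out2, compute_imi),
      ami_control = ami1,
      ami_injection = ami2,
      perc_ami_control = if (is.na(ami1)) NA_real_ else to_percent(ami1),
      perc_ami_injection = if (is.na(ami2)) NA_real_ else to_percent(ami2),
      stringsAsFactors = FALSE
    )
  }

  out <- do.call(rbind, lapply(split(rates, rates$cell_id), one_cell))
  rownames(out) <- NULL
  # carry session/subject metadata when present (constant within cell)
  for (extra in c("session_id", "subject")) {
    if (extra %in% names(rates)) {
      map <- rates[!duplicated(rates$cell_id), c("cell_id", extra)]
      out[[extra]] <- map[[extra]][match(out$cell_id, map$cell_id)]
    }
  }
  out
}
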