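# Independent oracles used to check the statistical routines and the
# vectorized counting code. These are deliberately brute-force (full
# enumeration, linear scans) and share no code with the implementation.

# Exact two-sided one-sample signed-rank p by enumerating all 2^n sign
# patterns of the rank magnitudes (assumes no zeros, no tied magnitudes).
exact_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  pl <- mean(w_all <= w_obs)
  pu <- mean(w_all >= w_obs)
  min(1, 2 * min(pl, pu))
}

# Exact two-sided rank-sum p by enumerating all C(n1+n2, n1) assignments of
# pooled ranks to the first sample (assumes no ties across the pool).
exact_rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  u_all <- apply(idx, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  pl <- mean(u_all <= u_obs)
  pu <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pu))
}

# Linear-scan spike count in a half-open window.
brute_window_rate <- function(times, onset, window_ms) {
  lo <- onset + window_ms[1] / 1000
  hi <- onset + window_ms[2] / 1000
  n <- 0L
  for (t in times) if (t >= lo && t < hi) n <- n + 1L
  n / ((window_ms[2] - window_ms[1]) / 1000)
}

# Sort-based median oracle.
sort_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# Constructed per-trial rate table for one cell, with clearly separated
# sensory conditions (preferred ~ pref_rate, null ~ pref_rate/2.5, fix-only
# low) and configurable trial counts, for inclusion-funnel tests.
make_cell_rates <- function(cell_id = "c001", n_per = 10, pref_rate = 20,
                            inj_mult = 1, flat_sensory = FALSE,
                            n_attend_in_inj = n_per) {
  types <- data.frame(
    condition = c("attend-in", "attend-out", "attend-fix", "attend-fix",
                  "fix-only"),
    direction = c("preferred", "preferred", "preferred", "null", "none"),
    stringsAsFactors = FALSE
  )
  base <- c(pref_rate * 1.25, pref_rate, pref_rate, pref_rate / 2.5, 4)
  if (flat_sensory) base <- rep(pref_rate, 5)
  rows <- list()
  for (blk in c("control", "injection")) {
    for (i in seq_len(nrow(types))) {
      n <- n_per
      if (blk == "injection" && types$condition[i] == "attend-in")
        n <- n_attend_in_inj
      mult <- if (blk == "injection") inj_mult else 1
      # deterministic spread around the target mean, no RNG involved;
      # offsets are exact binary fractions summing to exactly zero
      r <- base[i] * mult + (seq_len(n) - (n + 1) / 2) * 0.25
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cell_id, condition = types$condition[i],
        direction = types$direction[i], outcome = "hit", block = blk,
        rate = pmax(r, 0), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
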