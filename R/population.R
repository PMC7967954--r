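# Nonparametric test wrappers. All tests are two-sided. Exact p-values are
# used for small samples without ties (n <= 25), otherwise the normal
# approximation with continuity correction; the choice is reported in
# `method`. Statistic naming follows common usage in this literature:
# W for the one-sample/paired signed-rank statistic (sum of positive ranks),
# U for the two-sample Mann-Whitney statistic.

#' One-sample Wilcoxon signed-rank test against a median of zero
#'
#' Exact zeros are dropped before ranking; tied absolute values receive
#' mid-ranks. If every value is zero the test is degenerate and `p = 1` is
#' returned with a warning.
#'
#' @param values Numeric vector (e.g. per-cell modulation indices).
#' @return List: `statistic` (W, sum of positive ranks), `p` (two-sided),
#'   `n` (values used after dropping zeros), `method`.
#' @export
signed_rank_vs_zero <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1) stop("at least one value is required")
  nz <- values[values != 0]
  if (length(nz) == 0) {
    warning("all values are zero; test is degenerate")
    return(list(statistic = 0, p = 1, n = 0L, method = "degenerate"))
  }
  n <- length(nz)
  exact <- n <= 25 && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value, n = n,
       method = if (exact) "exact" else "normal approximation")
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return List: `statistic` (U for sample `x`), `p` (two-sided), `method`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  exact <- length(x) <= 25 && length(y) <= 25 && !any(duplicated(c(x, y)))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Paired comparison of attentional indices between blocks
#'
#' Two-sided Wilcoxon signed-rank test on the paired differences
#' (injection minus control), one pair per cell. This is the test of the
#' central question: does the injected substance change the magnitude of
#' attentional modulation?
#'
#' @param ami_control,ami_injection Numeric vectors of equal length, same
#'   cell order. Pairs with an `NA` on either side are dropped.
#' @return List: `statistic` (W), `p`, `n` (non-zero pairs), `method`.
#' @export
paired_ami_test <- function(ami_control, ami_injection) {
  if (length(ami_control) != length(ami_injection))
    stop("paired samples must have equal length")
  ok <- !is.na(ami_control) & !is.na(ami_injection)
  signed_rank_vs_zero(ami_injection[ok] - ami_control[ok])
}

#' Check whether two groups of cells may be pooled
#'
#' Two-sided rank-sum comparison of per-cell attentional indices between two
#' groups (e.g. the two subjects); pooling proceeds when the groups do not
#' differ at level `alpha`.
#'
#' @param ami_group_a,ami_group_b Numeric vectors of per-cell indices.
#' @param alpha Significance level (default 0.05).
#' @return List: `statistic` (U), `p`, `pool` (logical).
#' @export
pool_check <- function(ami_group_a, ami_group_b, alpha = 0.05) {
  ht <- rank_sum_test(ami_group_a, ami_group_b)
  list(statistic = ht$statistic, p = ht$p, pool = ht$p >= alpha,
       method = ht$method)
}

test_or_na <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1 || all(values == 0))
    return(list(statistic = NA_real_, p = NA_real_))
  suppressWarnings(signed_rank_vs_zero(values))
}

#' Population-level summary of modulation results
#'
#' Builds the full result ladder for one substance: the population test of
#' the sensory-condition injection index against zero; the split of cells
#' with a significant injection effect into increase and decrease subgroups;
#' per-subgroup medians of the attentional index in the control and injection
#' blocks, each tested against zero; and the paired control-vs-injection
#' comparison of attentional indices per subgroup. Percent modulation is
#' reported two ways — the percent conversion of the median index and the
#' median of per-cell percent values — because the two aggregations differ in
#' general.
#'
#' @param indices Per-cell index table from [modulation_indices()].
#' @param inclusion Per-cell report from [inclusion_report()].
#' @param alpha Significance level used throughout (default 0.05).
#' @return Data frame with one row per subgroup (`all`, `increase`,
#'   `decrease`) of cells passing criterion 1: medians, test statistics and
#'   two-sided p-values. If a `subject` column with two or more levels is
#'   present in `indices`, a rank-sum comparison of control-block attentional
#'   indices between the first two subjects is attached as attribute
#'   `pool_check`.
#' @export
summarize_population <- function(indices, inclusion, alpha = 0.05) {
  m <- merge(indices, inclusion[, c("cell_id", "pass", "injection_effect")],
             by = "cell_id", sort = TRUE)
  m <- m[m$pass, , drop = FALSE]

  pool <- NULL
  if ("subject" %in% names(m)) {
    subj <- sort(unique(m$subject))
    if (length(subj) >= 2) {
      a <- m$ami_control[m$subject == subj[1]]
      b <- m$ami_control[m$subject == subj[2]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) && length(b))
        pool <- c(pool_check(a, b, alpha), list(groups = subj[1:2]))
    }
  }

  one_group <- function(sub) {
    g <- if (sub == "all") m else m[m$injection_effect == sub, , drop = FALSE]
    imi <- test_or_na(g$imi_fix)
    amic <- test_or_na(g$ami_control)
    amii <- test_or_na(g$ami_injection)
    ok <- !is.na(g$ami_control) & !is.na(g$ami_injection)
    paired <- if (sum(ok) > 0 && any(g$ami_injection[ok] != g$ami_control[ok])) {
      paired_ami_test(g$ami_control[ok], g$ami_injection[ok])
    } else list(statistic = NA_real_, p = if (sum(ok) > 0) 1 else NA_real_)
    med <- function(x) if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE)
    med_perc <- function(x) {
      mx <- med(x)
      if (is.na(mx)) NA_real_ else to_percent(mx)
    }
    data.frame(
      subgroup = sub, n_cells = nrow(g),
      median_imi_fix = med(g$imi_fix),
      imi_W = imi$statistic, imi_p = imi$p,
      median_ami_control = med(g$ami_control),
      median_ami_injection = med(g$ami_injection),
      perc_of_median_ami_control = med_perc(g$ami_control),
      perc_of_median_ami_injection = med_perc(g$ami_injection),
      median_perc_ami_control = med(g$perc_ami_control),
      median_perc_ami_injection = med(g$perc_ami_injection),
      ami_control_W = amic$statistic, ami_control_p = amic$p,
      ami_injection_W = amii$statistic, ami_injection_p = amii$p,
      paired_W = paired$statistic, paired_p = paired$p,
      stringsAsFactors = FALSE
    )
  }

  out <- do.call(rbind, lapply(c("all", "increase", "decrease"), one_group))
  rownames(out) <- NULL
  attr(out, "pool_check") <- pool
  attr(out, "alpha") <- alpha
  out
}

fmt_p <- function(p) {
  if (is.na(p)) "NA" else if (p < 1e-4) sprintf("%.1e", p) else sprintf("%.3g", p)
}

#' Human-readable population report
#'
#' Renders a [summarize_population()] table as markdown text mirroring how
#' such results are conventionally reported: population injection effect,
#' subgroup sizes, attentional modulation per block with tests against zero,
#' and the paired block comparison.
#'
#' @param popres Result of [summarize_population()].
#' @param substance Substance label for the heading.
#' @return Character vector of markdown lines.
#' @export
population_report <- function(popres, substance = "substance") {
  pool <- attr(popres, "pool_check")
  lines <- c(sprintf("## Population results: %s", substance), "")
  if (!is.null(pool))
    lines <- c(lines, sprintf(
      "Control-block AMI compared between subjects %s and %s: U = %g, p = %s; data %s.",
      pool$groups[1], pool$groups[2], pool$statistic, fmt_p(pool$p),
      if (pool$pool) "were pooled" else "were NOT pooled"), "")
  for (i in seq_len(nrow(popres))) {
    r <- popres[i, ]
    lines <- c(lines, sprintf("### Subgroup: %s (N = %d)", r$subgroup, r$n_cells))
    if (r$subgroup == "all")
      lines <- c(lines, sprintf(
        "- median IMI (attend-fix) = %.3f (%.3g%%), W = %g, p = %s",
        r$median_imi_fix, to_percent(r$median_imi_fix),
        r$imi_W, fmt_p(r$imi_p)))
    lines <- c(lines, sprintf(
      "- control block: median AMI = %.3f (%.3g%%), W = %g, p = %s",
      r$median_ami_control, r$perc_of_median_ami_control,
      r$ami_control_W, fmt_p(r$ami_control_p)))
    lines <- c(lines, sprintf(
      "- injection block: median AMI = %.3f (%.3g%%), W = %g, p = %s",
      r$median_ami_injection, r$perc_of_median_ami_injection,
      r$ami_injection_W, fmt_p(r$ami_injection_p)))
    lines <- c(lines, sprintf(
      "- paired AMI comparison (injection - control): W = %g, p = %s",
      r$paired_W, fmt_p(r$paired_p)), "")
  }
  lines
}
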