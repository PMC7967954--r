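test_that("signed-rank against zero matches worked enumerations", {
  r <- signed_rank_vs_zero(c(1, 2, 3))
  expect_equal(r$statistic, 6)
  expect_equal(r$p, 0.25)
  # perfectly symmetric sample sits at the null center
  r <- signed_rank_vs_zero(c(-2, -1, 1, 2))
  expect_equal(r$p, 1)
  expect_warning(r <- signed_rank_vs_zero(c(0, 0, 0)), "all values are zero")
  expect_equal(r$p, 1)
})

test_that("paired comparison reduces to the signed-rank on differences", {
  expect_warning(r <- paired_ami_test(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)),
                 "all values are zero")
  expect_equal(r$p, 1)
  r <- paired_ami_test(rep(0, 5), c(1, 2, 3, 4, 5))
  expect_equal(r$p, 2 / 32)
  expect_equal(r$statistic, 15)
  expect_error(paired_ami_test(1:3, 1:4), "equal length")
})

test_that("pooling check matches exact rank enumeration", {
  r <- pool_check(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p, 1)
  expect_true(r$pool)
  r <- pool_check(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p, 2 / 20)
  expect_true(r$pool)            # 0.1 >= alpha = 0.05
  expect_false(pool_check(c(1, 2, 3), c(10, 11, 12), alpha = 0.2)$pool)
  expect_error(pool_check(numeric(0), 1:3), "non-empty")
})

test_that("test p-values agree with exhaustive enumeration for small n", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    x <- round(rnorm(n, 0.2, 1), 6)
    got <- signed_rank_vs_zero(x)
    expect_equal(got$p, exact_signed_rank_p(x), info = paste("signed-rank", i))
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    a <- round(rnorm(n1), 6); b <- round(rnorm(n2, 0.5), 6)
    got <- rank_sum_test(a, b)
    expect_equal(got$p, exact_rank_sum_p(a, b), info = paste("rank-sum", i))
  }
})

test_that("population summary medians match a sort-based oracle", {
  set.seed(42)
  n <- 15
  indices <- data.frame(
    cell_id = sprintf("c%03d", 1:n),
    imi_fix = rnorm(n, 0, 0.2),
    ami_control = rnorm(n, 0.1, 0.1),
    ami_injection = rnorm(n, 0.1, 0.1),
    stringsAsFactors = FALSE
  )
  indices$perc_ami_control <- to_percent(indices$ami_control)
  indices$perc_ami_injection <- to_percent(indices$ami_injection)
  inclusion <- data.frame(
    cell_id = indices$cell_id, pass = TRUE,
    injection_effect = rep(c("increase", "decrease", "none"), each = 5),
    stringsAsFactors = FALSE
  )
  pop <- summarize_population(indices, inclusion)
  expect_equal(pop$n_cells, c(15, 5, 5))
  for (grp in c("all", "increase", "decrease")) {
    sel <- if (grp == "all") rep(TRUE, n) else inclusion$injection_effect == grp
    row <- pop[pop$subgroup == grp, ]
    expect_equal(row$median_ami_control, sort_median(indices$ami_control[sel]))
    expect_equal(row$median_imi_fix, sort_median(indices$imi_fix[sel]))
    expect_equal(row$perc_of_median_ami_control,
                 to_percent(sort_median(indices$ami_control[sel])))
    expect_equal(row$median_perc_ami_control,
                 sort_median(indices$perc_ami_control[sel]))
  }
})

test_that("cells failing criterion 1 never enter the population summary", {
  indices <- data.frame(
    cell_id = c("c001", "c002"), imi_fix = c(0.5, 0.1),
    ami_control = c(0.2, 0.1), ami_injection = c(0.2, 0.1),
    perc_ami_control = c(50, 22), perc_ami_injection = c(50, 22),
    stringsAsFactors = FALSE
  )
  inclusion <- data.frame(cell_id = c("c001", "c002"), pass = c(FALSE, TRUE),
                          injection_effect = c("increase", "none"),
                          stringsAsFactors = FALSE)
  pop <- summarize_population(indices, inclusion)
  expect_equal(pop$n_cells[pop$subgroup == "all"], 1)
  expect_equal(pop$n_cells[pop$subgroup == "increase"], 0)
  expect_true(is.na(pop$median_ami_control[pop$subgroup == "increase"]))
})

test_that("a sign-mixed injection population recovers both subgroups", {
  cfg <- generator_config(
    n_cells = 10, trials_per_condition_per_block = 15,
    injection_mixture = c(increase = 0.5, decrease = 0.5, none = 0),
    injection_gains = c(increase = 2, decrease = 0.5))
  s <- generate_session(cfg, seed = 43)
  rt <- window_rates(s$trials, s$spikes)
  rt$block <- assign_blocks_all(s$trials, s$injections)
  inc <- inclusion_report(rt)
  idx <- modulation_indices(rt)
  pop <- summarize_population(idx, inc)
  expect_gt(pop$n_cells[pop$subgroup == "increase"], 0)
  expect_gt(pop$n_cells[pop$subgroup == "decrease"], 0)
  # classification direction matches the generating gains
  merged <- merge(inc, s$ground_truth, by = "cell_id")
  called <- merged$injection_effect != "none"
  expect_true(all(merged$injection_effect[called] == merged$class[called]))
})

test_that("the population report renders every subgroup", {
  cfg <- generator_config(n_cells = 4, trials_per_condition_per_block = 8)
  s <- generate_session(cfg, seed = 44)
  rt <- window_rates(s$trials, s$spikes)
  rt$block <- assign_blocks_all(s$trials, s$injections)
  rt$subject <- sub("-.*$", "", rt$session_id)
  pop <- summarize_population(modulation_indices(rt), inclusion_report(rt))
  txt <- population_report(pop, "scopolamine")
  expect_true(any(grepl("Subgroup: all", txt)))
  expect_true(any(grepl("paired AMI comparison", txt)))
  expect_true(any(grepl("pooled", txt)))
})
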