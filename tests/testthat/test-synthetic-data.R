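small_cfg <- function(...) {
  generator_config(n_cells = 3, trials_per_condition_per_block = 10, ...)
}

test_that("identical config and seed give byte-identical output", {
  s1 <- generate_session(small_cfg(), seed = 5)
  s2 <- generate_session(small_cfg(), seed = 5)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$injections, s2$injections)
  expect_identical(s1$ground_truth, s2$ground_truth)
  s3 <- generate_session(small_cfg(), seed = 6)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("trial counts and spike ownership are conserved", {
  cfg <- small_cfg()
  s <- generate_session(cfg, seed = 5)
  # 5 trial types x trials per type x 3 blocks x cells
  expect_equal(nrow(s$trials), 5 * 10 * 3 * 3)
  expect_true(all(s$spikes$trial_id %in% s$trials$trial_id))
  expect_false(anyDuplicated(s$trials$trial_id) > 0)
  counts <- table(s$trials$cell_id, paste(s$trials$condition, s$trials$direction))
  expect_true(all(counts == 30))  # 10 per block x 3 blocks
})

test_that("spikes are sorted and lie strictly within their trial", {
  cfg <- small_cfg()
  s <- generate_session(cfg, seed = 5)
  tr <- s$trials
  wmax <- cfg$change_window_ms[2] / 1000
  dur <- tr$stim_onset_s +
    ifelse(is.na(tr$change_time_s), wmax, tr$change_time_s) +
    cfg$response_window_s
  i <- match(s$spikes$trial_id, tr$trial_id)
  expect_true(all(s$spikes$spike_time_s > 0))
  expect_true(all(s$spikes$spike_time_s < dur[i]))
  by_sorted <- tapply(s$spikes$spike_time_s, s$spikes$trial_id,
                      function(x) !is.unsorted(x))
  expect_true(all(by_sorted))
})

test_that("catch trials are an exact floor proportion per condition", {
  set.seed(31)
  tr <- generate_trials(100, "attend-in", generator_config())
  expect_equal(sum(is.na(tr$change_time_s)), 10)
  tr0 <- generate_trials(50, "attend-out", generator_config(catch_fraction = 0))
  expect_true(all(!is.na(tr0$change_time_s)))
  expect_true(all(tr0$change_time_s >= 0.2 & tr0$change_time_s <= 2.5))
})

test_that("change times stay inside the configured window", {
  set.seed(32)
  cfg <- generator_config(catch_fraction = 0, change_window_ms = c(400, 1200))
  tr <- generate_trials(1e4, "attend-fix", cfg)
  expect_gte(min(tr$change_time_s), 0.4)
  expect_lte(max(tr$change_time_s), 1.2)
  # uniform draws approach both edges
  expect_lt(min(tr$change_time_s), 0.401)
  expect_gt(max(tr$change_time_s), 1.199)
})

test_that("trial records respect the task timing and labeling contracts", {
  set.seed(33)
  cfg <- generator_config()
  tin <- generate_trial("attend-in", cfg)
  expect_equal(tin$stim_onset_s, 0.15 + 0.15 + 0.35)
  tfo <- generate_trial("fix-only", cfg, direction = "preferred")
  expect_equal(tfo$direction, "none")
  expect_error(generate_trial("attend-up", cfg), "unknown condition")
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(baseline_rate = 0), "positive")
  expect_error(generator_config(attention_gain = -1), "positive")
  expect_error(generator_config(catch_fraction = 1.2), "catch_fraction")
  expect_error(generator_config(change_window_ms = c(100, 2000)), "200")
  expect_error(generator_config(change_window_ms = c(300, 2600)), "2500")
  expect_error(
    generator_config(injection_mixture = c(increase = 0.5, decrease = 0.5,
                                           none = 0.5)),
    "sum to 1")
  expect_error(generator_config(injection_times = c(700, 600)),
               "strictly increasing")
  expect_error(generator_config(injection_gains = c(increase = 0.9,
                                                    decrease = 0.5)),
               "injection gains")
})

test_that("block layout yields the configured trials per condition per block", {
  s <- generate_session(small_cfg(), seed = 8)
  rt <- s$trials
  rt$block <- assign_blocks_all(rt, s$injections)
  counts <- table(rt$cell_id, rt$block, paste(rt$condition, rt$direction))
  expect_true(all(counts == 10))             # every cell x block x type
  expect_false("transition" %in% rt$block)   # no trials fall in the gap
})

test_that("injection gain multiplies firing rates during the injection block", {
  cfg <- generator_config(
    n_cells = 6, trials_per_condition_per_block = 40,
    injection_mixture = c(increase = 1, decrease = 0, none = 0),
    injection_gains = c(increase = 1.5, decrease = 0.5))
  s <- generate_session(cfg, seed = 9)
  rt <- window_rates(s$trials, s$spikes)
  rt$block <- assign_blocks_all(s$trials, s$injections)
  sel <- rt$condition == "attend-fix" & rt$direction == "preferred"
  r1 <- mean(rt$rate[sel & rt$block == "control"])
  r2 <- mean(rt$rate[sel & rt$block == "injection"])
  r3 <- mean(rt$rate[sel & rt$block == "recovery"])
  # 240 trials per block: Poisson SE of the mean is ~0.4 spikes/s
  expect_lt(abs(r1 - 20), 1.5)
  expect_lt(abs(r2 - 30), 1.5)
  expect_lt(abs(r3 - 20), 1.5)  # effect washes out after the last injection
})

test_that("aborted trials can be injected and carry the abort label", {
  cfg <- small_cfg(abort_fraction = 0.2)
  s <- generate_session(cfg, seed = 10)
  expect_true(any(s$trials$outcome == "abort"))
  expect_true(all(s$trials$outcome %in% c("hit", "abort")))
})

test_that("an explicit injection timeline is honored", {
  cfg <- small_cfg(injection_times = c(300, 360, 420))
  s <- generate_session(cfg, seed = 11)
  expect_equal(unique(s$injections$time_s), c(300, 360, 420))
})
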