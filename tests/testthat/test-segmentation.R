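mk_trials <- function(starts) {
  data.frame(trial_id = sprintf("t%03d", seq_along(starts)),
             trial_start_s = starts, stringsAsFactors = FALSE)
}

test_that("block boundaries follow the 150 s rule", {
  tl <- session_timeline(c(600, 660, 720))
  got <- assign_blocks(mk_trials(c(500, 700, 800, 1000)), tl)
  expect_equal(as.character(got$block),
               c("control", "transition", "injection", "recovery"))
  # boundary trials: the injection block starts strictly after first + 150
  got <- assign_blocks(mk_trials(c(600, 750, 750.001, 870, 870.001)), tl)
  expect_equal(as.character(got$block),
               c("control", "transition", "injection", "injection", "recovery"))
})

test_that("sessions without injections are entirely control", {
  tl <- session_timeline(numeric(0))
  got <- assign_blocks(mk_trials(c(10, 500, 5000)), tl)
  expect_true(all(got$block == "control"))
})

test_that("repeated injection cycles are segmented per cycle", {
  tl <- session_timeline(c(600, 660, 1800, 1860))
  starts <- c(100, 700, 799, 1000, 1790, 1900, 2000, 2100)
  got <- assign_blocks(mk_trials(starts), tl)
  expect_equal(as.character(got$block),
               c("control", "transition", "injection", "recovery", "recovery",
                 "transition", "injection", "recovery"))
})

test_that("blocks partition the trials regardless of input order", {
  tl <- session_timeline(c(600, 660, 720))
  starts <- seq(0, 1500, by = 7)
  a <- assign_blocks(mk_trials(starts), tl)
  expect_equal(nrow(a), length(starts))
  expect_false(anyNA(a$block))
  ord <- sample(length(starts))
  b <- assign_blocks(mk_trials(starts)[ord, ], tl)
  expect_equal(b$block[order(b$trial_id)], a$block[order(a$trial_id)])
})

test_that("timeline construction rejects invalid inputs", {
  expect_error(session_timeline(c(700, 600)), "strictly increasing")
  expect_error(session_timeline(600, latency = 0), "positive")
  tl <- session_timeline(600, session_span = 1000)
  expect_error(assign_blocks(mk_trials(1500), tl), "session span")
})

test_that("cells violating exactly one sub-criterion fail with that reason", {
  good <- make_cell_rates()
  expect_true(check_criterion1(good)$pass)
  expect_equal(check_criterion1(good)$fail_reason, "")

  few <- make_cell_rates(n_attend_in_inj = 2)
  r <- check_criterion1(few)
  expect_false(r$pass)
  expect_equal(r$fail_reason, "trial-count")

  weak <- make_cell_rates(pref_rate = 6.9)
  r <- check_criterion1(weak)
  expect_false(r$pass)
  expect_equal(r$fail_reason, "responsiveness")
  expect_lt(r$mean_pref_rate, 7)

  flat <- make_cell_rates(flat_sensory = TRUE)
  r <- check_criterion1(flat)
  expect_false(r$pass)
  expect_equal(r$fail_reason, "sensory")
})

test_that("a cell at exactly 7 spikes/s passes responsiveness", {
  r <- check_criterion1(make_cell_rates(pref_rate = 7))
  expect_true(r$responsiveness_ok)
})

test_that("injection-effect classification is sign-correct and antisymmetric", {
  ctrl <- c(5, 6, 7, 8, 9)
  inj <- c(15, 16, 17, 18, 19)
  up <- classify_injection_effect(ctrl, inj)
  expect_equal(up$class, "increase")
  expect_equal(up$p, 2 / choose(10, 5))
  down <- classify_injection_effect(inj, ctrl)
  expect_equal(down$class, "decrease")
  expect_equal(down$p, up$p)

  same <- classify_injection_effect(ctrl, ctrl)
  expect_equal(same$class, "none")
  expect_equal(same$p, 1)

  expect_warning(out <- classify_injection_effect(c(5), c(1, 2, 3)),
                 "fewer than 2")
  expect_equal(out$class, "none")
})

test_that("inclusion report classifies only cells passing criterion 1", {
  good <- make_cell_rates("c001", inj_mult = 2.5)
  bad <- make_cell_rates("c002", pref_rate = 5, inj_mult = 2.5)
  rep <- inclusion_report(rbind(good, bad))
  expect_equal(rep$injection_effect[rep$cell_id == "c001"], "increase")
  expect_equal(rep$injection_effect[rep$cell_id == "c002"], "none")
  expect_true(is.na(rep$effect_p[rep$cell_id == "c002"]))
})
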