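test_that("behavioral summaries count outcomes and conserve probability", {
  tr <- data.frame(
    trial_id = 1:100,
    sample = "A",
    attention = "IN",
    is_catch = FALSE,
    outcome = c(rep("hit", 90), rep("miss", 6), rep("false_alarm", 4)),
    rt_ms = c(rep(400, 90), rep(NA, 6), rep(350, 4)),
    responded_position = NA_integer_, n_tests = 1L, target_position = 1L,
    trial_end_ms = 1500)
  bs <- behavior_summary(tr)
  all_row <- bs[bs$attention == "all", ]
  expect_equal(all_row$frac_correct, 0.90)
  expect_equal(all_row$frac_miss, 0.06)
  expect_equal(all_row$frac_false_alarm, 0.04)
  # all-catch session with no responses: 100% correct rejections
  trc <- tr
  trc$is_catch <- TRUE
  trc$outcome <- "correct_reject"
  trc$rt_ms <- NA_real_
  expect_equal(behavior_summary(trc)$frac_correct, c(1, 1))
  # conservation on a randomized outcome table
  set.seed(61)
  tr$outcome <- sample(c("hit", "miss", "false_alarm", "correct_reject"), 100,
                       replace = TRUE)
  bs2 <- behavior_summary(tr)
  expect_equal(bs2$frac_correct + bs2$frac_miss + bs2$frac_false_alarm,
               rep(1, nrow(bs2)))
  expect_error(behavior_summary(tr[0, ]), "no completed trials")
  # the simulator approximates the configured outcome rates
  ts <- generate_trials(task_config("two_location", n_trials = 2000), 62)
  bs3 <- behavior_summary(ts$trials)
  row <- bs3[bs3$attention == "all", ]
  expect_lt(abs(row$frac_correct - 0.90), 0.05)
  expect_lt(abs(row$frac_miss - 0.06 * 0.8), 0.03)
})

test_that("false-alarm maps locate the responded stimulus", {
  ts <- generate_trials(task_config("two_location", n_trials = 2500), 63)
  maps <- false_alarm_map(ts)
  expect_true(all(vapply(maps, function(m) all(m >= 0 & m <= 1), logical(1))))
  expect_true(all(dim(maps[[1]]) == c(8, 8)))
  # no false alarms -> all-zero grid
  ts0 <- generate_trials(task_config("two_location", n_trials = 300,
                                     behavior = c(hit = 0.94, miss = 0.06,
                                                  false_alarm = 0),
                                     catch_fa_rate = 0), 64)
  expect_true(all(unlist(false_alarm_map(ts0)) == 0))
  # independent group-by oracle for one grid
  tr <- ts$trials; ev <- ts$events
  ev$attention <- tr$attention[match(ev$trial_id, tr$trial_id)]
  sub <- ev[ev$location == "IN" & ev$attention == "IN", ]
  fa <- tr[tr$outcome == "false_alarm", ]
  resp <- merge(fa[, c("trial_id", "responded_position")], sub[sub$is_test, ],
                by.x = c("trial_id", "responded_position"),
                by.y = c("trial_id", "position"))
  for (cc in 1:8) for (dd in c(2, 5)) {
    n_pres <- sum(sub$color == cc & sub$direction == dd)
    n_resp <- sum(resp$color == cc & resp$direction == dd)
    expected <- if (n_pres == 0) 0 else n_resp / n_pres
    expect_equal(maps[["IN_IN"]][dd, cc], expected)
  }
  # a stimulus is only a false-alarm candidate when it is not the target:
  # the A conjunction draws false alarms only as sample-B opposite-target,
  # so its fraction stays below the per-stimulus average of the other cells
  off_target <- maps[["IN_IN"]][-7, -1]
  expect_lte(maps[["IN_IN"]][7, 1], max(off_target))
})

test_that("target-position ANOVA detects the first-position over-presentation", {
  make_sessions <- function(bias, n_sessions, seed) {
    lapply(seq_len(n_sessions), function(i) {
      generate_trials(task_config("two_location", n_trials = 150,
                                  target_position_bias = bias),
                      seed = seed + i)
    })
  }
  # equal counts in every session and position -> F exactly 0
  tabs <- data.frame(trial_id = 1:40, sample = "A", attention = "IN",
                     is_catch = FALSE, outcome = "hit", rt_ms = 400,
                     responded_position = rep(1:4, 10), n_tests = rep(1:4, 10),
                     target_position = rep(1:4, 10), trial_end_ms = 3000)
  same <- list(tabs, tabs, tabs)
  res0 <- target_position_anova(same)
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  # biased schedule (default: position 1 over-presented) is detected
  biased <- make_sessions(c(0.4, 0.22, 0.2, 0.18), 12, 700)
  res_b <- target_position_anova(biased)
  expect_lt(res_b$p, 0.01)
  # uniform schedule: null calibration over a few batches
  p_unif <- vapply(1:5, function(b) {
    target_position_anova(make_sessions(rep(0.25, 4), 8, 800 + 20 * b))$p
  }, numeric(1))
  expect_gte(mean(p_unif > 0.05), 0.8)
  expect_error(target_position_anova(same[1]), "2 sessions")
})

test_that("choice probability is negative for RT-coupled neurons and null otherwise", {
  cfg <- task_config("two_location", n_trials = 900)
  prof <- neuron_profile("cp1", w = -1, amp_match_hz = 35, cp_coupling = 1,
                         jitter_sd_ms = 40, rt_sd_ms = 10, attention_gain = 1)
  nr <- generate_neuron_spikes(prof, generate_trials(cfg, 71), 72)
  cp <- choice_probability(nr)
  expect_lt(cp$summary_r, -0.1)
  expect_true(all(abs(cp$r) <= 1))
  # uncoupled neuron: |r| small
  prof0 <- neuron_profile("cp0", w = -1, amp_match_hz = 35, cp_coupling = 0,
                          jitter_sd_ms = 40, attention_gain = 1)
  nr0 <- generate_neuron_spikes(prof0, generate_trials(cfg, 73), 74)
  cp0 <- choice_probability(nr0)
  expect_lt(abs(cp0$summary_r), 0.1)
  # qualifying-trial bookkeeping: hits at positions >= 2 with preferred sample
  ev <- event_table(nr, tests_only = TRUE, correct_only = TRUE)
  n_qual <- sum(ev$match_class == "target" & ev$outcome == "hit" &
                  ev$position >= 2 & ev$sample == cp$pref_sample)
  expect_equal(cp$n_trials, n_qual)
  expect_error(choice_probability(nr, min_trials = 1e6), "qualifying")
})

test_that("choice probability ignores shared additive offsets and flags constants", {
  # constant rate on every trial: every time point is degenerate, summary 0
  spec <- data.frame(sample = rep("A", 20), n_pre = 0, n_test = 30)
  nr <- manual_neuron(spec)
  nr$trials$is_catch <- FALSE
  nr$trials$outcome <- "hit"
  nr$trials$rt_ms <- seq(300, 490, by = 10)
  nr$trials$responded_position <- 2L
  nr$trials$target_position <- 2L
  # second event: the target at position 2
  ev2 <- nr$events
  ev2$position <- 2L
  ev2$onset_ms <- ev2$onset_ms + 450
  ev2$color <- 1L; ev2$direction <- 7L
  ev2$match_class <- "target"
  nr$events <- rbind(nr$events, ev2)
  nr$trials$trial_end_ms <- 1350 + 450 + 150
  # identical spike train in the target epoch for every trial
  for (tid in as.character(1:20)) {
    nr$spikes[[tid]] <- sort(c(nr$spikes[[tid]], seq(1360, 1780, by = 20)))
  }
  cp <- choice_probability(nr, pref_sample = "A")
  expect_true(all(cp$degenerate))
  expect_equal(cp$summary_r, 0)
})

test_that("choice probability covaries with VDI across a synthetic continuum", {
  cfg <- task_config("two_location", n_trials = 500)
  ws <- seq(-1, 1, length.out = 12)
  profs <- lapply(seq_along(ws), function(i) continuum_profile(paste0("c", i), ws[i]))
  ds <- generate_population(cfg, profs, seed = 75)$dataset
  pr <- neuron_profiles(ds, seed = 76, step_ms = 5, laterality = FALSE)
  res <- cp_vdi_correlation(pr)
  expect_gt(res$r, 0)
  expect_error(cp_vdi_correlation(pr[1:2, ]), "3")
})
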