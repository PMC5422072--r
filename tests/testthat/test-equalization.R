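test_that("pre-test rate ratio matches the worked firing-rate examples", {
  # 10 sample-A trials at 20 spikes/s pre-test, 10 sample-B at 25 spikes/s
  spec <- data.frame(sample = rep(c("A", "B"), each = 10),
                     n_pre = rep(c(4, 5), each = 10),
                     n_test = 20)
  nr <- manual_neuron(spec)
  pr <- pretest_ratio(nr, "sample")
  expect_equal(pr$ratio, 1.25)
  expect_equal(pr$target_condition, "B")
  expect_equal(pr$removal_fraction, 1 / 5)
  # equal rates
  spec2 <- data.frame(sample = rep(c("A", "B"), each = 5), n_pre = 4, n_test = 10)
  expect_equal(pretest_ratio(manual_neuron(spec2), "sample")$ratio, 1)
  # 10 vs 40 spikes/s
  spec3 <- data.frame(sample = rep(c("A", "B"), each = 5),
                      n_pre = rep(c(2, 8), each = 5), n_test = 10)
  pr3 <- pretest_ratio(manual_neuron(spec3), "sample")
  expect_equal(pr3$ratio, 4)
  expect_equal(pr3$removal_fraction, 0.75)
  # degenerate cases
  spec4 <- data.frame(sample = rep(c("A", "B"), each = 5), n_pre = 0, n_test = 5)
  expect_error(pretest_ratio(manual_neuron(spec4), "sample"), "nothing to equate")
  spec5 <- data.frame(sample = rep(c("A", "B"), each = 5),
                      n_pre = rep(c(0, 4), each = 5), n_test = 5)
  pr5 <- pretest_ratio(manual_neuron(spec5), "sample")
  expect_false(pr5$decimate)
})

test_that("decimation removes only target-condition test-period spikes", {
  spec <- data.frame(sample = rep(c("A", "B"), each = 10),
                     n_pre = rep(c(4, 5), each = 10), n_test = 30)
  nr <- manual_neuron(spec)
  plan <- pretest_ratio(nr, "sample")
  dec <- decimate_spikes(nr, plan, seed = 4)
  for (tid in as.character(1:10)) {           # sample A (non-target) untouched
    expect_identical(dec$spikes[[tid]], nr$spikes[[tid]])
  }
  for (tid in as.character(11:20)) {          # subset property, pre-test intact
    s0 <- nr$spikes[[tid]]; s1 <- dec$spikes[[tid]]
    expect_true(all(s1 %in% s0))
    expect_identical(s1[s1 < 900], s0[s0 < 900])
    expect_lte(length(s1), length(s0))
  }
  # removal_fraction 0 is the identity
  spec2 <- data.frame(sample = rep(c("A", "B"), each = 5), n_pre = 4, n_test = 10)
  nr2 <- manual_neuron(spec2)
  dec2 <- decimate_spikes(nr2, pretest_ratio(nr2, "sample"), seed = 1)
  expect_identical(dec2$spikes, nr2$spikes)
  # determinism
  expect_identical(decimate_spikes(nr, plan, seed = 9)$spikes,
                   decimate_spikes(nr, plan, seed = 9)$spikes)
})

test_that("Bernoulli thinning retains the binomially expected spike count", {
  # one target-condition trial stuffed with 100,000 test-period spikes
  spec <- data.frame(sample = c("A", "B"), n_pre = c(3, 4), n_test = 0)
  nr <- manual_neuron(spec)
  nr$trials$trial_end_ms <- 1e5 + 2000
  set.seed(99)
  pre2 <- nr$spikes[["2"]][nr$spikes[["2"]] < 900]
  nr$spikes[["2"]] <- sort(c(pre2, runif(100000, 900, 1e5)))
  plan <- pretest_ratio(nr, "sample")
  expect_equal(plan$removal_fraction, 0.25)
  dec <- decimate_spikes(nr, plan, seed = 17)
  kept <- sum(dec$spikes[["2"]] >= 900)
  ci <- qbinom(c(5e-4, 1 - 5e-4), 100000, 0.75)
  expect_gte(kept, ci[1]); expect_lte(kept, ci[2])
  expect_true(all(dec$spikes[["2"]] %in% nr$spikes[["2"]]))
  # exact-count mode removes exactly round(f * N)
  dec_e <- decimate_spikes(nr, plan, seed = 17, method = "exact")
  expect_equal(sum(dec_e$spikes[["2"]] >= 900), 75000)
})

test_that("sample equalization flattens memory-driven rate differences", {
  cfg <- task_config("two_location", n_trials = 1000)
  prof <- neuron_profile("mem", baseline_hz = 20, amp_identity_hz = 0,
                         amp_match_hz = 0, sample_memory_gain = 0.25,
                         attention_gain = 1)
  nr <- generate_neuron_spikes(prof, generate_trials(cfg, 41), 42)
  pr_before <- pretest_ratio(nr, "sample")
  expect_gt(pr_before$ratio, 1.15)
  eq <- equalize_by_sample(nr, seed = 7)
  pr_after <- pretest_ratio(eq, "sample")
  # position-1 pre-test windows fall in the (undecimated) delay epoch; restrict
  # the audit to windows inside the decimated test period
  ev <- event_table(eq)
  ev2 <- ev[ev$position >= 2, ]
  rates <- vapply(c("A", "B"), function(s) {
    mean_rate(aligned_counts(eq, ev2[ev2$sample == s, ], c(-200, 0)), 200)
  }, numeric(1))
  expect_lt(abs(rates[1] / rates[2] - 1), 0.05)
  # a memory-only neuron shows no pre-onset identity selectivity afterwards
  tr <- sliding_selectivity(eq, "identity", step_ms = 5)
  pre <- tr$roc[tr$times_ms < -50]
  expect_lt(max(abs(pre - 0.5)), 0.1)
  expect_false(any(tr$significant[tr$times_ms < -50]))
})

test_that("attention equalization equates IN and OUT pre-test rates", {
  cfg <- task_config("two_location", n_trials = 1200)
  prof <- neuron_profile("att", baseline_hz = 20, amp_identity_hz = 0,
                         amp_match_hz = 0, attention_gain = 1.5)
  nr <- generate_neuron_spikes(prof, generate_trials(cfg, 51), 52)
  eq <- equalize_by_attention(nr, seed = 8)
  ev <- event_table(eq)
  ev2 <- ev[ev$position >= 2, ]
  rates <- vapply(c("IN", "OUT"), function(a) {
    mean_rate(aligned_counts(eq, ev2[ev2$attention == a, ], c(-200, 0)), 200)
  }, numeric(1))
  expect_gt(rates[1] / rates[2], 0.95)
  expect_lt(rates[1] / rates[2], 1.05)
  # gain 1.0 is a near no-op
  prof0 <- neuron_profile("att0", baseline_hz = 20, amp_identity_hz = 0,
                          amp_match_hz = 0, attention_gain = 1)
  nr0 <- generate_neuron_spikes(prof0, generate_trials(
    task_config("two_location", n_trials = 600), 53), 54)
  plan0 <- pretest_ratio(nr0, "attention")
  expect_lt(plan0$removal_fraction, 0.06)
  # one_location data has no attention OUT
  nr1 <- generate_neuron_spikes(neuron_profile("one"), generate_trials(
    task_config("one_location", n_trials = 50), 55), 56)
  expect_error(equalize_by_attention(nr1), "two_location")
})

test_that("attention ratio excludes delay-epoch windows at sequence position one", {
  # memory gain elevates the delay but not the test period: including
  # position-1 windows (delay) must change the measured ratio
  cfg <- task_config("two_location", n_trials = 1000)
  prof <- neuron_profile("dl", baseline_hz = 20, amp_identity_hz = 0,
                         amp_match_hz = 0, attention_gain = 1.25,
                         sample_memory_gain = 0)
  nr <- generate_neuron_spikes(prof, generate_trials(cfg, 61), 62)
  # inflate delay-epoch rate artificially by injecting spikes into [700, 900)
  # of attention-IN trials only
  set.seed(63)
  for (tid in nr$trials$trial_id[nr$trials$attention == "IN"]) {
    extra <- runif(8, 700, 899)
    nr$spikes[[as.character(tid)]] <-
      sort(c(nr$spikes[[as.character(tid)]], extra))
  }
  plan_attention <- pretest_ratio(nr, "attention")
  # manual ratio over all positions (including position 1)
  ev <- event_table(nr)
  rates_all <- vapply(c("IN", "OUT"), function(a) {
    mean_rate(aligned_counts(nr, ev[ev$attention == a, ], c(-200, 0)), 200)
  }, numeric(1))
  ratio_all <- max(rates_all) / min(rates_all)
  expect_gt(abs(ratio_all - plan_attention$ratio), 0.05)
})
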