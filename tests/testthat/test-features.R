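test_that("additivity index vanishes for any additive construction", {
  set.seed(31)
  for (i in 1:1000) {
    C <- runif(1, 0, 10); D <- runif(1, 0, 10); I <- runif(1, 0, 10)
    cr <- list(T = C + D + I, CM = C + I, DM = D + I, OT = I)
    expect_identical(additivity_index(cr), 0)
  }
  # super-additive arithmetic example
  expect_equal(additivity_index(list(T = 2.5, CM = 1, DM = 1, OT = 0.5)), 1)
  # baseline invariance: adding a constant to all four responses changes nothing
  set.seed(32)
  for (i in 1:50) {
    r <- as.list(setNames(runif(4, 0, 5), c("T", "CM", "DM", "OT")))
    k <- runif(1, -10, 10)
    shifted <- lapply(r, `+`, k)
    expect_equal(additivity_index(shifted), additivity_index(r), tolerance = 1e-12)
  }
})

test_that("condition responses recover the generative response gradient", {
  cfg <- task_config("two_location", n_trials = 800, p_opposite = 0.2)
  # additive feature coder preferring the A conjunction
  prof <- continuum_profile("add", w = 1)
  nr <- generate_neuron_spikes(prof, generate_trials(cfg, 111), 112)
  cr <- condition_responses(nr)
  expect_true(all(cr$n >= 3))
  # pure color coder whose preference follows the relevant color: CM tracks T
  prof_c <- neuron_profile("col", amp_identity_hz = 0, amp_match_hz = 0,
                           color_slope_per_step = 0, fba_color_shift = 3,
                           attention_gain = 1, baseline_hz = 25)
  nr_c <- generate_neuron_spikes(prof_c, generate_trials(cfg, 113), 114)
  cr_c <- condition_responses(nr_c)
  expect_gt(cr_c$T, cr_c$DM)
  expect_gt(cr_c$CM, cr_c$DM)
  expect_gt(cr_c$DM, cr_c$OT)
  expect_lt(abs(cr_c$T - cr_c$CM), 0.2)
  # identically responding neuron: all four responses equal
  prof_f <- neuron_profile("flat", amp_identity_hz = 0, amp_match_hz = 0,
                           attention_gain = 1, baseline_hz = 30)
  nr_f <- generate_neuron_spikes(prof_f, generate_trials(cfg, 115), 116)
  cr_f <- condition_responses(nr_f)
  expect_lt(max(abs(c(cr_f$T, cr_f$CM, cr_f$DM) - cr_f$OT)), 0.15)
  # empty class errors by name
  few <- generate_neuron_spikes(neuron_profile("few"), generate_trials(
    task_config("two_location", n_trials = 6, catch_fraction = 0), 117), 118)
  expect_error(condition_responses(few), "CM|DM|OT|class")
})

test_that("match-driven neurons are super-additive, feature coders additive", {
  cfg <- task_config("two_location", n_trials = 700, p_opposite = 0.2)
  n_pos <- 0
  for (s in 1:10) {
    prof <- continuum_profile(paste0("m", s), w = -1)   # pure match coder
    nr <- generate_neuron_spikes(prof, generate_trials(cfg, 120 + s), 140 + s)
    n_pos <- n_pos + (additivity_index(condition_responses(nr)) > 0)
  }
  expect_gte(n_pos, 9)   # super-additive in >= 90% of simulated neurons
  idx_add <- vapply(1:6, function(s) {
    prof <- continuum_profile(paste0("a", s), w = 1)    # pure feature coder
    nr <- generate_neuron_spikes(prof, generate_trials(cfg, 160 + s), 180 + s)
    additivity_index(condition_responses(nr))
  }, numeric(1))
  expect_lt(abs(median(idx_add)), 0.25)
})

test_that("color slope matches closed-form least squares and its symmetries", {
  # engineered responses 10, 12, ..., 24 across colors 1..8 -> slope 2
  x <- 1:8
  y <- seq(10, 24, by = 2)
  expect_equal(unname(coef(lm(y ~ x))[2]), 2)
  cfg <- task_config("two_location", n_trials = 900)
  prof <- neuron_profile("cs", amp_identity_hz = 0, amp_match_hz = 0,
                         color_slope_per_step = 2, attention_gain = 1,
                         baseline_hz = 30)
  nr <- generate_neuron_spikes(prof, generate_trials(cfg, 211), 212)
  sA <- color_slope(nr, "A")
  expect_lt(abs(sA - 2), 0.6)
  # flat tuning -> slope ~ 0; reversing the color axis negates the slope
  prof0 <- neuron_profile("cs0", amp_identity_hz = 0, amp_match_hz = 0,
                          attention_gain = 1, baseline_hz = 30)
  nr0 <- generate_neuron_spikes(prof0, generate_trials(cfg, 213), 214)
  expect_lt(abs(color_slope(nr0, "A")), 0.5)
  nr_rev <- nr
  nr_rev$events$color <- 9L - nr_rev$events$color
  samp <- setNames(nr_rev$trials$sample, as.character(nr_rev$trials$trial_id))
  nr_rev$events$match_class <- match_class(
    nr_rev$events$color, nr_rev$events$direction,
    samp[as.character(nr_rev$events$trial_id)])
  expect_equal(color_slope(nr_rev, "A"), -sA, tolerance = 0.35)
})

test_that("attention shifts color tuning with the documented sign convention", {
  cfg <- task_config("two_location", n_trials = 900)
  # displacement toward the relevant color -> negative slope difference
  prof <- neuron_profile("fba", amp_identity_hz = 0, amp_match_hz = 0,
                         color_slope_per_step = 1, fba_color_shift = 1.5,
                         attention_gain = 1, baseline_hz = 30)
  nr <- generate_neuron_spikes(prof, generate_trials(cfg, 221), 222)
  expect_lt(color_shift(nr), 0)
  # identical tuning under both samples -> shift ~ 0, antisymmetric under swap
  prof0 <- neuron_profile("fba0", amp_identity_hz = 0, amp_match_hz = 0,
                          color_slope_per_step = 2, attention_gain = 1,
                          baseline_hz = 30)
  nr0 <- generate_neuron_spikes(prof0, generate_trials(cfg, 223), 224)
  expect_lt(abs(color_shift(nr0)), 0.8)
  sw <- nr
  sw$trials$sample <- ifelse(sw$trials$sample == "A", "B", "A")
  samp <- setNames(sw$trials$sample, as.character(sw$trials$trial_id))
  sw$events$match_class <- match_class(sw$events$color, sw$events$direction,
                                       samp[as.character(sw$events$trial_id)])
  expect_equal(color_shift(sw), -color_shift(nr), tolerance = 1e-12)
})

test_that("preferred direction follows the rate-weighted vector method", {
  # undefined for perfectly flat tuning (zero resultant): 8 identical-count
  # events, one per direction
  spec <- data.frame(sample = rep("A", 8), n_pre = 0, n_test = 10)
  nr_flat <- manual_neuron(spec)
  nr_flat$events$color <- 3L
  nr_flat$events$direction <- 1:8
  nr_flat$events$match_class <- match_class(3L, 1:8, "A")
  expect_true(is.na(preferred_direction(nr_flat, "A")))
  cfg <- task_config("two_location", n_trials = 600)
  # noiseless cosine tuning peaked at 90 deg recovers 90 within a degree
  fr <- 5 + 4 * cos((direction_angle(1:8) - 90) * pi / 180)
  th <- direction_angle(1:8) * pi / 180
  ang <- atan2(sum(fr * sin(th)), sum(fr * cos(th))) * 180 / pi
  expect_equal(ang %% 360, 90, tolerance = 1e-9)
  # generator with von Mises tuning at 90 recovers the peak
  prof <- neuron_profile("dv", amp_identity_hz = 0, amp_match_hz = 0,
                         amp_direction_hz = 30, direction_pref_deg = 90,
                         direction_kappa = 2, attention_gain = 1,
                         baseline_hz = 5)
  nr <- generate_neuron_spikes(prof, generate_trials(cfg, 233), 234)
  pd <- preferred_direction(nr, "A")
  expect_lt(abs(dcmlip:::circ_diff(pd, 90)), 15)
})

test_that("direction shifts are signed toward the relevant direction and bounded", {
  cfg <- task_config("two_location", n_trials = 900)
  # attention displaces the preferred direction toward the sample's direction
  prof <- neuron_profile("ds", amp_identity_hz = 0, amp_match_hz = 0,
                         amp_direction_hz = 30, direction_pref_deg = 180,
                         direction_kappa = 2, fba_direction_shift_deg = 30,
                         attention_gain = 1, baseline_hz = 5)
  nr <- generate_neuron_spikes(prof, generate_trials(cfg, 241), 242)
  sh <- direction_shift(nr)
  expect_false(is.na(sh))
  expect_gt(sh, 0)
  expect_lte(abs(sh), 180)
  # no displacement -> shift near zero
  prof0 <- neuron_profile("ds0", amp_identity_hz = 0, amp_match_hz = 0,
                          amp_direction_hz = 30, direction_pref_deg = 180,
                          direction_kappa = 2, attention_gain = 1,
                          baseline_hz = 5)
  nr0 <- generate_neuron_spikes(prof0, generate_trials(cfg, 243), 244)
  expect_lt(abs(direction_shift(nr0)), 20)
})

test_that("profile correlations behave on exact, null, and degenerate input", {
  d <- data.frame(x = 1:20, y = 1:20)
  expect_equal(correlate_profiles(d, "x", "y")$r, 1)
  set.seed(41)
  d2 <- data.frame(x = rnorm(1000), y = rnorm(1000))
  expect_lt(abs(correlate_profiles(d2, "x", "y")$r), 0.1)
  expect_error(correlate_profiles(data.frame(x = 1:2, y = 2:1), "x", "y"), "3")
  expect_error(correlate_profiles(data.frame(x = rep(1, 5), y = 1:5), "x", "y"),
               "zero variance")
})

test_that("sliding additivity summarizes the continuum in VDI order", {
  set.seed(51)
  prof <- data.frame(vdi = runif(60, -1, 1))
  prof$additivity <- -0.5 * prof$vdi + rnorm(60, 0, 0.05)
  sl <- sliding_additivity(prof, width = 31)
  expect_equal(nrow(sl), 30)
  expect_true(all(diff(sl$vdi) > 0))
  expect_gt(sl$additivity[1], sl$additivity[30])
  expect_error(sliding_additivity(prof[1:10, ], width = 31), "31")
})
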