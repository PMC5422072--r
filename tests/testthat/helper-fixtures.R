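# Hand-built minimal neuron: `spec` is a data.frame with one row per trial:
# sample, n pre-window spikes (in [700, 900)), n test-period spikes (in
# [900, 1350)), attention, outcome. One opposite-target test event per trial
# at onset 900 (duration 450) so no trial needs a target.
manual_neuron <- function(spec, variant = "two_location", epoch = 450) {
  n <- nrow(spec)
  onset <- 2 * epoch
  trials <- data.frame(
    trial_id = seq_len(n), sample = spec$sample,
    attention = spec$attention %||% rep("IN", n),
    is_catch = TRUE, outcome = spec$outcome %||% rep("correct_reject", n),
    rt_ms = NA_real_, responded_position = NA_integer_,
    n_tests = 1L, target_position = NA_integer_,
    trial_end_ms = onset + epoch + 150
  )
  opp <- ifelse(spec$sample == "A", "B", "A")
  ev <- data.frame(
    trial_id = seq_len(n), position = 1L, onset_ms = onset, duration_ms = epoch,
    location = "IN",
    color = vapply(opp, function(s) dcmlip:::SAMPLE_DEFS[[s]]$color, integer(1)),
    direction = vapply(opp, function(s) dcmlip:::SAMPLE_DEFS[[s]]$direction, integer(1)),
    is_test = TRUE
  )
  ev$match_class <- match_class(ev$color, ev$direction, spec$sample)
  spikes <- lapply(seq_len(n), function(i) {
    pre <- if (spec$n_pre[i] > 0) {
      seq(onset - 200, onset - 1, length.out = spec$n_pre[i])
    } else numeric(0)
    post <- if (spec$n_test[i] > 0) {
      seq(onset, onset + epoch - 1, length.out = spec$n_test[i])
    } else numeric(0)
    sort(c(pre, post))
  })
  names(spikes) <- as.character(seq_len(n))
  dcm_neuron(paste0("manual"), "m", variant, trials, ev, spikes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cached small population used by several IO / decoding tests.
small_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- task_config("two_location", n_trials = 120)
      profs <- lapply(1:5, function(i) {
        neuron_profile(paste0("n", i), w = c(-1, -0.5, 0, 0.5, 1)[i],
                       sample_memory_gain = 0.15)
      })
      cache <<- generate_population(cfg, profs, seed = 42)
    }
    cache
  }
})

# A selectivity trace object assembled by hand from a significance mask, for
# unit tests of the latency rule.
trace_from_mask <- function(times_ms, sig, rt = 450, step = 1) {
  structure(
    data.frame(times_ms = times_ms, roc = 0.5, p = ifelse(sig, 0, 1),
               significant = sig),
    class = c("dcm_selectivity_trace", "data.frame"),
    comparison = "identity", alpha = 0.01, n_windows = length(times_ms),
    pref = "stimulus_A", step_ms = step, session_mean_rt_ms = rt)
}

# Continuum profile whose identity drive comes from linear feature terms
# (color ramp + direction tuning preferring the A conjunction) and whose
# match drive comes from the match term; used by sign-chain tests.
continuum_profile <- function(id, w, cp_by_match = TRUE, fba = 0) {
  id_gain <- (1 + w) / 2
  neuron_profile(id, w = w,
                 amp_identity_hz = 0,
                 amp_match_hz = 30,
                 color_slope_per_step = -2.5 * id_gain,
                 amp_direction_hz = 18 * id_gain,
                 direction_kappa = 1.5,
                 direction_pref_deg = 270,
                 fba_color_shift = fba,
                 cp_coupling = if (cp_by_match) (1 - w) / 2 else 0,
                 jitter_sd_ms = 40, rt_sd_ms = 20,
                 sample_memory_gain = 0.1)
}
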