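#' Task configuration for the DCM simulator
#'
#' Describes one behavioral session of the delayed-conjunction-matching task.
#' The two-location variant uses 450-ms sample/delay/test epochs, up to 4 test
#' stimuli per trial, 20% catch trials, and simultaneous distractor stimuli in
#' the opposite hemifield; the one-location variant uses 550-ms epochs, up to
#' 3 test stimuli, 25% catch trials and no distractors.
#'
#' @param variant "two_location" or "one_location".
#' @param n_trials number of trials to simulate.
#' @param epoch_ms epoch duration (sample = delay = test); default 450 or 550
#'   by variant.
#' @param max_tests maximum sequence length; default 4 or 3 by variant.
#' @param catch_fraction fraction of trials without a target; default 0.20 or
#'   0.25 by variant.
#' @param target_position_bias weights over sequence positions for the target;
#'   defaults over-represent position 1 as observed behaviorally. Use uniform
#'   weights to remove the bias.
#' @param p_opposite probability that a pre-target (or catch) test stimulus is
#'   the opposite-target conjunction rather than one of the 62 remaining
#'   conjunctions.
#' @param behavior named probabilities `hit`, `miss`, `false_alarm` for
#'   non-catch trials (fixation breaks are not modeled).
#' @param catch_fa_rate false-alarm probability on catch trials.
#' @param pad_ms recording padding after the last test offset, so that
#'   analysis windows extending past the final stimulus stay inside the trial.
#' @return list of class `dcm_task_config`.
#' @export
task_config <- function(variant = c("two_location", "one_location"),
                        n_trials = 400,
                        epoch_ms = NULL, max_tests = NULL, catch_fraction = NULL,
                        target_position_bias = NULL,
                        p_opposite = 0.25,
                        behavior = c(hit = 0.90, miss = 0.06, false_alarm = 0.04),
                        catch_fa_rate = 0.04,
                        pad_ms = 150) {
  variant <- match.arg(variant)
  two <- variant == "two_location"
  epoch_ms <- epoch_ms %||% if (two) 450 else 550
  max_tests <- max_tests %||% if (two) 4L else 3L
  catch_fraction <- catch_fraction %||% if (two) 0.20 else 0.25
  if (is.null(target_position_bias)) {
    target_position_bias <- if (two) c(0.40, 0.22, 0.20, 0.18) else c(0.40, 0.32, 0.28)
  }
  if (length(target_position_bias) != max_tests) {
    stop("target_position_bias must have one weight per sequence position")
  }
  if (any(target_position_bias < 0) || sum(target_position_bias) <= 0) {
    stop("target_position_bias weights must be nonnegative with positive sum")
  }
  if (catch_fraction < 0 || catch_fraction >= 1) stop("catch_fraction must lie in [0, 1)")
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (abs(sum(behavior) - 1) > 1e-8) stop("behavior probabilities must sum to 1")
  structure(list(variant = variant, n_trials = as.integer(n_trials),
                 epoch_ms = epoch_ms, max_tests = as.integer(max_tests),
                 catch_fraction = catch_fraction,
                 target_position_bias = target_position_bias / sum(target_position_bias),
                 p_opposite = p_opposite, behavior = behavior,
                 catch_fa_rate = catch_fa_rate, pad_ms = pad_ms),
            class = "dcm_task_config")
}

#' Generative profile for one simulated neuron
#'
#' Parameterizes a neuron on the continuum from purely identity-selective
#' (`w = +1`) to purely match-selective (`w = -1`). Effective response
#' amplitudes follow the mixing rule
#' `amp_identity_eff = amp_identity_hz * (1 + w) / 2` and
#' `amp_match_eff = amp_match_hz * (1 - w) / 2`, a monotone map from `w` to
#' the expected visuo-decision index.
#'
#' @param neuron_id identifier.
#' @param w continuum weight in `[-1, 1]`.
#' @param baseline_hz spontaneous rate.
#' @param amp_identity_hz,amp_match_hz full-scale response amplitudes.
#' @param latency_identity_ms,latency_match_ms response onset latencies after
#'   test-stimulus onset.
#' @param rise_ms linear rise time of the response step (0 = pure step).
#' @param pref_identity preferred stimulus identity, "A" or "B".
#' @param attention_gain multiplicative gain on the baseline when attention is
#'   directed into the receptive field (>= 0).
#' @param bilateral_match when TRUE the match response is also evoked by
#'   targets outside the receptive field.
#' @param sample_memory_gain fractional rate increase throughout trials whose
#'   sample is the preferred identity (delay-period memory signal).
#' @param color_slope_per_step linear color tuning, Hz per color-index step
#'   (colors 1..8, centered on 4.5).
#' @param amp_direction_hz amplitude of circular direction tuning.
#' @param direction_kappa concentration of the (von Mises shaped) direction
#'   tuning curve.
#' @param direction_pref_deg preferred direction without attention.
#' @param fba_color_shift feature-based-attention displacement of the color
#'   ramp, expressed in Hz/step added toward the currently relevant color.
#' @param fba_direction_shift_deg displacement of the preferred direction
#'   toward the currently relevant direction, in degrees.
#' @param cp_coupling in `[0, 1]`: fraction of RT variability shared with the
#'   trial-by-trial jitter of the match-response onset.
#' @param jitter_sd_ms sd of the shared onset/RT jitter.
#' @param rt_mean_ms,rt_sd_ms reaction-time model (Gaussian, truncated at
#'   150 ms).
#' @param monkey_id session label.
#' @return list of class `dcm_neuron_profile`.
#' @export
neuron_profile <- function(neuron_id = "n1", w = 0,
                           baseline_hz = 10,
                           amp_identity_hz = 25, amp_match_hz = 25,
                           latency_identity_ms = 100, latency_match_ms = 190,
                           rise_ms = 0,
                           pref_identity = "A",
                           attention_gain = 1.3,
                           bilateral_match = FALSE,
                           sample_memory_gain = 0,
                           color_slope_per_step = 0,
                           amp_direction_hz = 0,
                           direction_kappa = 2,
                           direction_pref_deg = 90,
                           fba_color_shift = 0,
                           fba_direction_shift_deg = 0,
                           cp_coupling = 0,
                           jitter_sd_ms = 30,
                           rt_mean_ms = 400, rt_sd_ms = 50,
                           monkey_id = "sim") {
  if (abs(w) > 1) stop("continuum weight w must lie in [-1, 1]")
  if (attention_gain < 0) stop("attention_gain must be >= 0")
  if (rt_sd_ms < 0) stop("rt_sd_ms must be >= 0")
  if (cp_coupling < 0 || cp_coupling > 1) stop("cp_coupling must lie in [0, 1]")
  if (!pref_identity %in% c("A", "B")) stop("pref_identity must be A or B")
  structure(as.list(environment()), class = "dcm_neuron_profile")
}

#' Generate a session of DCM trials
#'
#' Draws trial schedules (samples, attention, stimulus sequences, outcomes)
#' without spikes or reaction times; those are attached per neuron by
#' [generate_neuron_spikes()]. Non-catch trials contain exactly one target at
#' a position drawn from `target_position_bias`; pre-target test stimuli are
#' opposite-targets with probability `p_opposite` and otherwise uniform draws
#' from the 62 remaining conjunctions; distractors (two-location variant) are
#' uniform over all 64 conjunctions. False-alarm trials are truncated at the
#' responded (non-target) stimulus.
#'
#' @param cfg [task_config()].
#' @param seed RNG seed.
#' @return list of class `dcm_trialset` with `trials` and `events`
#'   data.frames plus the config.
#' @export
generate_trials <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "dcm_task_config"))
  set.seed(seed)
  E <- cfg$epoch_ms
  two <- cfg$variant == "two_location"
  n <- cfg$n_trials
  universe <- stimulus_universe()

  trials <- vector("list", n)
  events <- vector("list", n)
  for (i in seq_len(n)) {
    sample_id <- if (runif(1) < 0.5) "A" else "B"
    attention <- if (two && runif(1) < 0.5) "OUT" else "IN"
    is_catch <- runif(1) < cfg$catch_fraction
    tgt <- SAMPLE_DEFS[[sample_id]]
    opp <- SAMPLE_DEFS[[if (sample_id == "A") "B" else "A"]]

    if (is_catch) {
      n_tests <- cfg$max_tests
      target_pos <- NA_integer_
      u <- runif(1)
      outcome <- if (u < cfg$catch_fa_rate) "false_alarm" else "correct_reject"
    } else {
      target_pos <- sample.int(cfg$max_tests, 1, prob = cfg$target_position_bias)
      n_tests <- target_pos
      u <- runif(1)
      b <- cumsum(cfg$behavior)
      outcome <- if (u < b[1]) "hit" else if (u < b[2]) "miss" else "false_alarm"
      # a false alarm needs a pre-target stimulus to respond to
      if (outcome == "false_alarm" && target_pos == 1L) outcome <- "hit"
    }

    col <- integer(n_tests); dir <- integer(n_tests)
    for (k in seq_len(n_tests)) {
      if (!is_catch && k == target_pos) {
        col[k] <- tgt$color; dir[k] <- tgt$direction
      } else if (runif(1) < cfg$p_opposite) {
        col[k] <- opp$color; dir[k] <- opp$direction
      } else {
        repeat {
          j <- sample.int(64L, 1)
          cj <- universe$color[j]; dj <- universe$direction[j]
          tgt_like <- cj == tgt$color && dj == tgt$direction
          opp_like <- cj == opp$color && dj == opp$direction
          if (!tgt_like && !opp_like) break
        }
        col[k] <- cj; dir[k] <- dj
      }
    }

    responded_pos <- NA_integer_
    if (outcome == "hit") {
      responded_pos <- target_pos
    } else if (outcome == "false_alarm") {
      cand <- if (is_catch) seq_len(n_tests) else seq_len(target_pos - 1L)
      responded_pos <- if (length(cand) == 1L) cand else sample(cand, 1)
      n_tests <- responded_pos           # trial ends at the erroneous response
      col <- col[seq_len(n_tests)]; dir <- dir[seq_len(n_tests)]
    }

    onsets <- 2 * E + (seq_len(n_tests) - 1) * E
    test_loc <- if (attention == "IN") "IN" else "OUT"
    ev <- data.frame(
      trial_id = i, position = seq_len(n_tests), onset_ms = onsets,
      duration_ms = E, location = test_loc, color = col, direction = dir,
      match_class = match_class(col, dir, sample_id), is_test = TRUE
    )
    if (two) {
      j <- sample.int(64L, n_tests, replace = TRUE)
      dev <- data.frame(
        trial_id = i, position = seq_len(n_tests), onset_ms = onsets,
        duration_ms = E, location = if (test_loc == "IN") "OUT" else "IN",
        color = universe$color[j], direction = universe$direction[j],
        match_class = match_class(universe$color[j], universe$direction[j], sample_id),
        is_test = FALSE
      )
      ev <- rbind(ev, dev)
    }
    events[[i]] <- ev
    trials[[i]] <- data.frame(
      trial_id = i, sample = sample_id, attention = attention,
      is_catch = is_catch, outcome = outcome, rt_ms = NA_real_,
      responded_position = responded_pos,
      n_tests = n_tests, target_position = target_pos,
      trial_end_ms = onsets[n_tests] + E + cfg$pad_ms
    )
  }
  structure(list(trials = do.call(rbind, trials),
                 events = do.call(rbind, events),
                 cfg = cfg, seed = seed),
            class = "dcm_trialset")
}

#' Reaction times coupled to match-response onset jitter
#'
#' `rt = rt_mean + cp_coupling * shared_jitter + independent noise`, truncated
#' below at 150 ms by redrawing the independent component. `shared_jitter` is
#' the same latent draw that shifts the trial's match-response onset in
#' [generate_neuron_spikes()], which is what makes firing dynamics and RT
#' covary when `cp_coupling > 0`.
#'
#' @param profile [neuron_profile()].
#' @param shared_jitter numeric vector of latent onset jitters (ms), one per
#'   trial.
#' @return numeric vector of RTs in ms (> 0).
#' @export
generate_rt <- function(profile, shared_jitter) {
  n <- length(shared_jitter)
  if (profile$rt_sd_ms < 0) stop("rt_sd_ms must be >= 0")
  base <- profile$rt_mean_ms + profile$cp_coupling * shared_jitter
  rt <- base + rnorm(n, 0, profile$rt_sd_ms)
  for (it in 1:100) {
    bad <- rt < 150
    if (!any(bad)) break
    if (profile$rt_sd_ms == 0) { rt[bad] <- 150; break }
    rt[bad] <- base[bad] + rnorm(sum(bad), 0, profile$rt_sd_ms)
  }
  rt[rt < 150] <- 150
  rt
}

# Shift an angle toward a target angle by at most `by` degrees (shorter arc).
shift_toward <- function(angle, target, by) {
  d <- ((target - angle + 180) %% 360) - 180
  angle + sign(d) * pmin(abs(d), by)
}

# Effective color slope under a given sample: the ramp is rotated about the
# color-axis midpoint toward the relevant color (1 for sample A, 8 for B).
effective_color_slope <- function(profile, sample_id) {
  rel_col <- SAMPLE_DEFS[[sample_id]]$color
  profile$color_slope_per_step +
    profile$fba_color_shift * (if (rel_col > 4.5) 1 else -1)
}

effective_direction_pref <- function(profile, sample_id) {
  rel_dir <- direction_angle(SAMPLE_DEFS[[sample_id]]$direction)
  shift_toward(profile$direction_pref_deg, rel_dir, profile$fba_direction_shift_deg)
}

#' Simulate one neuron's spike trains for a trial set
#'
#' Builds a 1-ms resolution firing-rate profile per trial and draws spikes
#' from an inhomogeneous Poisson process. The rate is
#' `floor0[ baseline * attention_gain^(attend IN) * (1 + memory term)
#'   + identity term + match term + feature terms ]`:
#' the identity term steps on `latency_identity_ms` after onset of
#' preferred-identity test stimuli, the match term steps on
#' `latency_match_ms + shared_jitter` after target onset (inside the RF, or on
#' either side for `bilateral_match` neurons), and the feature terms implement
#' linear color tuning and circular direction tuning with attention-dependent
#' displacement toward the currently relevant features. Reaction times for hit
#' and false-alarm trials are drawn here so that hit RTs share the match-onset
#' jitter.
#'
#' @param profile [neuron_profile()].
#' @param trialset [generate_trials()] output.
#' @param seed RNG seed.
#' @return a validated [dcm_neuron()].
#' @export
generate_neuron_spikes <- function(profile, trialset, seed = 1) {
  stopifnot(inherits(profile, "dcm_neuron_profile"),
            inherits(trialset, "dcm_trialset"))
  set.seed(seed)
  trials <- trialset$trials
  events <- trialset$events
  pref <- SAMPLE_DEFS[[profile$pref_identity]]
  n <- nrow(trials)

  shared_jitter <- rnorm(n, 0, profile$jitter_sd_ms)
  rt <- rep(NA_real_, n)
  hits <- trials$outcome == "hit"
  rt[hits] <- generate_rt(profile, shared_jitter[hits])
  fas <- trials$outcome == "false_alarm"
  if (any(fas)) rt[fas] <- generate_rt(profile, rep(0, sum(fas)))
  trials$rt_ms <- rt

  spikes <- vector("list", n)
  names(spikes) <- as.character(trials$trial_id)
  for (i in seq_len(n)) {
    end_ms <- trials$trial_end_ms[i]
    nb <- as.integer(end_ms)
    att_in <- trials$attention[i] == "IN"
    mem <- profile$sample_memory_gain * (trials$sample[i] == profile$pref_identity)
    rate <- rep(profile$baseline_hz * (if (att_in) profile$attention_gain else 1) *
                  (1 + mem), nb)
    ev <- events[events$trial_id == trials$trial_id[i], , drop = FALSE]
    slope <- effective_color_slope(profile, trials$sample[i])
    dpref <- effective_direction_pref(profile, trials$sample[i])
    for (k in seq_len(nrow(ev))) {
      in_rf <- ev$location[k] == "IN"
      on <- ev$onset_ms[k]; off <- on + ev$duration_ms[k]
      add_step <- function(r, amp, lat) {
        if (amp == 0) return(r)
        t0 <- on + lat
        if (t0 >= off) return(r)
        if (profile$rise_ms > 0) {
          ramp_end <- min(t0 + profile$rise_ms, off)
          idx <- seq.int(floor(t0), ramp_end - 1)
          idx <- idx[idx >= 0 & idx < nb]
          r[idx + 1L] <- r[idx + 1L] + amp * (idx - t0 + 1) / profile$rise_ms
          t0 <- ramp_end
        }
        if (t0 < off) {
          idx <- seq.int(floor(t0), off - 1)
          idx <- idx[idx >= 0 & idx < nb]
          r[idx + 1L] <- r[idx + 1L] + amp
        }
        r
      }
      if (in_rf && ev$is_test[k]) {
        # identity term: responds to the preferred sample-identity conjunction
        if (ev$color[k] == pref$color && ev$direction[k] == pref$direction) {
          rate <- add_step(rate, profile$amp_identity_hz * (1 + profile$w) / 2,
                           profile$latency_identity_ms)
        }
        # feature terms: linear color ramp + circular direction tuning
        feat <- slope * (ev$color[k] - 4.5)
        if (profile$amp_direction_hz != 0) {
          dth <- (direction_angle(ev$direction[k]) - dpref) * pi / 180
          feat <- feat + profile$amp_direction_hz *
            exp(profile$direction_kappa * (cos(dth) - 1))
        }
        if (feat != 0) rate <- add_step(rate, feat, profile$latency_identity_ms)
      }
      # match term: targets in the RF, or anywhere for bilateral cells
      if (ev$is_test[k] && ev$match_class[k] == "target" &&
          (in_rf || profile$bilateral_match)) {
        rate <- add_step(rate, profile$amp_match_hz * (1 - profile$w) / 2,
                         profile$latency_match_ms + shared_jitter[i])
      }
    }
    rate[rate < 0] <- 0
    counts <- rpois(nb, rate * 1e-3)
    spikes[[i]] <- as.numeric(rep.int(seq_len(nb) - 1L, counts))
  }

  dcm_neuron(profile$neuron_id, profile$monkey_id, trialset$cfg$variant,
             trials, events, spikes)
}

#' Generate a synthetic population with its ground-truth report
#'
#' Each neuron gets its own independently generated session (trial schedule and
#' spikes), mirroring sequential single-electrode recordings. The report
#' records every profile field, realized per-condition trial counts and the
#' per-neuron seeds, so that the same config + seed regenerates the identical
#' dataset.
#'
#' @param cfg [task_config()].
#' @param profiles list of [neuron_profile()] (unique `neuron_id`s).
#' @param seed master RNG seed.
#' @return list with `dataset` ([dcm_population()]) and `report` (data.frame).
#' @export
generate_population <- function(cfg, profiles, seed = 1) {
  if (length(profiles) < 1) stop("need at least one profile")
  ids <- vapply(profiles, function(p) as.character(p$neuron_id), character(1))
  if (anyDuplicated(ids)) stop("duplicate neuron_ids in profiles")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, 2 * length(profiles))
  neurons <- vector("list", length(profiles))
  rows <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    ts <- generate_trials(cfg, sub_seeds[2 * i - 1])
    nr <- generate_neuron_spikes(profiles[[i]], ts, sub_seeds[2 * i])
    neurons[[i]] <- nr
    p <- profiles[[i]]
    scalars <- p[!vapply(p, is.null, logical(1))]
    rows[[i]] <- data.frame(
      scalars[vapply(scalars, function(x) is.atomic(x) && length(x) == 1, logical(1))],
      trial_seed = sub_seeds[2 * i - 1], spike_seed = sub_seeds[2 * i],
      n_trials = nrow(nr$trials),
      n_hit = sum(nr$trials$outcome == "hit"),
      n_catch = sum(nr$trials$is_catch),
      n_target_events = sum(nr$events$is_test & nr$events$match_class == "target"),
      session_mean_rt_ms = nr$session_mean_rt_ms
    )
  }
  report <- do.call(rbind, rows)
  list(dataset = dcm_population(neurons,
                                provenance = list(kind = "synthetic", cfg = cfg, seed = seed)),
       report = report)
}
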