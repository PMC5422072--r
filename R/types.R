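#' @importFrom stats rnorm rpois runif rbinom sd cor cor.test t.test aov anova
#'   pnorm qnorm complete.cases setNames aggregate lm coef dnorm predict
#' @importFrom utils head tail
NULL

# Sample identities: A = color 1 (yellow) moving down, B = color 8 (red) moving up.
# Direction indices 1..8 map to angles (i-1)*45 deg; 90 = up, 270 = down.
SAMPLE_DEFS <- list(
  A = list(color = 1L, direction = 7L),  # 270 deg, downward
  B = list(color = 8L, direction = 3L)   # 90 deg, upward
)

MATCH_CLASSES <- c("target", "opposite_target", "color_match", "direction_match", "other")

#' Angle of a direction index
#'
#' Directions are indexed 1-8 and evenly spaced over 360 degrees:
#' `angle = (index - 1) * 45`.
#'
#' @param direction_index integer vector in 1..8.
#' @return numeric vector of angles in degrees.
#' @export
direction_angle <- function(direction_index) {
  stopifnot(all(direction_index %in% 1:8))
  (direction_index - 1) * 45
}

#' Enumerate the stimulus universe
#'
#' All conjunctions of the 8 colors (1 = yellow ... 8 = red) and 8 motion
#' directions used as test/distractor stimuli.
#'
#' @return data.frame with columns `color`, `direction` (64 rows).
#' @export
stimulus_universe <- function() {
  expand.grid(color = 1:8, direction = 1:8, KEEP.OUT.ATTRS = FALSE)
}

#' Classify a stimulus against the trial's sample
#'
#' A test stimulus is a `target` when it equals the sample conjunction, an
#' `opposite_target` when it equals the other sample, a `color_match` when it
#' shares only the relevant color, a `direction_match` when it shares only the
#' relevant direction, and `other` otherwise.
#'
#' @param color,direction integer vectors (1..8).
#' @param sample "A" or "B" (recycled).
#' @return character vector of match classes.
#' @export
match_class <- function(color, direction, sample) {
  stopifnot(all(sample %in% c("A", "B")))
  n <- max(length(color), length(direction), length(sample))
  color <- rep_len(as.integer(color), n)
  direction <- rep_len(as.integer(direction), n)
  sample <- rep_len(sample, n)
  rel <- SAMPLE_DEFS[sample]
  rel_col <- vapply(rel, `[[`, integer(1), "color")
  rel_dir <- vapply(rel, `[[`, integer(1), "direction")
  opp <- ifelse(sample == "A", "B", "A")
  opp_col <- vapply(SAMPLE_DEFS[opp], `[[`, integer(1), "color")
  opp_dir <- vapply(SAMPLE_DEFS[opp], `[[`, integer(1), "direction")
  out <- rep("other", n)
  out[color == rel_col & direction == rel_dir] <- "target"
  out[color == opp_col & direction == opp_dir & out == "other"] <- "opposite_target"
  out[color == rel_col & out == "other"] <- "color_match"
  out[direction == rel_dir & out == "other"] <- "direction_match"
  out
}

new_neuron <- function(neuron_id, monkey_id, variant, trials, events, spikes,
                       session_mean_rt_ms = NULL) {
  obj <- structure(
    list(
      neuron_id = neuron_id,
      monkey_id = monkey_id,
      variant = variant,
      trials = as.data.frame(trials),
      events = as.data.frame(events),
      spikes = spikes,
      session_mean_rt_ms = session_mean_rt_ms
    ),
    class = "dcm_neuron"
  )
  if (is.null(session_mean_rt_ms)) {
    hits <- obj$trials$rt_ms[obj$trials$outcome == "hit"]
    obj$session_mean_rt_ms <- if (length(hits)) mean(hits) else NA_real_
  }
  obj
}

#' Construct a neuron recording
#'
#' Bundles per-trial task metadata, stimulus events and spike trains for one
#' neuron. `trials` must have columns `trial_id`, `sample` (A/B), `attention`
#' (IN/OUT), `is_catch`, `outcome` (hit/miss/false_alarm/correct_reject),
#' `rt_ms` (NA unless hit or false_alarm), `responded_position`,
#' `trial_end_ms`. `events` must have `trial_id`, `position`, `onset_ms`,
#' `duration_ms`, `location` (IN/OUT), `color`, `direction`, `match_class`,
#' `is_test`. `spikes` is a list of sorted spike-time vectors (ms from trial
#' start), one per trial, named by trial id.
#'
#' @param neuron_id,monkey_id identifiers.
#' @param variant "two_location" or "one_location".
#' @param trials,events data.frames as described.
#' @param spikes named list of numeric vectors.
#' @param session_mean_rt_ms mean hit RT for the session; computed from
#'   `trials` when NULL.
#' @param validate run [validate_neuron()]?
#' @return object of class `dcm_neuron`.
#' @export
dcm_neuron <- function(neuron_id, monkey_id = "sim", variant = "two_location",
                       trials, events, spikes, session_mean_rt_ms = NULL,
                       validate = TRUE) {
  obj <- new_neuron(neuron_id, monkey_id, variant, trials, events, spikes,
                    session_mean_rt_ms)
  if (validate) validate_neuron(obj)
  obj
}

#' Validate a neuron recording
#'
#' Checks the structural invariants of the data model: one spike train per
#' trial, sorted spike times within trial bounds, stimulus indices in 1..8,
#' match classes consistent with the trial's sample, catch trials without
#' targets, and RT present exactly on hit/false-alarm trials.
#'
#' @param neuron `dcm_neuron`.
#' @param strict when FALSE, only structural (not semantic) checks are run.
#' @return the neuron, invisibly; errors describe the first violation.
#' @export
validate_neuron <- function(neuron, strict = TRUE) {
  tr <- neuron$trials
  ev <- neuron$events
  req_tr <- c("trial_id", "sample", "attention", "is_catch", "outcome",
              "rt_ms", "trial_end_ms")
  miss <- setdiff(req_tr, names(tr))
  if (length(miss)) stop("trials table missing field(s): ", paste(miss, collapse = ", "))
  req_ev <- c("trial_id", "position", "onset_ms", "duration_ms", "location",
              "color", "direction", "match_class", "is_test")
  miss <- setdiff(req_ev, names(ev))
  if (length(miss)) stop("events table missing field(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tr$trial_id)) stop("duplicate trial_id in trials table")
  if (!all(as.character(tr$trial_id) %in% names(neuron$spikes)) ||
      length(neuron$spikes) != nrow(tr)) {
    stop("spikes must hold exactly one train per trial, named by trial_id")
  }
  if (!all(ev$trial_id %in% tr$trial_id)) stop("events reference unknown trial_id")
  if (!all(ev$color %in% 1:8) || !all(ev$direction %in% 1:8)) {
    stop("stimulus color/direction indices must lie in 1..8")
  }
  end_of <- setNames(tr$trial_end_ms, as.character(tr$trial_id))
  for (id in as.character(tr$trial_id)) {
    s <- neuron$spikes[[id]]
    if (is.unsorted(s)) stop("unsorted spike train in trial ", id)
    if (length(s) && (s[1] < 0 || s[length(s)] >= end_of[[id]])) {
      stop("spike time outside trial bounds in trial ", id)
    }
  }
  if (strict) {
    if (!all(tr$sample %in% c("A", "B"))) stop("sample must be A or B")
    if (!all(tr$attention %in% c("IN", "OUT"))) stop("attention must be IN or OUT")
    if (!all(ev$match_class %in% MATCH_CLASSES)) stop("unknown match_class value")
    samp_of <- setNames(tr$sample, as.character(tr$trial_id))
    expect_mc <- match_class(ev$color, ev$direction, samp_of[as.character(ev$trial_id)])
    if (!all(ev$match_class == expect_mc)) {
      stop("match_class inconsistent with sample identity for ",
           sum(ev$match_class != expect_mc), " event(s)")
    }
    catch_ids <- tr$trial_id[tr$is_catch]
    if (any(ev$is_test & ev$match_class == "target" & ev$trial_id %in% catch_ids)) {
      stop("catch trial contains a target test event")
    }
    has_rt <- !is.na(tr$rt_ms)
    should <- tr$outcome %in% c("hit", "false_alarm")
    if (!all(has_rt == should)) stop("rt_ms must be present iff outcome is hit or false_alarm")
    mx <- if (neuron$variant == "two_location") 4L else 3L
    if (any(ev$position > mx)) stop("position_in_sequence exceeds task maximum")
    if (neuron$variant == "one_location" && any(!ev$is_test)) {
      stop("distractor events are only defined for the two_location variant")
    }
  }
  invisible(neuron)
}

#' @export
print.dcm_neuron <- function(x, ...) {
  cat(sprintf("<dcm_neuron %s> monkey %s, %s task: %d trials, %d events, %d spikes\n",
              x$neuron_id, x$monkey_id, x$variant, nrow(x$trials), nrow(x$events),
              sum(lengths(x$spikes))))
  invisible(x)
}

#' Construct a population dataset
#'
#' @param neurons list of [dcm_neuron()] objects with unique ids.
#' @param provenance free-form list (e.g. generator config + seed, or source path).
#' @return object of class `dcm_population`.
#' @export
dcm_population <- function(neurons, provenance = list()) {
  ids <- vapply(neurons, function(n) as.character(n$neuron_id), character(1))
  if (anyDuplicated(ids)) stop("duplicate neuron_ids in population")
  structure(list(neurons = neurons, provenance = provenance),
            class = "dcm_population")
}

#' @export
print.dcm_population <- function(x, ...) {
  cat(sprintf("<dcm_population> %d neurons\n", length(x$neurons)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flat event table for one neuron
#'
#' Joins the events table with per-trial metadata (sample, attention, outcome,
#' rt, trial end), the standard starting point for windowed analyses.
#'
#' @param neuron `dcm_neuron`.
#' @param tests_only drop distractor events?
#' @param correct_only keep only hit and correct-reject trials (the analyses
#'   operate on correct trials)?
#' @return data.frame, one row per event.
#' @export
event_table <- function(neuron, tests_only = TRUE, correct_only = TRUE) {
  ev <- neuron$events
  tr <- neuron$trials
  idx <- match(ev$trial_id, tr$trial_id)
  ev$sample <- tr$sample[idx]
  ev$attention <- tr$attention[idx]
  ev$outcome <- tr$outcome[idx]
  ev$rt_ms <- tr$rt_ms[idx]
  ev$is_catch <- tr$is_catch[idx]
  ev$trial_end_ms <- tr$trial_end_ms[idx]
  ev$responded_position <- tr$responded_position[idx]
  if (tests_only) ev <- ev[ev$is_test, , drop = FALSE]
  if (correct_only) ev <- ev[ev$outcome %in% c("hit", "correct_reject"), , drop = FALSE]
  ev
}
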