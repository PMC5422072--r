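#' Pre-test firing-rate ratio between two trial conditions
#'
#' Computes mean firing rates in the 200-ms window preceding each test
#' stimulus (`[-200, 0)` ms from onset), separately for the two levels of the
#' grouping variable, on correct (hit and correct-reject) trials only. The
#' ratio is `higher / lower` and identifies which condition must be decimated
#' to equate pre-stimulus activity. For `grouping = "attention"` the windows
#' preceding the first stimulus in the sequence are excluded, so that the
#' ratio reflects visually driven rather than delay-period activity.
#'
#' @param neuron `dcm_neuron`.
#' @param grouping "sample" (A vs B trials) or "attention" (IN vs OUT trials).
#' @param window_ms pre-test window length (default 200).
#' @return list of class `dcm_decimation_plan`: `grouping`, `ratio`,
#'   `target_condition` (the higher-rate level), `removal_fraction`
#'   `= 1 - lower/higher`, per-condition `rates`, and `decimate` (FALSE when
#'   one condition is silent, flagged rather than decimated).
#' @export
pretest_ratio <- function(neuron, grouping = c("sample", "attention"),
                          window_ms = 200) {
  grouping <- match.arg(grouping)
  ev <- event_table(neuron, tests_only = TRUE, correct_only = TRUE)
  if (grouping == "attention") {
    if (neuron$variant != "two_location") {
      stop("attention equalization requires two_location data (no attention OUT otherwise)")
    }
    ev <- ev[ev$position >= 2, , drop = FALSE]
  }
  cond <- if (grouping == "sample") ev$sample else ev$attention
  levels_needed <- if (grouping == "sample") c("A", "B") else c("IN", "OUT")
  if (!all(levels_needed %in% cond)) {
    stop("need at least one qualifying pre-test window per ", grouping, " condition")
  }
  rates <- vapply(levels_needed, function(lv) {
    cnt <- aligned_counts(neuron, ev[cond == lv, , drop = FALSE],
                          c(-window_ms, 0))
    mean(cnt) / window_ms * 1000
  }, numeric(1))
  if (all(rates == 0)) stop("zero pre-test rate in both conditions: nothing to equate")
  if (any(rates == 0)) {
    return(structure(list(grouping = grouping, ratio = Inf,
                          target_condition = names(rates)[which.max(rates)],
                          removal_fraction = NA_real_, rates = rates,
                          decimate = FALSE),
                     class = "dcm_decimation_plan"))
  }
  hi <- which.max(rates)
  ratio <- max(rates) / min(rates)
  structure(list(grouping = grouping, ratio = ratio,
                 target_condition = names(rates)[hi],
                 removal_fraction = 1 - min(rates) / max(rates),
                 rates = rates, decimate = TRUE),
            class = "dcm_decimation_plan")
}

#' Randomly decimate test-period spikes of the higher-rate condition
#'
#' Removes spikes from the target condition's trials so that pre-test firing
#' rates are equated in expectation. Only spikes emitted during the test
#' period (from the onset of the first test stimulus to the end of the trial)
#' are candidates for removal; spikes in the sample and delay epochs, and all
#' spikes of the non-target condition, are untouched. The default removes each
#' candidate spike independently with probability `removal_fraction`
#' (Bernoulli thinning, which preserves Poisson statistics); the `"exact"`
#' method removes `round(fraction * N)` uniformly chosen spikes instead.
#'
#' @param neuron `dcm_neuron`.
#' @param plan [pretest_ratio()] result.
#' @param seed RNG seed.
#' @param method "bernoulli" (default) or "exact".
#' @return decimated `dcm_neuron`; the plan is attached as attribute
#'   `decimation_plan` for audit.
#' @export
decimate_spikes <- function(neuron, plan, seed = 1,
                            method = c("bernoulli", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(plan, "dcm_decimation_plan"))
  if (!isTRUE(plan$decimate) || plan$removal_fraction == 0) {
    attr(neuron, "decimation_plan") <- plan
    return(neuron)
  }
  f <- plan$removal_fraction
  if (is.na(f) || f >= 1) stop("removal_fraction must lie in [0, 1)")
  set.seed(seed)
  tr <- neuron$trials
  cond <- if (plan$grouping == "sample") tr$sample else tr$attention
  target_trials <- tr$trial_id[cond == plan$target_condition]
  ev <- neuron$events
  for (tid in target_trials) {
    tev <- ev[ev$trial_id == tid & ev$is_test, , drop = FALSE]
    if (!nrow(tev)) next
    test_start <- min(tev$onset_ms)
    s <- neuron$spikes[[as.character(tid)]]
    in_test <- s >= test_start
    idx <- which(in_test)
    if (!length(idx)) next
    if (method == "bernoulli") {
      keep <- runif(length(idx)) >= f
    } else {
      n_remove <- round(f * length(idx))
      keep <- rep(TRUE, length(idx))
      if (n_remove > 0) keep[sample.int(length(idx), n_remove)] <- FALSE
    }
    neuron$spikes[[as.character(tid)]] <- s[c(which(!in_test), idx[keep])]
  }
  attr(neuron, "decimation_plan") <- plan
  neuron
}

#' Equate sample-A and sample-B trial activity by decimation
#'
#' Composition of [pretest_ratio()] (grouping by sample identity) and
#' [decimate_spikes()]. Removes the spurious pre-onset "identity selectivity"
#' that sample-memory activity would otherwise imprint on the sliding ROC.
#'
#' @param neuron `dcm_neuron`.
#' @param seed RNG seed.
#' @param method see [decimate_spikes()].
#' @return decimated `dcm_neuron`.
#' @export
equalize_by_sample <- function(neuron, seed = 1, method = "bernoulli") {
  decimate_spikes(neuron, pretest_ratio(neuron, "sample"), seed, method)
}

#' Equate attention-IN and attention-OUT activity by decimation
#'
#' As [equalize_by_sample()] but grouping by attention condition, with
#' first-sequence-position pre-test windows excluded from the ratio (their
#' pre-stimulus window is the delay epoch). Two-location data only.
#'
#' @inheritParams equalize_by_sample
#' @return decimated `dcm_neuron`.
#' @export
equalize_by_attention <- function(neuron, seed = 1, method = "bernoulli") {
  decimate_spikes(neuron, pretest_ratio(neuron, "attention"), seed, method)
}
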