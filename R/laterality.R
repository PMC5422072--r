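# Exact tail fraction of positive pairwise differences a_i - b_j without
# materializing the full outer product: ties count as not positive.
tail_fraction_positive <- function(a, b) {
  sum(findInterval(a, sort(b), left.open = TRUE)) / (length(a) * length(b))
}

# Bootstrap distribution of the ROC (target vs opposite-target): resample
# trials within each condition with replacement before every AUC.
bootstrap_roc <- function(x_target, x_opp, n_boot) {
  n1 <- length(x_target); n2 <- length(x_opp)
  vapply(seq_len(n_boot), function(b) {
    roc_auc(x_target[sample.int(n1, n1, replace = TRUE)],
            x_opp[sample.int(n2, n2, replace = TRUE)])
  }, numeric(1))
}

#' Laterality of match selectivity: IN vs OUT receptive field
#'
#' Computes sliding match-selectivity (ROC, target vs opposite-target)
#' separately for test stimuli inside and outside the neuron's receptive
#' field, and their difference, the laterality index. Values near 0 indicate
#' location-independent (bilateral) match signals. Run the neuron through
#' [equalize_by_attention()] first so that space-based attention gain does not
#' inflate the IN response.
#'
#' @param neuron two-location `dcm_neuron` (post attention equalization).
#' @param ... passed to [sliding_selectivity()] (window, step, alpha).
#' @return list of class `dcm_laterality_trace`: `times_ms`, `roc_in`,
#'   `roc_out`, `laterality_index`, and the two component traces.
#' @export
laterality_trace <- function(neuron, ...) {
  if (neuron$variant != "two_location") {
    stop("laterality analysis requires two_location data")
  }
  tin <- sliding_selectivity(neuron, "match_in", ...)
  tout <- sliding_selectivity(neuron, "match_out", ...)
  stopifnot(identical(tin$times_ms, tout$times_ms))
  structure(list(times_ms = tin$times_ms, roc_in = tin$roc, roc_out = tout$roc,
                 laterality_index = tin$roc - tout$roc,
                 trace_in = tin, trace_out = tout),
            class = "dcm_laterality_trace")
}

#' Permutation test for bilateral vs unilateral match selectivity
#'
#' For the aggregation window (and optionally every sliding window),
#' bootstraps `n_boot` match-ROC values for IN and for OUT target locations
#' and evaluates all `n_boot^2` pairwise differences via an exact
#' tail-fraction computation. IN selectivity exceeds OUT when strictly more
#' than 95% of the IN-minus-OUT differences are positive (ties count as not
#' positive); the symmetric rule detects OUT > IN. A match-selective neuron
#' with no significant difference in the aggregation window is classified
#' bilateral.
#'
#' @param neuron two-location `dcm_neuron` (post attention equalization).
#' @param n_boot bootstrap samples per side (default 1000).
#' @param seed RNG seed.
#' @param window aggregation window ms (default `c(100, 350)`).
#' @param match_selective is the neuron match-selective (from the selectivity
#'   module)? Non-selective neurons are classified "non_selective".
#' @param crit strict exceedance threshold (default 0.95).
#' @param times_ms optional window centers for a per-time significance mask
#'   (NULL skips it).
#' @param window_ms sliding window length for the per-time mask.
#' @param min_events minimum events per cell of target/opposite x IN/OUT.
#' @return list of class `dcm_laterality_test`: `classification` one of
#'   "bilateral", "unilateral_in", "unilateral_out", "non_selective";
#'   `frac_in_gt_out` for the aggregation window; optional per-time
#'   `significant_in`, `significant_out` masks.
#' @export
permutation_laterality_test <- function(neuron, n_boot = 1000, seed = 1,
                                        window = c(100, 350),
                                        match_selective = TRUE,
                                        crit = 0.95,
                                        times_ms = NULL, window_ms = 200,
                                        min_events = 5) {
  if (neuron$variant != "two_location") {
    stop("laterality analysis requires two_location data")
  }
  set.seed(seed)
  ev <- event_table(neuron, tests_only = TRUE, correct_only = TRUE)
  ev <- ev[ev$match_class %in% c("target", "opposite_target"), , drop = FALSE]
  cells <- list(
    target_in = ev[ev$match_class == "target" & ev$location == "IN", ],
    opp_in = ev[ev$match_class == "opposite_target" & ev$location == "IN", ],
    target_out = ev[ev$match_class == "target" & ev$location == "OUT", ],
    opp_out = ev[ev$match_class == "opposite_target" & ev$location == "OUT", ])
  sizes <- vapply(cells, nrow, integer(1))
  if (any(sizes < min_events)) {
    stop("empty or underpopulated cell(s): ",
         paste(names(sizes)[sizes < min_events], collapse = ", "))
  }
  counts <- lapply(cells, function(e) aligned_counts(neuron, e, window, check = FALSE))
  roc_in_b <- bootstrap_roc(counts$target_in, counts$opp_in, n_boot)
  roc_out_b <- bootstrap_roc(counts$target_out, counts$opp_out, n_boot)
  frac_pos <- tail_fraction_positive(roc_in_b, roc_out_b)
  frac_neg <- tail_fraction_positive(roc_out_b, roc_in_b)
  classification <- if (!isTRUE(match_selective)) {
    "non_selective"
  } else if (frac_pos > crit) {
    "unilateral_in"
  } else if (frac_neg > crit) {
    "unilateral_out"
  } else {
    "bilateral"
  }
  out <- list(classification = classification, frac_in_gt_out = frac_pos,
              frac_out_gt_in = frac_neg, window = window, n_boot = n_boot)
  if (!is.null(times_ms)) {
    half <- window_ms / 2
    cm <- lapply(cells, function(e) aligned_count_matrix(neuron, e, times_ms, half))
    sig_in <- logical(length(times_ms)); sig_out <- logical(length(times_ms))
    for (j in seq_along(times_ms)) {
      rin <- bootstrap_roc(cm$target_in[, j], cm$opp_in[, j], n_boot)
      rout <- bootstrap_roc(cm$target_out[, j], cm$opp_out[, j], n_boot)
      fp <- tail_fraction_positive(rin, rout)
      fn <- tail_fraction_positive(rout, rin)
      sig_in[j] <- fp > crit
      sig_out[j] <- fn > crit
    }
    out$times_ms <- times_ms
    out$significant_in <- sig_in
    out$significant_out <- sig_out
  }
  structure(out, class = "dcm_laterality_test")
}
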