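#' Area under the ROC curve for two spike-count samples
#'
#' Probability that a random draw from `counts_pref` exceeds a random draw
#' from `counts_nonpref`, ties counted 1/2 — the Mann-Whitney U statistic
#' divided by `n1 * n2`.
#'
#' @param counts_pref,counts_nonpref numeric vectors (both nonempty).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(counts_pref, counts_nonpref) {
  n1 <- length(counts_pref); n2 <- length(counts_nonpref)
  if (n1 == 0 || n2 == 0) stop("roc_auc requires nonempty groups")
  r <- rank(c(counts_pref, counts_nonpref))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Column-wise Mann-Whitney (Wilcoxon rank-sum) over a count matrix:
# rows = events, columns = time windows. Returns AUC (group1 vs group2) and
# two-sided normal-approximation p with tie correction and continuity
# correction, matching stats::wilcox.test(exact = FALSE, correct = TRUE).
ranksum_cols <- function(m, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  nc <- ncol(m)
  auc <- numeric(nc); p <- numeric(nc)
  sub <- m[c(idx1, idx2), , drop = FALSE]
  for (j in seq_len(nc)) {
    x <- sub[, j]
    r <- rank(x)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    auc[j] <- U / (n1 * n2)
    nt <- table(x)
    tie_term <- sum(nt^3 - nt)
    n <- n1 + n2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) { p[j] <- 1; next }
    z <- U - n1 * n2 / 2
    corr <- sign(z) * 0.5
    z <- (z - corr) / sqrt(sigma2)
    p[j] <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
  }
  list(auc = auc, p = p)
}

# Event pools for the four comparison kinds. Identity compares stimulus A vs
# stimulus B test events (targets and opposite-targets pooled); match compares
# target vs opposite-target events. The *_in / *_out variants restrict to
# events inside / outside the receptive field.
comparison_groups <- function(neuron, comparison) {
  ev <- event_table(neuron, tests_only = TRUE, correct_only = TRUE)
  ev <- ev[ev$match_class %in% c("target", "opposite_target"), , drop = FALSE]
  if (comparison %in% c("identity", "match")) ev <- ev[ev$location == "IN", , drop = FALSE]
  if (comparison == "match_in") ev <- ev[ev$location == "IN", , drop = FALSE]
  if (comparison == "match_out") ev <- ev[ev$location == "OUT", , drop = FALSE]
  if (comparison == "identity") {
    is_a <- ev$color == SAMPLE_DEFS$A$color & ev$direction == SAMPLE_DEFS$A$direction
    list(events = ev, g1 = which(is_a), g2 = which(!is_a),
         labels = c("stimulus_A", "stimulus_B"))
  } else {
    is_t <- ev$match_class == "target"
    list(events = ev, g1 = which(is_t), g2 = which(!is_t),
         labels = c("target", "opposite_target"))
  }
}

#' Sliding ROC selectivity trace
#'
#' Slides a 200-ms window in `step_ms` steps across the peri-stimulus epoch;
#' at each window center `t` it computes the ROC value and a two-sided
#' Wilcoxon rank-sum p-value over per-event spike counts in
#' `[t - 100, t + 100)` ms from test onset. Significance is Bonferroni
#' corrected over the number of window centers in the trace (familywise
#' `alpha`). For the identity comparison the ROC is oriented
#' preferred-vs-nonpreferred (preference fixed from mean rates in the
#' 100-350 ms window); match comparisons are oriented target vs
#' opposite-target.
#'
#' Run the neuron through [equalize_by_sample()] first so that sample-memory
#' activity does not masquerade as pre-onset identity selectivity.
#'
#' @param neuron `dcm_neuron` (typically post-equalization).
#' @param comparison one of "identity", "match", "match_in", "match_out".
#' @param window_ms sliding window length (default 200).
#' @param step_ms window-center step (default 1).
#' @param alpha familywise significance level (default 0.01).
#' @param t_range window-center range in ms from test onset; default
#'   `c(-100, epoch)` where epoch is the test-stimulus duration.
#' @param min_events minimum events per side (default 5).
#' @return data.frame of class `dcm_selectivity_trace` with columns
#'   `times_ms`, `roc`, `p`, `significant`; attributes `comparison`,
#'   `alpha`, `n_windows`, `pref`, `session_mean_rt_ms`.
#' @export
sliding_selectivity <- function(neuron,
                                comparison = c("identity", "match",
                                               "match_in", "match_out"),
                                window_ms = 200, step_ms = 1, alpha = 0.01,
                                t_range = NULL, min_events = 5) {
  comparison <- match.arg(comparison)
  grp <- comparison_groups(neuron, comparison)
  if (length(grp$g1) < min_events || length(grp$g2) < min_events) {
    stop("insufficient events for comparison '", comparison, "': ",
         length(grp$g1), " vs ", length(grp$g2), " (need >= ", min_events, ")")
  }
  ev <- grp$events
  epoch <- max(ev$duration_ms)
  if (is.null(t_range)) t_range <- c(-100, epoch)
  centers <- seq(t_range[1], t_range[2], by = step_ms)
  half <- window_ms / 2
  m <- aligned_count_matrix(neuron, ev, centers, half)

  g1 <- grp$g1; g2 <- grp$g2
  if (comparison == "identity") {
    # preferred side = higher mean response in the 100-350 ms window
    resp <- aligned_counts(neuron, ev, c(100, 350), check = FALSE)
    if (mean(resp[g2]) > mean(resp[g1])) { tmp <- g1; g1 <- g2; g2 <- tmp }
  }
  rs <- ranksum_cols(m, g1, g2)
  n_windows <- length(centers)
  out <- data.frame(times_ms = centers, roc = rs$auc, p = rs$p,
                    significant = rs$p < alpha / n_windows)
  structure(out, class = c("dcm_selectivity_trace", "data.frame"),
            comparison = comparison, alpha = alpha, n_windows = n_windows,
            pref = grp$labels[if (identical(g1, grp$g1)) 1 else 2],
            step_ms = step_ms,
            session_mean_rt_ms = neuron$session_mean_rt_ms)
}

#' Selectivity onset latency from a sliding trace
#'
#' The latency is the earliest time in `[0, session_mean_rt_ms]` that begins a
#' run of at least `run_ms` consecutive significant milliseconds (the run may
#' extend beyond the mean RT; only its start is bounded). `NA` when no such
#' run exists — absence of a measurable latency is a valid outcome.
#'
#' @param trace [sliding_selectivity()] output.
#' @param session_mean_rt_ms search upper bound; defaults to the value stored
#'   on the trace.
#' @param run_ms required run length (default 100).
#' @return latency in ms, or `NA_real_`.
#' @export
detect_latency <- function(trace, session_mean_rt_ms = NULL, run_ms = 100) {
  rt <- session_mean_rt_ms %||% attr(trace, "session_mean_rt_ms")
  if (is.null(rt) || is.na(rt)) stop("session_mean_rt_ms required to bound the latency search")
  step <- attr(trace, "step_ms") %||% diff(trace$times_ms[1:2])
  need <- ceiling(run_ms / step)
  sig <- trace$significant
  n <- length(sig)
  if (n < need) return(NA_real_)
  cs <- cumsum(sig)
  runsum <- cs[need:n] - c(0, cs)[1:(n - need + 1)]
  starts <- which(runsum == need)            # index of run start
  if (!length(starts)) return(NA_real_)
  t0 <- trace$times_ms[starts]
  ok <- t0 >= 0 & t0 <= rt
  if (!any(ok)) return(NA_real_)
  min(t0[ok])
}

#' Visuo-decision index from identity and match traces
#'
#' Selectivity strength for each signal is the mean over the window of
#' `2 * |ROC(t) - 0.5|` (0 at chance, 1 at perfect discrimination); the VDI is
#' identity strength minus match strength, so +1 marks purely
#' identity-selective and -1 purely match-selective neurons.
#'
#' @param identity_trace,match_trace [sliding_selectivity()] outputs covering
#'   the window.
#' @param window averaging window in ms (default `c(100, 350)`).
#' @return list of class `dcm_vdi`: `vdi`, `identity_strength`,
#'   `match_strength`, `window`.
#' @export
compute_vdi <- function(identity_trace, match_trace, window = c(100, 350)) {
  strength <- function(trace) {
    keep <- trace$times_ms >= window[1] & trace$times_ms <= window[2]
    if (!any(keep) || min(trace$times_ms) > window[1] ||
        max(trace$times_ms) < window[2]) {
      stop("trace does not cover the ", window[1], "-", window[2], " ms window")
    }
    mean(2 * abs(trace$roc[keep] - 0.5))
  }
  is_ <- strength(identity_trace); ms_ <- strength(match_trace)
  structure(list(vdi = is_ - ms_, identity_strength = is_, match_strength = ms_,
                 window = window),
            class = "dcm_vdi")
}

#' Population statistics on selectivity latencies
#'
#' Unpaired t-test comparing identity vs match latencies across neurons, and a
#' paired t-test restricted to neurons with both latencies (dual-selective
#' cells), which controls for between-neuron rate differences.
#'
#' @param profiles data.frame with columns `latency_identity` and
#'   `latency_match` (NA = not selective).
#' @return list with per-signal `n`, `mean`, `sd`, the `unpaired` and `paired`
#'   htest results (paired is a `no_difference` flag when all paired
#'   differences are zero).
#' @export
population_latency_stats <- function(profiles) {
  li <- profiles$latency_identity[!is.na(profiles$latency_identity)]
  lm_ <- profiles$latency_match[!is.na(profiles$latency_match)]
  if (length(li) < 2 || length(lm_) < 2) {
    stop("need at least 2 latencies per signal (got ", length(li), " identity, ",
         length(lm_), " match)")
  }
  unpaired <- t.test(li, lm_)
  both <- !is.na(profiles$latency_identity) & !is.na(profiles$latency_match)
  paired <- NULL
  no_difference <- FALSE
  if (sum(both) >= 2) {
    d <- profiles$latency_identity[both] - profiles$latency_match[both]
    if (all(d == 0) || sd(d) == 0) {
      no_difference <- all(d == 0)
    } else {
      paired <- t.test(profiles$latency_identity[both],
                       profiles$latency_match[both], paired = TRUE)
    }
  }
  list(n = c(identity = length(li), match = length(lm_), dual = sum(both)),
       mean = c(identity = mean(li), match = mean(lm_)),
       sd = c(identity = sd(li), match = sd(lm_)),
       unpaired = unpaired, paired = paired, no_difference = no_difference)
}
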