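#' Behavioral outcome summary
#'
#' Fractions of correct (hits + correct rejections), miss, and false-alarm
#' trials per attention condition. Fixation breaks are not modeled; the
#' fractions sum to 1.
#'
#' @param trials trials data.frame (e.g. `neuron$trials` or
#'   `trialset$trials`).
#' @return data.frame with one row per attention condition plus a pooled row.
#' @export
behavior_summary <- function(trials) {
  if (nrow(trials) == 0) stop("no completed trials")
  one <- function(tr, label) {
    n <- nrow(tr)
    data.frame(attention = label, n = n,
               frac_correct = sum(tr$outcome %in% c("hit", "correct_reject")) / n,
               frac_miss = sum(tr$outcome == "miss") / n,
               frac_false_alarm = sum(tr$outcome == "false_alarm") / n)
  }
  out <- do.call(rbind, lapply(sort(unique(trials$attention)), function(a) {
    one(trials[trials$attention == a, , drop = FALSE], a)
  }))
  rbind(out, one(trials, "all"))
}

#' False-alarm fraction per stimulus
#'
#' For each of the 64 conjunctions, the fraction of its presentations that
#' triggered a false-alarm response, computed separately for every
#' location x attention combination. Rows index direction, columns color.
#'
#' @param trialset [generate_trials()] output, or any list with `trials` and
#'   `events` (a `dcm_neuron` works).
#' @return named list of 8x8 matrices, keys `"<location>_<attention>"`.
#' @export
false_alarm_map <- function(trialset) {
  tr <- trialset$trials
  ev <- trialset$events
  idx <- match(ev$trial_id, tr$trial_id)
  ev$attention <- tr$attention[idx]
  fa <- tr[tr$outcome == "false_alarm", , drop = FALSE]
  out <- list()
  for (loc in sort(unique(ev$location))) {
    for (att in sort(unique(ev$attention))) {
      sub <- ev[ev$location == loc & ev$attention == att, , drop = FALSE]
      pres <- matrix(0, 8, 8, dimnames = list(direction = 1:8, color = 1:8))
      hits <- pres
      if (nrow(sub)) {
        tab <- table(factor(sub$direction, 1:8), factor(sub$color, 1:8))
        pres <- pres + as.matrix(tab)
      }
      # responded events: the test stimulus on screen at the erroneous response
      resp <- merge(fa[, c("trial_id", "responded_position")],
                    sub[sub$is_test, , drop = FALSE],
                    by.x = c("trial_id", "responded_position"),
                    by.y = c("trial_id", "position"))
      if (nrow(resp)) {
        tab <- table(factor(resp$direction, 1:8), factor(resp$color, 1:8))
        hits <- hits + as.matrix(tab)
      }
      frac <- hits / pres
      frac[pres == 0] <- 0
      out[[paste(loc, att, sep = "_")]] <- frac
    }
  }
  out
}

#' Target sequence-position control
#'
#' Counts target presentations per sequence position in each session and runs
#' a one-way ANOVA of counts across positions. Detection-rate artifacts in
#' the choice-probability analysis arise when the target is over-presented at
#' particular positions (notably position 1), which this test diagnoses.
#'
#' @param sessions list of trial tables (or of objects with a `$trials`
#'   element), one per session.
#' @return list with `counts` (session x position data.frame), `F`, `p`.
#' @export
target_position_anova <- function(sessions) {
  if (length(sessions) < 2) stop("need >= 2 sessions")
  tabs <- lapply(seq_along(sessions), function(i) {
    tr <- sessions[[i]]
    if (!is.data.frame(tr)) tr <- tr$trials
    # targets actually presented: hit and miss trials carry the target
    tr <- tr[!tr$is_catch & tr$outcome %in% c("hit", "miss"), , drop = FALSE]
    pos <- tr$target_position
    data.frame(session = i, position = seq_len(max(1, max(pos, 1))),
               count = tabulate(pos, nbins = max(pos, 1)))
  })
  counts <- do.call(rbind, tabs)
  if (length(unique(counts$position)) < 2) stop("only one sequence position present")
  if (var(counts$count) == 0) {
    return(list(counts = counts, F = 0, p = 1))
  }
  fit <- aov(count ~ factor(position), data = counts)
  an <- anova(fit)
  Fv <- an[["F value"]][1]
  if (is.nan(Fv)) Fv <- 0   # zero between- and within-group variance
  list(counts = counts, F = Fv,
       p = if (Fv == 0 && is.nan(an[["Pr(>F)"]][1])) 1 else an[["Pr(>F)"]][1])
}

#' Choice probability: trial-by-trial rate vs reaction time
#'
#' Pairs each qualifying trial's smoothed firing rate (1-ms bins, Gaussian
#' sigma 15 ms, z-scored per time point across trials) with that trial's RT
#' and reports the Pearson correlation at every millisecond after target
#' onset. Qualifying trials are hits with the target at sequence position 2
#' or later (position-1 targets are over-presented and removed) during trials
#' whose sample is the neuron's preferred stimulus.
#'
#' Since the Pearson correlation is invariant to per-time-point affine
#' transforms, z-scoring across trials changes no r value; it is the
#' convention under which the trace is interpreted (PSTH shape removed).
#'
#' @param neuron `dcm_neuron`.
#' @param t_range correlation epoch in ms from target onset (default
#'   `c(0, 450)`).
#' @param sigma_ms smoothing kernel sd (default 15).
#' @param summary_window window for the scalar summary r (default
#'   `c(100, 350)`).
#' @param pref_sample "A"/"B"; inferred from identity responses when NULL.
#' @param min_trials minimum qualifying trials (default 10).
#' @return list of class `dcm_cp_trace`: `times_ms`, `r`, `n_trials`,
#'   `summary_r`, `degenerate` (mask of zero-variance time points, r set 0).
#' @export
choice_probability <- function(neuron, t_range = c(0, 450), sigma_ms = 15,
                               summary_window = c(100, 350),
                               pref_sample = NULL, min_trials = 10) {
  if (is.null(pref_sample)) pref_sample <- preferred_identity(neuron)
  ev <- event_table(neuron, tests_only = TRUE, correct_only = TRUE)
  tgt <- ev[ev$match_class == "target" & ev$outcome == "hit" &
              ev$position >= 2 & ev$sample == pref_sample, , drop = FALSE]
  if (nrow(tgt) < min_trials) {
    stop("only ", nrow(tgt), " qualifying trials (hits, position >= 2, sample ",
         pref_sample, "); need >= ", min_trials)
  }
  raster <- binned_raster(neuron, tgt, t_range)
  sm <- t(apply(raster, 1, smooth_trace, sigma_ms = sigma_ms)) * 1000
  rt <- tgt$rt_ms
  nt <- ncol(sm)
  r <- numeric(nt); degenerate <- logical(nt)
  for (j in seq_len(nt)) {
    if (sd(sm[, j]) == 0 || sd(rt) == 0) {
      r[j] <- 0; degenerate[j] <- TRUE
    } else {
      r[j] <- cor(sm[, j], rt)
    }
  }
  times <- seq(t_range[1], t_range[2] - 1)
  keep <- times >= summary_window[1] & times <= summary_window[2]
  structure(list(times_ms = times, r = r, n_trials = nrow(tgt),
                 summary_r = mean(r[keep]), degenerate = degenerate,
                 pref_sample = pref_sample),
            class = "dcm_cp_trace")
}

# Preferred stimulus identity from mean responses to stimulus-A vs stimulus-B
# test events in the RF, 100-350 ms window.
preferred_identity <- function(neuron, window = c(100, 350)) {
  ev <- event_table(neuron, tests_only = TRUE, correct_only = TRUE)
  ev <- ev[ev$location == "IN" &
             ev$match_class %in% c("target", "opposite_target"), , drop = FALSE]
  is_a <- ev$color == SAMPLE_DEFS$A$color & ev$direction == SAMPLE_DEFS$A$direction
  if (!any(is_a) || all(is_a)) return("A")
  cnt <- aligned_counts(neuron, ev, window, check = FALSE)
  if (mean(cnt[is_a]) >= mean(cnt[!is_a])) "A" else "B"
}

#' Correlation between choice probability and VDI across neurons
#'
#' @param profiles data.frame with columns `cp_r` and `vdi` (see
#'   [neuron_profiles()]); optionally `laterality_class` for the
#'   bilateral-removed rerun.
#' @param exclude_bilateral drop neurons classified bilaterally
#'   match-selective before correlating?
#' @return [correlate_profiles()] result.
#' @export
cp_vdi_correlation <- function(profiles, exclude_bilateral = FALSE) {
  if (exclude_bilateral && "laterality_class" %in% names(profiles)) {
    profiles <- profiles[is.na(profiles$laterality_class) |
                           profiles$laterality_class != "bilateral", , drop = FALSE]
  }
  correlate_profiles(profiles, "cp_r", "vdi")
}
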