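#' Condition-mean responses for the additivity decomposition
#'
#' Mean responses to the four stimulus classes defined relative to the
#' current sample: target (T, relevant color and direction), color-match
#' (CM, relevant color with any of the 7 irrelevant directions),
#' direction-match (DM, relevant direction with any of the 7 irrelevant
#' colors) and opposite-target (OT, the other sample's conjunction), over
#' test stimuli inside the receptive field on correct trials. By default each
#' mean is normalized by the neuron's mean rate over all test-stimulus
#' windows; the additivity index is invariant to this choice.
#'
#' @param neuron `dcm_neuron`.
#' @param window response window ms from onset (default `c(100, 350)`).
#' @param normalize divide by the all-stimulus mean rate?
#' @param min_events minimum events per class (default 3).
#' @return list of class `dcm_condition_responses`: `T`, `CM`, `DM`, `OT`,
#'   per-class event counts `n`, `window`.
#' @export
condition_responses <- function(neuron, window = c(100, 350), normalize = TRUE,
                                min_events = 3) {
  ev <- event_table(neuron, tests_only = TRUE, correct_only = TRUE)
  ev <- ev[ev$location == "IN", , drop = FALSE]
  classes <- c(T = "target", CM = "color_match", DM = "direction_match",
               OT = "opposite_target")
  counts_all <- aligned_counts(neuron, ev, window, check = FALSE)
  means <- numeric(length(classes)); n <- integer(length(classes))
  names(means) <- names(classes); names(n) <- names(classes)
  for (k in seq_along(classes)) {
    sel <- ev$match_class == classes[k]
    n[k] <- sum(sel)
    if (n[k] < min_events) {
      stop("class ", names(classes)[k], " (", classes[k], ") has ", n[k],
           " events; need >= ", min_events)
    }
    means[k] <- mean(counts_all[sel]) / diff(window) * 1000
  }
  if (normalize) {
    denom <- mean(counts_all) / diff(window) * 1000
    if (denom > 0) means <- means / denom
  }
  structure(list(T = unname(means["T"]), CM = unname(means["CM"]),
                 DM = unname(means["DM"]), OT = unname(means["OT"]),
                 n = n, window = window),
            class = "dcm_condition_responses")
}

#' Conjunction-coding additivity index
#'
#' After removing the irrelevant-information component (estimated by the
#' opposite-target response) from each condition, the index is
#' `(T - OT) - ((CM - OT) + (DM - OT))`. It is exactly 0 whenever the
#' condition means satisfy the additive decomposition `T = C + D + I`,
#' `CM = C + I`, `DM = D + I`, `OT = I`; positive values indicate
#' super-additive conjunction coding. The index is invariant to adding any
#' constant to all four responses.
#'
#' @param cr [condition_responses()], or any list with elements `T`, `CM`,
#'   `DM`, `OT`.
#' @return numeric index.
#' @export
additivity_index <- function(cr) {
  (cr$T - cr$OT) - ((cr$CM - cr$OT) + (cr$DM - cr$OT))
}

#' Sliding-averaged additivity index along the VDI continuum
#'
#' Orders neurons by VDI and averages the additivity index in a moving window
#' of `width` neurons, the population-level summary of how conjunction coding
#' changes along the visuo-decision continuum.
#'
#' @param profiles data.frame with columns `vdi` and `additivity`.
#' @param width moving-window width in neurons (default 31).
#' @return data.frame with `vdi` (window-center VDI) and `additivity`
#'   (window mean).
#' @export
sliding_additivity <- function(profiles, width = 31) {
  keep <- complete.cases(profiles[, c("vdi", "additivity")])
  d <- profiles[keep, ]
  d <- d[order(d$vdi), ]
  n <- nrow(d)
  if (n < width) stop("need at least ", width, " neurons with VDI and additivity")
  starts <- seq_len(n - width + 1)
  data.frame(
    vdi = vapply(starts, function(s) mean(d$vdi[s:(s + width - 1)]), numeric(1)),
    additivity = vapply(starts, function(s) mean(d$additivity[s:(s + width - 1)]),
                        numeric(1)))
}

# Events usable for feature-tuning measurements: test stimuli in the RF on
# correct trials with the given sample, match stimuli (the two sample
# conjunctions) excluded.
tuning_events <- function(neuron, sample_condition) {
  ev <- event_table(neuron, tests_only = TRUE, correct_only = TRUE)
  ev[ev$location == "IN" & ev$sample == sample_condition &
       !ev$match_class %in% c("target", "opposite_target"), , drop = FALSE]
}

#' Linear color-tuning slope
#'
#' Least-squares slope of the mean response per color against the color code
#' (1 = yellow ... 8 = red), over non-match test stimuli in the RF during
#' trials with the given sample.
#'
#' @param neuron `dcm_neuron`.
#' @param sample_condition "A" or "B".
#' @param window response window ms (default `c(100, 350)`).
#' @return slope in spikes/s per color step.
#' @export
color_slope <- function(neuron, sample_condition, window = c(100, 350)) {
  ev <- tuning_events(neuron, sample_condition)
  cnt <- aligned_counts(neuron, ev, window, check = FALSE)
  have <- sort(unique(ev$color))
  if (!all(1:8 %in% have)) {
    stop("missing color level(s) ", paste(setdiff(1:8, have), collapse = ", "),
         " for sample ", sample_condition)
  }
  rate <- vapply(1:8, function(cc) mean(cnt[ev$color == cc]) / diff(window) * 1000,
                 numeric(1))
  unname(coef(lm(rate ~ x, data = data.frame(rate = rate, x = 1:8)))[2])
}

#' Attention-induced color-tuning shift
#'
#' `slope(sample A) - slope(sample B)`. With the relevant color at 1 (yellow)
#' for sample A and 8 (red) for sample B, negative values mean the tuning
#' shifted toward the currently relevant color.
#'
#' @inheritParams color_slope
#' @return slope difference.
#' @export
color_shift <- function(neuron, window = c(100, 350)) {
  color_slope(neuron, "A", window) - color_slope(neuron, "B", window)
}

#' Preferred direction by the vector method
#'
#' Resultant angle of the 8 rate-weighted unit vectors
#' `(FR(i) cos theta_i, FR(i) sin theta_i)` over non-match test stimuli.
#' Flagged undefined (NA) when the resultant length is below
#' `1e-6 * sum(FR)` (e.g. perfectly flat tuning).
#'
#' @inheritParams color_slope
#' @return angle in degrees in `[0, 360)`, or `NA_real_` when undefined.
#' @export
preferred_direction <- function(neuron, sample_condition, window = c(100, 350)) {
  ev <- tuning_events(neuron, sample_condition)
  cnt <- aligned_counts(neuron, ev, window, check = FALSE)
  have <- sort(unique(ev$direction))
  if (!all(1:8 %in% have)) {
    stop("missing direction level(s) ", paste(setdiff(1:8, have), collapse = ", "),
         " for sample ", sample_condition)
  }
  fr <- vapply(1:8, function(dd) mean(cnt[ev$direction == dd]) / diff(window) * 1000,
               numeric(1))
  th <- direction_angle(1:8) * pi / 180
  x <- sum(fr * cos(th)); y <- sum(fr * sin(th))
  if (sum(fr) == 0 || sqrt(x^2 + y^2) < 1e-6 * sum(fr)) return(NA_real_)
  (atan2(y, x) * 180 / pi) %% 360
}

# Signed circular difference a - b in (-180, 180].
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Attention-induced direction-tuning shift
#'
#' Angular distance between the preferred directions measured under sample A
#' and sample B, sign-normalized so that positive values mean the preferred
#' direction moved toward the currently relevant direction (the sample's
#' motion direction).
#'
#' @inheritParams color_slope
#' @return signed shift in degrees in `(-180, 180]`, or NA when either
#'   preferred direction is undefined.
#' @export
direction_shift <- function(neuron, window = c(100, 350)) {
  pa <- preferred_direction(neuron, "A", window)
  pb <- preferred_direction(neuron, "B", window)
  if (is.na(pa) || is.na(pb)) return(NA_real_)
  rel_a <- direction_angle(SAMPLE_DEFS$A$direction)
  magnitude <- abs(circ_diff(pa, pb))
  d_a <- abs(circ_diff(pa, rel_a))   # pref under A, distance to A's direction
  d_b <- abs(circ_diff(pb, rel_a))   # pref under B, distance to A's direction
  sign <- if (d_a < d_b) 1 else if (d_a > d_b) -1 else 0
  sign * magnitude
}

#' Pearson correlation between two per-neuron profile fields
#'
#' @param profiles data.frame (one row per neuron).
#' @param x_field,y_field column names.
#' @return list with `r`, `p`, `n`, and the `htest` object.
#' @export
correlate_profiles <- function(profiles, x_field, y_field) {
  x <- profiles[[x_field]]; y <- profiles[[y_field]]
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3) stop("need >= 3 complete pairs (got ", sum(keep), ")")
  if (sd(x[keep]) == 0 || sd(y[keep]) == 0) {
    stop("zero variance in ", if (sd(x[keep]) == 0) x_field else y_field)
  }
  ct <- cor.test(x[keep], y[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep), htest = ct)
}
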