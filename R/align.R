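#' Spike counts in a window aligned to events
#'
#' Counts spikes in the half-open window `[onset + t0, onset + t1)` for each
#' event row. All windowed analyses in the package use this half-open
#' convention: a spike exactly at the upper bound belongs to the next window.
#'
#' @param neuron `dcm_neuron`.
#' @param events data.frame with at least `trial_id` and `onset_ms`
#'   (typically a filtered [event_table()]).
#' @param window numeric length-2, `c(t0, t1)` in ms relative to event onset,
#'   `t0 < t1`.
#' @param check error when a window extends beyond the recorded trial span?
#' @return integer vector of per-event counts.
#' @export
aligned_counts <- function(neuron, events, window, check = TRUE) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (nrow(events) == 0) return(integer(0))
  if (check) {
    end_of <- setNames(neuron$trials$trial_end_ms, as.character(neuron$trials$trial_id))
    ends <- end_of[as.character(events$trial_id)]
    bad <- which(events$onset_ms + window[2] > ends | events$onset_ms + window[1] < 0)
    if (length(bad)) {
      stop("window [", window[1], ", ", window[2], ") extends beyond trial span for ",
           length(bad), " event(s): trial_id ",
           paste(utils::head(events$trial_id[bad], 5), collapse = ", "))
    }
  }
  out <- integer(nrow(events))
  for (i in seq_len(nrow(events))) {
    s <- neuron$spikes[[as.character(events$trial_id[i])]]
    lo <- events$onset_ms[i] + window[1]
    hi <- events$onset_ms[i] + window[2]
    out[i] <- sum(s >= lo & s < hi)
  }
  out
}

# Per-event counts at many window centers at once. Returns an events x centers
# integer matrix; window at center t is [t - half, t + half).
aligned_count_matrix <- function(neuron, events, centers, half_width) {
  n_ev <- nrow(events)
  m <- matrix(0L, n_ev, length(centers))
  lo <- centers - half_width
  hi <- centers + half_width
  for (i in seq_len(n_ev)) {
    s <- neuron$spikes[[as.character(events$trial_id[i])]]
    if (!length(s)) next
    rel <- s - events$onset_ms[i]
    m[i, ] <- findInterval(hi, rel, left.open = TRUE) -
      findInterval(lo, rel, left.open = TRUE)
  }
  m
}

#' Mean firing rate from window counts
#'
#' @param counts per-event spike counts.
#' @param window_ms window duration in ms (> 0).
#' @return mean rate in spikes/s.
#' @export
mean_rate <- function(counts, window_ms) {
  if (window_ms <= 0) stop("window_ms must be positive")
  if (length(counts) == 0) stop("mean rate undefined for zero events")
  mean(counts) / window_ms * 1000
}

#' Gaussian smoothing of a 1-ms binned trace
#'
#' Convolves with a unit-area Gaussian kernel (sd `sigma_ms`), truncated at
#' +/- 4 sigma. Near the edges the kernel is renormalized by its in-range
#' mass, so a constant trace is returned unchanged and the trace sum is
#' conserved in the interior.
#'
#' @param x numeric trace at 1-ms resolution.
#' @param sigma_ms kernel standard deviation in ms (default 15).
#' @return smoothed numeric trace, same length as `x`.
#' @export
smooth_trace <- function(x, sigma_ms = 15) {
  if (sigma_ms <= 0) stop("sigma_ms must be positive")
  n <- length(x)
  half <- ceiling(4 * sigma_ms)
  k <- dnorm(seq(-half, half), sd = sigma_ms)
  k <- k / sum(k)
  padded <- c(rep(0, half), x, rep(0, half))
  sm <- stats::filter(padded, k, sides = 2)
  sm <- as.numeric(sm[(half + 1):(half + n)])
  # in-range kernel mass for edge renormalization
  mass <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
  mass <- as.numeric(mass[(half + 1):(half + n)])
  sm / mass
}

# Binned spike counts (1-ms bins) aligned to an event, bins [t, t+1) for
# t in offsets[1] .. offsets[2]-1 relative to onset.
binned_raster <- function(neuron, events, offsets) {
  t0 <- offsets[1]; t1 <- offsets[2]
  nb <- t1 - t0
  m <- matrix(0L, nrow(events), nb)
  for (i in seq_len(nrow(events))) {
    s <- neuron$spikes[[as.character(events$trial_id[i])]]
    rel <- s - events$onset_ms[i] - t0
    rel <- rel[rel >= 0 & rel < nb]
    if (length(rel)) {
      tb <- tabulate(floor(rel) + 1L, nbins = nb)
      m[i, ] <- tb
    }
  }
  m
}
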