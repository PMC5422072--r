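#' Per-neuron profile table: the central population artifact
#'
#' Runs the single-neuron pipeline over a population: sample equalization,
#' sliding identity and match selectivity with latencies, VDI, choice
#' probability, conjunction additivity, feature-tuning shifts and (for
#' two-location data, on request) the laterality classification. One row per
#' neuron; analyses that cannot run for a neuron (insufficient events) yield
#' NA with a warning.
#'
#' @param dataset [dcm_population()].
#' @param seed RNG seed (drives decimation and permutation resampling).
#' @param step_ms sliding-window step for the ROC traces (default 1; use 5
#'   for large populations, latencies then resolve to 5 ms).
#' @param alpha familywise significance level for the sliding tests.
#' @param window scalar-summary window (VDI, additivity, tuning, CP summary).
#' @param laterality run the bootstrap laterality test (two-location neurons
#'   only)?
#' @param n_boot bootstrap samples for the laterality test.
#' @param features compute additivity and tuning shifts?
#' @param cp compute choice probability?
#' @return data.frame of class `dcm_profile_table`.
#' @export
neuron_profiles <- function(dataset, seed = 1, step_ms = 1, alpha = 0.01,
                            window = c(100, 350), laterality = FALSE,
                            n_boot = 1000, features = TRUE, cp = TRUE) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2 * length(dataset$neurons))
  rows <- vector("list", length(dataset$neurons))
  for (i in seq_along(dataset$neurons)) {
    nr <- dataset$neurons[[i]]
    row <- data.frame(neuron_id = as.character(nr$neuron_id),
                      monkey_id = nr$monkey_id, variant = nr$variant,
                      session_mean_rt_ms = nr$session_mean_rt_ms,
                      vdi = NA_real_, identity_strength = NA_real_,
                      match_strength = NA_real_,
                      latency_identity = NA_real_, latency_match = NA_real_,
                      identity_selective = NA, match_selective = NA,
                      cp_r = NA_real_, additivity = NA_real_,
                      color_shift = NA_real_, direction_shift = NA_real_,
                      laterality_class = NA_character_)
    res <- tryCatch({
      eq <- equalize_by_sample(nr, seed = seeds[2 * i - 1])
      idt <- sliding_selectivity(eq, "identity", step_ms = step_ms, alpha = alpha)
      mct <- sliding_selectivity(eq, "match", step_ms = step_ms, alpha = alpha)
      v <- compute_vdi(idt, mct, window)
      li <- detect_latency(idt)
      lm_ <- detect_latency(mct)
      row$vdi <- v$vdi
      row$identity_strength <- v$identity_strength
      row$match_strength <- v$match_strength
      row$latency_identity <- li
      row$latency_match <- lm_
      row$identity_selective <- !is.na(li)
      row$match_selective <- !is.na(lm_)
      row
    }, error = function(e) {
      warning("selectivity failed for neuron ", nr$neuron_id, ": ",
              conditionMessage(e))
      row
    })
    row <- res
    if (cp) {
      cp_res <- tryCatch(choice_probability(nr), error = function(e) NULL)
      if (!is.null(cp_res)) row$cp_r <- cp_res$summary_r
    }
    if (features) {
      row$additivity <- tryCatch(additivity_index(condition_responses(nr, window)),
                                 error = function(e) NA_real_)
      row$color_shift <- tryCatch(color_shift(nr, window),
                                  error = function(e) NA_real_)
      row$direction_shift <- tryCatch(direction_shift(nr, window),
                                      error = function(e) NA_real_)
    }
    if (laterality && nr$variant == "two_location") {
      row$laterality_class <- tryCatch({
        eq_att <- equalize_by_attention(nr, seed = seeds[2 * i])
        permutation_laterality_test(eq_att, n_boot = n_boot,
                                    seed = seeds[2 * i],
                                    window = window,
                                    match_selective = isTRUE(row$match_selective)
                                    )$classification
      }, error = function(e) NA_character_)
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dcm_profile_table", "data.frame")
  out
}
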