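#' Write a population dataset to disk
#'
#' Two dialects are supported. `"tabular_bundle"` writes a directory of
#' comma-separated tables (`neurons.csv`, `trials.csv`, `events.csv`,
#' `spikes.csv`) with documented column names, readable by any tool.
#' `"structured_container"` writes a single hierarchical binary file (R
#' serialization, `.rds`) holding the same schema. Both round-trip every
#' field; spike times generated by this package lie on a 1-ms integer grid,
#' so the text dialect is lossless for them too.
#'
#' @param dataset [dcm_population()].
#' @param path target directory (tabular) or file (structured).
#' @param format "tabular_bundle" or "structured_container".
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path,
                          format = c("tabular_bundle", "structured_container")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "dcm_population"))
  if (format == "structured_container") {
    saveRDS(dataset, path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  neurons <- data.table::rbindlist(lapply(dataset$neurons, function(n) {
    data.table::data.table(neuron_id = n$neuron_id, monkey_id = n$monkey_id,
                           variant = n$variant,
                           session_mean_rt_ms = n$session_mean_rt_ms)
  }))
  trials <- data.table::rbindlist(lapply(dataset$neurons, function(n) {
    data.table::data.table(neuron_id = n$neuron_id, n$trials)
  }), fill = TRUE)
  events <- data.table::rbindlist(lapply(dataset$neurons, function(n) {
    data.table::data.table(neuron_id = n$neuron_id, n$events)
  }), fill = TRUE)
  spikes <- data.table::rbindlist(lapply(dataset$neurons, function(n) {
    data.table::rbindlist(lapply(names(n$spikes), function(id) {
      s <- n$spikes[[id]]
      if (!length(s)) return(NULL)
      data.table::data.table(neuron_id = n$neuron_id, trial_id = as.integer(id),
                             time_ms = s)
    }))
  }))
  if (ncol(neurons) == 0) {
    neurons <- data.table::data.table(neuron_id = character(), monkey_id = character(),
                                      variant = character(), session_mean_rt_ms = numeric())
  }
  if (ncol(trials) == 0) {
    trials <- data.table::data.table(neuron_id = character(), trial_id = integer(),
                                     sample = character(), attention = character(),
                                     is_catch = logical(), outcome = character(),
                                     rt_ms = numeric(), responded_position = integer(),
                                     n_tests = integer(), target_position = integer(),
                                     trial_end_ms = numeric())
  }
  if (ncol(events) == 0) {
    events <- data.table::data.table(neuron_id = character(), trial_id = integer(),
                                     position = integer(), onset_ms = numeric(),
                                     duration_ms = numeric(), location = character(),
                                     color = integer(), direction = integer(),
                                     match_class = character(), is_test = logical())
  }
  if (nrow(spikes) == 0) {
    spikes <- data.table::data.table(neuron_id = character(), trial_id = integer(),
                                     time_ms = numeric())
  }
  data.table::fwrite(neurons, file.path(path, "neurons.csv"))
  data.table::fwrite(trials, file.path(path, "trials.csv"))
  data.table::fwrite(events, file.path(path, "events.csv"))
  data.table::fwrite(spikes, file.path(path, "spikes.csv"))
  invisible(path)
}

#' Read a population dataset
#'
#' Inverse of [write_dataset()]. Every neuron is validated on load unless
#' `strict = FALSE` (permissive exploratory loading: structural checks only).
#'
#' @param path directory (tabular bundle) or `.rds` file (structured
#'   container).
#' @param format storage dialect; see [write_dataset()].
#' @param strict validate semantic invariants?
#' @return [dcm_population()].
#' @export
read_dataset <- function(path,
                         format = c("tabular_bundle", "structured_container"),
                         strict = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "structured_container") {
    dataset <- readRDS(path)
    if (!inherits(dataset, "dcm_population")) stop("not a dcm_population container")
    for (n in dataset$neurons) validate_neuron(n, strict = strict)
    return(dataset)
  }
  need <- file.path(path, c("neurons.csv", "trials.csv", "events.csv", "spikes.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) stop("tabular bundle incomplete, missing: ",
                            paste(basename(missing), collapse = ", "))
  coerce_cols <- function(df, numeric_cols = character(), integer_cols = character()) {
    for (cc in intersect(numeric_cols, names(df))) df[[cc]] <- as.numeric(df[[cc]])
    for (cc in intersect(integer_cols, names(df))) df[[cc]] <- as.integer(df[[cc]])
    df
  }
  neurons_tab <- data.table::fread(need[1], colClasses = list(character = "neuron_id"))
  if (nrow(neurons_tab) == 0) {
    return(dcm_population(list(), provenance = list(kind = "file", source = path)))
  }
  neurons_tab <- coerce_cols(neurons_tab, "session_mean_rt_ms")
  trials_tab <- data.table::fread(need[2], colClasses = list(character = "neuron_id"))
  trials_tab <- coerce_cols(trials_tab, c("rt_ms", "trial_end_ms"),
                            c("responded_position", "target_position", "n_tests"))
  events_tab <- data.table::fread(need[3], colClasses = list(character = "neuron_id"))
  spikes_tab <- data.table::fread(need[4], colClasses = list(character = "neuron_id"))
  for (tab in list(trials = trials_tab, events = events_tab)) {
    if (nrow(neurons_tab) > 0 && nrow(tab) == 0) stop("schema error: empty required table")
  }
  req_tr <- c("neuron_id", "trial_id", "sample", "attention", "is_catch",
              "outcome", "rt_ms", "trial_end_ms")
  miss <- setdiff(req_tr, names(trials_tab))
  if (length(miss)) stop("schema error: trials.csv missing field(s): ",
                         paste(miss, collapse = ", "))
  req_ev <- c("neuron_id", "trial_id", "position", "onset_ms", "duration_ms",
              "location", "color", "direction", "match_class", "is_test")
  miss <- setdiff(req_ev, names(events_tab))
  if (length(miss)) stop("schema error: events.csv missing field(s): ",
                         paste(miss, collapse = ", "))
  neurons <- lapply(seq_len(nrow(neurons_tab)), function(i) {
    id <- neurons_tab$neuron_id[i]
    tr <- as.data.frame(trials_tab[trials_tab$neuron_id == id, ])
    tr$neuron_id <- NULL
    ev <- as.data.frame(events_tab[events_tab$neuron_id == id, ])
    ev$neuron_id <- NULL
    sp <- spikes_tab[spikes_tab$neuron_id == id, ]
    spikes <- setNames(vector("list", nrow(tr)), as.character(tr$trial_id))
    for (tid in names(spikes)) spikes[[tid]] <- numeric(0)
    if (nrow(sp)) {
      by_trial <- split(sp$time_ms, as.character(sp$trial_id))
      for (tid in names(by_trial)) spikes[[tid]] <- as.numeric(sort(by_trial[[tid]]))
    }
    rownames(tr) <- NULL; rownames(ev) <- NULL
    dcm_neuron(id, neurons_tab$monkey_id[i], neurons_tab$variant[i],
               tr, ev, spikes,
               session_mean_rt_ms = neurons_tab$session_mean_rt_ms[i],
               validate = FALSE)
  })
  dataset <- dcm_population(neurons, provenance = list(kind = "file", source = path))
  for (n in dataset$neurons) validate_neuron(n, strict = strict)
  dataset
}
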