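# Per-neuron event pools for each decoding scheme. Every class is a named
# list of sub-condition event index vectors into the neuron's pooled event
# table; pseudo-trials are drawn with the stated sub-condition composition.
decode_pools <- function(neuron, scheme) {
  if (scheme == "sample") {
    tr <- neuron$trials
    keep <- tr$outcome %in% c("hit", "correct_reject")
    ev <- data.frame(trial_id = tr$trial_id[keep], onset_ms = 0,
                     sample = tr$sample[keep])
    return(list(events = ev,
                classes = list(A = list(sampleA = which(ev$sample == "A")),
                               B = list(sampleB = which(ev$sample == "B")))))
  }
  ev <- event_table(neuron, tests_only = TRUE, correct_only = TRUE)
  ev <- ev[ev$location == "IN" &
             ev$match_class %in% c("target", "opposite_target"), , drop = FALSE]
  is_a <- ev$color == SAMPLE_DEFS$A$color & ev$direction == SAMPLE_DEFS$A$direction
  is_t <- ev$match_class == "target"
  pools <- list(target_A = which(is_a & is_t), opp_A = which(is_a & !is_t),
                target_B = which(!is_a & is_t), opp_B = which(!is_a & !is_t))
  classes <- if (scheme == "identity") {
    list(A = pools[c("target_A", "opp_A")], B = pools[c("target_B", "opp_B")])
  } else {
    list(match = pools[c("target_A", "target_B")],
         nonmatch = pools[c("opp_A", "opp_B")])
  }
  list(events = ev, classes = classes)
}

# One train/test draw for one neuron: each sub-condition's source events are
# first partitioned into a training and a testing source pool, then the
# pseudo-trials are sampled with replacement within each pool. Test draws are
# therefore always disjoint from training draws at the source-event level.
draw_split <- function(class_pools, n_train, n_test, train_frac = 0.7) {
  train <- list(); test <- list()
  for (cls in names(class_pools)) {
    tr_idx <- integer(0); te_idx <- integer(0)
    for (sub in class_pools[[cls]]) {
      m <- length(sub)
      if (m < 2) return(NULL)
      n_tr_src <- max(1L, min(m - 1L, round(train_frac * m)))
      src_tr <- sample.int(m, n_tr_src)
      src_te <- setdiff(seq_len(m), src_tr)
      tr <- sub[src_tr][sample.int(n_tr_src, n_train, replace = TRUE)]
      te <- sub[src_te][sample.int(length(src_te), n_test, replace = TRUE)]
      tr_idx <- c(tr_idx, tr); te_idx <- c(te_idx, te)
    }
    train[[cls]] <- tr_idx; test[[cls]] <- te_idx
  }
  list(train = train, test = test)
}

#' Build one pseudo-trial train/test set
#'
#' Draws, independently for every neuron, the stated sub-condition composition
#' with replacement (identity: per class 140 train = 70 target + 70
#' opposite-target presentations of the same stimulus, 60 test; match: 140
#' train = 70 target A + 70 target B vs the two opposite-target pools, 60
#' test; sample: 70 train / 30 test per sample), with test draws restricted to
#' source events not used for training. Feature vectors concatenate per-neuron
#' spike counts in `window` (ms from event onset; trial start for the sample
#' scheme).
#'
#' @param dataset [dcm_population()].
#' @param scheme "identity", "match" or "sample".
#' @param window counting window `c(t0, t1)` ms.
#' @param n_train,n_test per-sub-condition train/test draws.
#' @param seed RNG seed.
#' @return list with `x_train`, `y_train`, `x_test`, `y_test`, the per-neuron
#'   source indices (`sources`), and `excluded` neuron ids (missing a
#'   sub-condition).
#' @export
build_pseudotrials <- function(dataset, scheme = c("identity", "match", "sample"),
                               window = c(100, 300), n_train = 70, n_test = 30,
                               seed = 1) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  prep <- prep_decode(dataset, scheme, centers = mean(window),
                      half = diff(window) / 2)
  splits <- lapply(prep$pools, function(p) draw_split(p$classes, n_train, n_test))
  if (any(vapply(splits, is.null, logical(1)))) {
    stop("a neuron's sub-condition pool is too small to hold out test events; ",
         "reduce n_train or simulate more trials")
  }
  assemble <- function(part) {
    cls_names <- names(prep$pools[[1]]$classes)
    xs <- list(); ys <- list()
    for (cls in cls_names) {
      cols <- lapply(seq_along(prep$pools), function(i) {
        prep$counts[[i]][splits[[i]][[part]][[cls]], 1]
      })
      xs[[cls]] <- do.call(cbind, cols)
      ys[[cls]] <- rep(cls, nrow(xs[[cls]]))
    }
    list(x = do.call(rbind, xs), y = factor(unlist(ys)))
  }
  tr <- assemble("train"); te <- assemble("test")
  list(x_train = tr$x, y_train = tr$y, x_test = te$x, y_test = te$y,
       sources = splits, excluded = prep$excluded)
}

# Shared preparation: filter usable neurons, precompute count matrices
# (events x centers) per neuron.
prep_decode <- function(dataset, scheme, centers, half) {
  pools <- list(); counts <- list(); excluded <- character(0)
  for (n in dataset$neurons) {
    p <- decode_pools(n, scheme)
    sizes <- unlist(lapply(p$classes, function(cl) vapply(cl, length, integer(1))))
    if (any(sizes < 2)) {
      excluded <- c(excluded, as.character(n$neuron_id))
      next
    }
    pools[[length(pools) + 1]] <- p
    counts[[length(counts) + 1]] <- aligned_count_matrix(n, p$events, centers, half)
  }
  if (length(excluded)) {
    warning("excluded ", length(excluded),
            " neuron(s) lacking a sub-condition: ",
            paste(utils::head(excluded, 5), collapse = ", "))
  }
  if (!length(pools)) stop("no usable neurons for scheme")
  list(pools = pools, counts = counts, excluded = excluded)
}

#' Time-resolved pseudo-population decoding
#'
#' At each window center, trains a linear maximum-margin classifier
#' (`e1071::svm`, linear kernel, cost 1) on freshly drawn pseudo-trials and
#' measures accuracy on held-out draws; repeated `n_iter` times. Features are
#' per-neuron spike counts in the 200-ms window, standardized per iteration
#' using training-set statistics. The decoder is significant at a time point
#' when accuracy exceeds chance (0.5) on more than `signif_frac` of the
#' iterations (the 990/1000 rule at the defaults).
#'
#' @param dataset [dcm_population()].
#' @param scheme "identity", "match" or "sample".
#' @param window_ms sliding window (default 200).
#' @param step_ms window-center step (default 10).
#' @param t_range center range; defaults to `c(-100, 450)` ms from test onset
#'   (identity/match) or `c(0, 1350)` ms from trial start (sample).
#' @param n_iter iterations (default 1000).
#' @param n_train,n_test per-sub-condition draws (defaults 70/30).
#' @param signif_frac strict significance threshold on the fraction of
#'   above-chance iterations (default 0.99).
#' @param standardize z-score features with training statistics?
#' @param cost SVM regularization constant.
#' @param seed RNG seed.
#' @return list of class `dcm_decode_result`: `times_ms`, `accuracy` (mean
#'   over iterations), `iteration_accuracies` (n_iter x time matrix),
#'   `significant`, `significance_latency_ms` (earliest significant center
#'   >= 0), `scheme`, `chance = 0.5`, `excluded`.
#' @export
decode_timecourse <- function(dataset, scheme = c("identity", "match", "sample"),
                              window_ms = 200, step_ms = 10, t_range = NULL,
                              n_iter = 1000, n_train = 70, n_test = 30,
                              signif_frac = 0.99, standardize = TRUE, cost = 1,
                              seed = 1) {
  scheme <- match.arg(scheme)
  if (is.null(t_range)) t_range <- if (scheme == "sample") c(0, 1350) else c(-100, 450)
  centers <- seq(t_range[1], t_range[2], by = step_ms)
  half <- window_ms / 2
  set.seed(seed)
  prep <- prep_decode(dataset, scheme, centers, half)
  n_neur <- length(prep$pools)
  cls_names <- names(prep$pools[[1]]$classes)

  acc <- matrix(NA_real_, n_iter, length(centers))
  for (it in seq_len(n_iter)) {
    splits <- lapply(prep$pools, function(p) draw_split(p$classes, n_train, n_test))
    if (any(vapply(splits, is.null, logical(1)))) {
      stop("a neuron's sub-condition pool is too small to hold out test events; ",
           "reduce n_train or simulate more trials")
    }
    tr_rows <- lapply(cls_names, function(cls) {
      vapply(seq_len(n_neur), function(i) splits[[i]]$train[[cls]],
             integer(length(splits[[1]]$train[[cls]])))
    })
    te_rows <- lapply(cls_names, function(cls) {
      vapply(seq_len(n_neur), function(i) splits[[i]]$test[[cls]],
             integer(length(splits[[1]]$test[[cls]])))
    })
    y_train <- factor(rep(cls_names, vapply(tr_rows, nrow, integer(1))))
    y_test <- factor(rep(cls_names, vapply(te_rows, nrow, integer(1))))
    tr_rows <- do.call(rbind, tr_rows)   # pseudo-trials x neurons (source rows)
    te_rows <- do.call(rbind, te_rows)
    for (j in seq_along(centers)) {
      xtr <- matrix(0, nrow(tr_rows), n_neur)
      xte <- matrix(0, nrow(te_rows), n_neur)
      for (i in seq_len(n_neur)) {
        cj <- prep$counts[[i]][, j]
        xtr[, i] <- cj[tr_rows[, i]]
        xte[, i] <- cj[te_rows[, i]]
      }
      if (standardize) {
        mu <- colMeans(xtr)
        sdv <- apply(xtr, 2, sd)
        sdv[sdv == 0] <- 1
        xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
        xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
      }
      fit <- e1071::svm(xtr, y_train, kernel = "linear", cost = cost,
                        scale = FALSE)
      acc[it, j] <- mean(predict(fit, xte) == y_test)
    }
  }
  frac_above <- colMeans(acc > 0.5)
  significant <- frac_above > signif_frac
  lat <- NA_real_
  post <- which(significant & centers >= 0)
  if (length(post)) lat <- centers[min(post)]
  structure(list(times_ms = centers, accuracy = colMeans(acc),
                 iteration_accuracies = acc, significant = significant,
                 frac_above_chance = frac_above,
                 significance_latency_ms = lat, scheme = scheme, chance = 0.5,
                 n_iter = n_iter, excluded = prep$excluded),
            class = "dcm_decode_result")
}
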