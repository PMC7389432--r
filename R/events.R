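#' Reconstruct a foot-floor-contact signal from window labels
#'
#' Expands each window's predicted label to its `window_len` samples in
#' chronological order. All windows — including those that straddled a
#' phase transition during training — must carry a prediction here.
#'
#' @param labels Integer/numeric vector of 0/1 window labels in
#'   chronological order.
#' @param window_len Window length in samples.
#' @return Integer vector of length `length(labels) * window_len`.
#' @export
#' @examples
#' reconstruct_basographic(c(0, 0, 1, 1), window_len = 20)
reconstruct_basographic <- function(labels, window_len = 20) {
  if (length(labels) == 0)
    stopf("no window labels to reconstruct from",
          class = "gaitphase_validation_error")
  if (anyNA(labels) || !all(labels %in% c(0, 1)))
    stopf("window labels must all be 0 or 1 at reconstruction time",
          class = "gaitphase_validation_error")
  rep(as.integer(labels), each = window_len)
}

rle_tbl <- function(x) {
  r <- rle(as.integer(x))
  tibble(value = r$values, length = r$lengths,
         start = c(0L, cumsum(head(r$lengths, -1))))
}

#' Remove spuriously short phases from a binary signal
#'
#' Gait phases shorter than `min_duration_ms` are physiologically
#' implausible misclassification spikes. The signal is scanned as
#' run-length segments and, while any run is strictly shorter than the
#' minimum, the shortest violating run (leftmost on ties) is absorbed: an
#' interior or final run merges into the preceding phase, the first run
#' takes the value of the following phase. Runs of exactly the minimum
#' duration are kept.
#'
#' @param x Binary vector (0 stance / 1 swing).
#' @param sampling_rate Sampling rate in Hz.
#' @param min_duration_ms Minimum accepted phase duration in milliseconds.
#' @return List with `signal` (cleaned vector) and `spikes`: a tibble of
#'   removed runs (`value`, `length`, `duration_ms`).
#' @export
#' @examples
#' remove_short_phases(rep(c(0, 1, 0), c(500, 300, 700)), 2000)$spikes
remove_short_phases <- function(x, sampling_rate, min_duration_ms = 175) {
  min_len <- min_duration_ms / 1000 * sampling_rate
  r <- rle(as.integer(x))
  removed_len <- integer(0)
  removed_val <- integer(0)
  repeat {
    k <- length(r$lengths)
    if (k <= 1) break
    viol <- which(r$lengths < min_len)
    if (length(viol) == 0) break
    i <- viol[which.min(r$lengths[viol])]
    removed_len <- c(removed_len, r$lengths[i])
    removed_val <- c(removed_val, r$values[i])
    if (i == 1) {
      # first run merges forward: it takes the next phase's value
      r$lengths[2] <- r$lengths[2] + r$lengths[1]
      r$lengths <- r$lengths[-1]
      r$values <- r$values[-1]
    } else {
      # merge into the preceding phase; coalesce with the following run,
      # which necessarily shares the preceding run's value
      r$lengths[i - 1] <- r$lengths[i - 1] + r$lengths[i]
      if (i < k) {
        r$lengths[i - 1] <- r$lengths[i - 1] + r$lengths[i + 1]
        drop <- c(i, i + 1)
      } else drop <- i
      r$lengths <- r$lengths[-drop]
      r$values <- r$values[-drop]
    }
  }
  list(signal = inverse.rle(r),
       spikes = tibble(value = removed_val, length = removed_len,
                       duration_ms = removed_len / sampling_rate * 1000))
}

#' Detect heel-strike and toe-off events in a binary signal
#'
#' A heel-strike (HS) is any 1-to-0 transition (swing to stance), a toe-off
#' (TO) any 0-to-1 transition. The event time is the first sample of the
#' new phase, 0-based; times are reported in samples and milliseconds.
#'
#' @param x Binary vector (0 stance / 1 swing), ideally cleaned with
#'   [remove_short_phases()].
#' @param sampling_rate Sampling rate in Hz.
#' @return Tibble with `type` ("HS"/"TO"), `sample`, `time_ms`, ordered in
#'   time; empty for a constant signal.
#' @export
#' @examples
#' detect_events(rep(c(1, 0, 1), c(400, 800, 400)), 2000)
detect_events <- function(x, sampling_rate) {
  x <- as.integer(x)
  d <- diff(x)
  idx <- which(d != 0)           # transition after sample idx (1-based)
  tibble(type = ifelse(d[idx] < 0, "HS", "TO"),
         sample = as.integer(idx),          # 0-based first sample of new phase
         time_ms = idx / sampling_rate * 1000)
}

greedy_match_one_type <- function(pred_ms, truth_ms, tolerance_ms) {
  truth_used <- rep(FALSE, length(truth_ms))
  pairs_p <- numeric(0)
  pairs_g <- numeric(0)
  for (tp in pred_ms) {
    if (length(truth_ms) == 0) break
    d <- abs(truth_ms - tp)
    d[truth_used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && d[j] < tolerance_ms) {
      truth_used[j] <- TRUE
      pairs_p <- c(pairs_p, tp)
      pairs_g <- c(pairs_g, truth_ms[j])
    }
  }
  list(pairs = tibble(pred_ms = pairs_p, truth_ms = pairs_g,
                      error_ms = abs(pairs_g - pairs_p)),
       fp_ms = setdiff(pred_ms, pairs_p),
       fn_ms = truth_ms[!truth_used])
}

#' Match predicted events against ground truth within a tolerance
#'
#' Per event type, predicted events are paired one-to-one with ground-truth
#' events: scanning predictions chronologically, each takes the nearest
#' still-unmatched truth event of the same type with
#' `|t_g - t_p| < tolerance_ms` (strict). Unmatched predictions are false
#' positives, unmatched truth events false negatives.
#'
#' @param predicted,truth Event tibbles as returned by [detect_events()]
#'   (columns `type`, `time_ms`).
#' @param tolerance_ms Temporal tolerance T in milliseconds.
#' @return An `event_match`: list with per-type elements `HS` and `TO`,
#'   each holding `pairs` (tibble `pred_ms`, `truth_ms`, `error_ms`),
#'   `fp_ms`, `fn_ms`; plus `tolerance_ms`.
#' @export
match_events <- function(predicted, truth, tolerance_ms = 600) {
  out <- lapply(c(HS = "HS", TO = "TO"), function(ty) {
    greedy_match_one_type(
      sort(predicted$time_ms[predicted$type == ty]),
      sort(truth$time_ms[truth$type == ty]),
      tolerance_ms)
  })
  structure(c(out, list(tolerance_ms = tolerance_ms)),
            class = "event_match")
}

#' @export
print.event_match <- function(x, ...) {
  for (ty in c("HS", "TO"))
    cat(sprintf("%s: TP %d FP %d FN %d\n", ty, nrow(x[[ty]]$pairs),
                length(x[[ty]]$fp_ms), length(x[[ty]]$fn_ms)))
  invisible(x)
}

#' Score matched events: precision, recall, F1 and timing error
#'
#' Precision = TP / (TP + FP), recall = TP / (TP + FN), F1 their harmonic
#' mean, and MAE the mean absolute time difference over matched pairs (ms).
#' A metric whose denominator is zero is reported as `NA`, not 0.
#'
#' @param match An `event_match` from [match_events()].
#' @return Tibble with one row per event type: `type`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`, `mae_ms`.
#' @export
score_events <- function(match) {
  stopifnot(inherits(match, "event_match"))
  purrr::map_dfr(c("HS", "TO"), function(ty) {
    m <- match[[ty]]
    tp <- nrow(m$pairs)
    fp <- length(m$fp_ms)
    fn <- length(m$fn_ms)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    tibble(type = ty, tp = tp, fp = fp, fn = fn,
           precision = precision, recall = recall, f1 = f1,
           mae_ms = if (tp > 0) mean(m$pairs$error_ms) else NA_real_)
  })
}

#' Predicted-label windows to scored gait events, end to end
#'
#' Reconstructs the foot-floor-contact signal from per-window predictions,
#' removes implausibly short phases, detects HS/TO events, and scores them
#' against ground-truth events.
#'
#' @param pred_labels 0/1 predicted labels for every window, chronological.
#' @param truth_events Ground-truth event tibble (`type`, `time_ms`).
#' @param sampling_rate Sampling rate in Hz.
#' @param window_len Window length in samples.
#' @param offset_ms Time of the first window's first sample, in ms (nonzero
#'   when scoring a test slot cut from a longer record).
#' @param tolerance_ms Matching tolerance T in ms.
#' @param min_duration_ms Minimum phase duration for spike removal, ms.
#' @return List with `events` (predicted event tibble), `match`, `scores`
#'   (from [score_events()]), and `spikes`.
#' @export
evaluate_events <- function(pred_labels, truth_events, sampling_rate,
                            window_len = 20, offset_ms = 0,
                            tolerance_ms = 600, min_duration_ms = 175) {
  baso <- reconstruct_basographic(pred_labels, window_len)
  cleaned <- remove_short_phases(baso, sampling_rate, min_duration_ms)
  ev <- detect_events(cleaned$signal, sampling_rate)
  ev$time_ms <- ev$time_ms + offset_ms
  m <- match_events(ev, truth_events, tolerance_ms)
  list(events = ev, match = m, scores = score_events(m),
       spikes = cleaned$spikes)
}
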