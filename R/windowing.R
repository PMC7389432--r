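#' Interleave envelope channels into fixed-length window vectors
#'
#' Splits the common timeline into consecutive, non-overlapping windows of
#' `window_len` samples and builds one flat vector per window with
#' channel-fastest interleaving: vector position `t * n_channels + m`
#' (0-based) holds sample `t` of channel `m`, so a 20-sample window over 10
#' channels becomes a 200-value vector whose first entries are sample 0 of
#' every channel in [emg_channels()] order. Trailing samples that do not
#' fill a window are discarded.
#'
#' @param env An `envelope_set`, or any data frame whose non-`sample`
#'   columns are the channels (channel order = column order).
#' @param window_len Window length in samples.
#' @return List with `vectors` (matrix, `n_windows` x
#'   `window_len * n_channels`) and `window_start` (0-based start sample of
#'   each window).
#' @export
#' @examples
#' env <- tibble::tibble(a = 1:6 / 10, b = 7:12 / 100)
#' interleave_windows(env, window_len = 3)$vectors
interleave_windows <- function(env, window_len = 20) {
  cols <- setdiff(names(env), "sample")
  X <- as.matrix(as.data.frame(env)[cols])
  n <- nrow(X)
  m <- ncol(X)
  nw <- n %/% window_len
  if (nw < 1)
    stopf("need at least %d samples for one window, got %d",
          window_len, n, class = "gaitphase_empty_dataset")
  used <- X[seq_len(nw * window_len), , drop = FALSE]
  # t(used) is channel-fastest over samples; each column of the reshape is
  # one window's interleaved vector
  vectors <- t(matrix(t(used), nrow = window_len * m))
  colnames(vectors) <- paste0(rep(cols, times = window_len), "_t",
                              rep(seq_len(window_len) - 1, each = m))
  list(vectors = vectors,
       window_start = as.integer((seq_len(nw) - 1) * window_len))
}

#' Undo the channel interleaving of window vectors
#'
#' @param vectors Matrix from [interleave_windows()].
#' @param n_channels Number of interleaved channels.
#' @return Matrix with `n_windows * window_len` rows and `n_channels`
#'   columns: the reconstructed channel samples in timeline order.
#' @export
deinterleave_windows <- function(vectors, n_channels = 10) {
  stopifnot(ncol(vectors) %% n_channels == 0)
  out <- matrix(t(vectors), ncol = n_channels, byrow = TRUE)
  colnames(out) <- NULL
  out
}

#' Label windows from the foot-floor-contact signal
#'
#' A window whose basographic samples are all 0 is a stance window (label
#' 0); all 1, a swing window (label 1). Windows containing a phase
#' transition are masked: they carry no class label and are excluded from
#' classifier training and accuracy, but still receive a prediction when
#' the foot-floor-contact signal is reconstructed for event detection.
#'
#' @param basographic Integer/numeric vector of 0/1 values covering every
#'   window.
#' @param window_start 0-based window start samples.
#' @param window_len Window length in samples.
#' @return Tibble with `label` (0, 1, or NA when masked) and `masked`.
#' @export
label_windows <- function(basographic, window_start, window_len = 20) {
  if (!all(basographic %in% c(0, 1)))
    stopf("basographic signal must be binary (0 = stance, 1 = swing)",
          class = "gaitphase_validation_error")
  if (max(window_start) + window_len > length(basographic))
    stopf("basographic signal (%d samples) does not cover the last window",
          length(basographic), class = "gaitphase_validation_error")
  lab <- vapply(window_start, function(s) {
    w <- basographic[(s + 1):(s + window_len)]
    if (all(w == 0)) 0L else if (all(w == 1)) 1L else NA_integer_
  }, integer(1))
  tibble(label = lab, masked = is.na(lab))
}

#' Build the windowed dataset for one target leg
#'
#' Combines [interleave_windows()] and [label_windows()] into the dataset
#' the classifier consumes: one row per window, chronological order.
#'
#' @param env An `envelope_set` from [preprocess_recording()].
#' @param target_leg `"L"` or `"R"`: which leg's foot-floor-contact signal
#'   provides the labels.
#' @param window_len Window length in samples.
#' @return A `window_dataset` tibble with columns `start` (0-based sample),
#'   `label`, `masked`, and a matrix column `vector`; attributes
#'   `window_len`, `n_channels`, `target_leg`, `sampling_rate`,
#'   `subject_id`.
#' @export
window_dataset <- function(env, target_leg = "L", window_len = 20) {
  stopifnot(inherits(env, "envelope_set"))
  target_leg <- match.arg(target_leg, c("L", "R"))
  baso_col <- paste0("FSW_", target_leg)
  baso <- attr(env, "basographic")[[baso_col]]
  iw <- interleave_windows(env, window_len)
  labs <- label_windows(baso, iw$window_start, window_len)
  out <- tibble(start = iw$window_start, label = labs$label,
                masked = labs$masked, vector = iw$vectors)
  structure(out,
            class = c("window_dataset", class(tibble())),
            window_len = as.integer(window_len),
            n_channels = length(setdiff(names(env), "sample")),
            target_leg = target_leg,
            sampling_rate = attr(env, "sampling_rate"),
            subject_id = attr(env, "subject_id"))
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf(
    "<window_dataset> %s leg %s | %d windows x %d values | %d masked\n",
    attr(x, "subject_id") %||% "?", attr(x, "target_leg"), nrow(x),
    ncol(x$vector), sum(x$masked)))
  invisible(x)
}

#' Split windows into contiguous equal slots
#'
#' Partitions the chronological window sequence into `k` contiguous,
#' disjoint, exhaustive ranges whose sizes differ by at most one window —
#' the slots used by the intra-subject 10-fold protocol.
#'
#' @param n_windows Total number of windows (or a `window_dataset`).
#' @param k Number of slots.
#' @return Tibble with `slot`, `from`, `to` (1-based inclusive window
#'   indices) and `n`.
#' @export
#' @examples
#' split_slots(101, k = 10)
split_slots <- function(n_windows, k = 10) {
  if (inherits(n_windows, "data.frame")) n_windows <- nrow(n_windows)
  if (k < 2)
    stopf("`k` must be at least 2", class = "gaitphase_validation_error")
  if (n_windows < k)
    stopf("cannot split %d windows into %d slots", n_windows, k,
          class = "gaitphase_validation_error")
  sizes <- rep(n_windows %/% k, k)
  rem <- n_windows %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  to <- cumsum(sizes)
  tibble(slot = seq_len(k), from = c(1L, head(to, -1) + 1L),
         to = as.integer(to), n = as.integer(sizes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
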