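# Apply a linear-phase FIR (odd length) with reflection padding and
# group-delay compensation, so the output is time-aligned with the input.
fir_apply <- function(x, h) {
  m <- length(h)
  stopifnot(m %% 2 == 1)
  d <- (m - 1) / 2
  n <- length(x)
  if (n <= m)
    stopf("signal (%d samples) must be longer than the filter (%d taps)",
          n, m, class = "gaitphase_length_error")
  pad_front <- x[pmin(n, m:1 + 1)]
  pad_back <- x[pmax(1, n - (1:m))]
  y <- signal::fftfilt(h, c(pad_front, x, pad_back))
  y[(m + d + 1):(m + d + n)]
}

#' Band-pass filter raw sEMG
#'
#' High-pass (motion-artifact removal) then low-pass (high-frequency noise
#' removal) using two linear-phase FIR filters applied in cascade, with
#' group-delay compensation so the output stays time-aligned with the input.
#'
#' @param x Numeric vector, one raw EMG channel.
#' @param sampling_rate Sampling rate in Hz.
#' @param hp_cutoff,lp_cutoff High-/low-pass cut-off frequencies in Hz.
#' @param order FIR order per filter (taps = order + 1, Hamming window).
#' @return Numeric vector, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 2000)
#' y <- bandpass_raw(sin(2 * pi * 100 * t), 2000)
bandpass_raw <- function(x, sampling_rate, hp_cutoff = 20, lp_cutoff = 450,
                         order = 250) {
  if (sampling_rate <= 2 * lp_cutoff)
    stopf("sampling rate %g Hz cannot represent a %g Hz low-pass band",
          sampling_rate, lp_cutoff, class = "gaitphase_invalid_parameter")
  if (order %% 2 == 1) order <- order + 1  # keep an odd tap count (type I)
  nyq <- sampling_rate / 2
  hp <- signal::fir1(order, hp_cutoff / nyq, type = "high")
  lp <- signal::fir1(order, lp_cutoff / nyq, type = "low")
  fir_apply(fir_apply(x, hp), lp)
}

#' Extract the linear envelope of a filtered EMG signal
#'
#' Full-wave rectification followed by a second-order Butterworth low-pass
#' applied forward and backward (zero net phase shift). Reflection padding
#' suppresses start-up transients; tiny negative overshoots from the IIR
#' filter are clipped at zero.
#'
#' @param x Numeric vector, a band-passed EMG channel.
#' @param sampling_rate Sampling rate in Hz.
#' @param env_cutoff Envelope low-pass cut-off in Hz.
#' @return Non-negative numeric vector, same length as `x`.
#' @export
extract_envelope <- function(x, sampling_rate, env_cutoff = 5) {
  if (sampling_rate <= 2 * env_cutoff)
    stopf("sampling rate %g Hz cannot represent a %g Hz envelope band",
          sampling_rate, env_cutoff, class = "gaitphase_invalid_parameter")
  r <- abs(x)
  bf <- signal::butter(2, env_cutoff / (sampling_rate / 2), type = "low")
  n <- length(r)
  # reflection pad long enough for the 2nd-order IIR start-up transient to
  # decay below 1e-6 (pole radius ~ 1 - env_cutoff*pi/nyquist)
  pad <- min(n - 1, 6 * ceiling(sampling_rate / env_cutoff))
  z <- c(r[pad:1 + 1], r, r[n - (1:pad)])
  fwd <- signal::filter(bf, z)
  bwd <- rev(as.numeric(signal::filter(bf, rev(as.numeric(fwd)))))
  pmax(0, bwd[(pad + 1):(pad + n)])
}

#' Min-max normalize an envelope to \[0, 1\]
#'
#' @param x Numeric vector (non-empty).
#' @return List with `values` (normalized vector) and `bounds`
#'   (named numeric `min`, `max` used for scaling).
#' @export
#' @examples
#' minmax_normalize(c(2, 4, 6))$values
minmax_normalize <- function(x) {
  if (length(x) == 0)
    stopf("cannot normalize an empty sequence",
          class = "gaitphase_invalid_parameter")
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo)
    stopf("degenerate (constant) channel: min == max == %g", lo,
          class = "gaitphase_degenerate_signal")
  list(values = (x - lo) / (hi - lo), bounds = c(min = lo, max = hi))
}

#' Pre-process a subject recording into normalized envelopes
#'
#' Applies, per channel and in order: band-pass FIR filtering
#' ([bandpass_raw()]), rectification + zero-phase Butterworth envelope
#' extraction ([extract_envelope()]), and subject-level min-max
#' normalization ([minmax_normalize()]). Channel order is preserved.
#'
#' @param rec A `subject_recording` (see [simulate_subject()],
#'   [read_subject_csv()]).
#' @param hp_cutoff,lp_cutoff,env_cutoff Filter cut-offs in Hz.
#' @param fir_order FIR order for the band-pass stage.
#' @return An `envelope_set`: tibble with `sample` and one \[0,1\] column per
#'   channel; attributes `subject_id`, `sampling_rate`, `bounds` (tibble
#'   `channel`, `min`, `max`) and `basographic` (the recording's FSW
#'   columns, carried along for windowing).
#' @export
preprocess_recording <- function(rec, hp_cutoff = 20, lp_cutoff = 450,
                                 env_cutoff = 5, fir_order = 250) {
  stopifnot(inherits(rec, "subject_recording"))
  fs <- attr(rec, "sampling_rate")
  envs <- vector("list", length(emg_channels()))
  bounds <- vector("list", length(emg_channels()))
  for (i in seq_along(emg_channels())) {
    ch <- emg_channels()[i]
    res <- tryCatch({
      filt <- bandpass_raw(rec[[ch]], fs, hp_cutoff, lp_cutoff, fir_order)
      env <- extract_envelope(filt, fs, env_cutoff)
      minmax_normalize(env)
    }, gaitphase_error = function(e) {
      stopf("channel %s: %s", ch, conditionMessage(e),
            class = class(e)[1])
    })
    envs[[i]] <- res$values
    bounds[[i]] <- res$bounds
  }
  names(envs) <- emg_channels()
  out <- tibble(sample = rec$sample, !!!envs)
  structure(out,
            class = c("envelope_set", class(tibble())),
            subject_id = attr(rec, "subject_id"),
            sampling_rate = fs,
            bounds = tibble(channel = emg_channels(),
                            min = vapply(bounds, `[[`, 0, "min"),
                            max = vapply(bounds, `[[`, 0, "max")),
            basographic = tibble(FSW_R = rec$FSW_R, FSW_L = rec$FSW_L))
}

#' @export
print.envelope_set <- function(x, ...) {
  cat(sprintf("<envelope_set> %s | %d samples @ %g Hz\n",
              attr(x, "subject_id"), nrow(x), attr(x, "sampling_rate")))
  NextMethod()
}
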