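#' Default per-muscle activation profiles
#'
#' One burst list per EMG channel, expressed in the owning leg's gait-cycle
#' coordinates (heel-strike at cycle fraction 0, toe-off near 0.6 for a
#' typical 60/40 stance/swing split). Each burst is a Gaussian bump with a
#' `center` (cycle fraction in \[0,1)), `width` (Gaussian sigma, cycle
#' fraction) and `amplitude` (arbitrary units). The shapes follow the classic
#' activation timing of the five recorded muscles: tibialis anterior (TA)
#' fires during swing and at loading, gastrocnemius lateralis (GL) in
#' mid/late stance, medial hamstrings (MH) in terminal swing, vastus
#' lateralis (VL) and rectus femoris (RF) at loading response with an extra
#' RF burst around toe-off.
#'
#' @return Named list over [emg_channels()]; each element a tibble with
#'   columns `center`, `width`, `amplitude`.
#' @export
default_muscle_profiles <- function() {
  per_leg <- list(
    TA = tibble(center = c(0.05, 0.80), width = c(0.04, 0.10),
                amplitude = c(0.9, 1.0)),
    GL = tibble(center = 0.40, width = 0.08, amplitude = 1.0),
    MH = tibble(center = c(0.95, 0.05), width = c(0.05, 0.05),
                amplitude = c(0.9, 0.5)),
    VL = tibble(center = 0.07, width = 0.05, amplitude = 1.0),
    RF = tibble(center = c(0.07, 0.63), width = c(0.05, 0.05),
                amplitude = c(0.7, 0.6))
  )
  out <- c(per_leg, per_leg)
  names(out) <- emg_channels()
  out
}

#' Parameters for the synthetic gait/EMG simulator
#'
#' Bundles everything the simulator needs: walk duration and sampling rate,
#' stride-timing statistics, the stance/swing split, per-muscle activation
#' bursts, and the broadband carrier band. Defaults emulate a ~5-minute
#' self-paced walk of a healthy adult (~270 strides at 1.1 s per stride)
#' recorded at 2 kHz with a 60/40 stance/swing split.
#'
#' @param duration_s Walk duration in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param stride_mean_ms,stride_sd_ms Mean and SD of stride duration (ms);
#'   draws are truncated at three SDs.
#' @param stance_fraction_mean,stance_fraction_sd Mean and SD of the per-
#'   stride stance fraction; draws are truncated to \[0.45, 0.75\].
#' @param muscle_profiles Named list of burst tables as produced by
#'   [default_muscle_profiles()], one per channel in [emg_channels()] order.
#' @param carrier_band Length-2 numeric, the EMG carrier band in Hz.
#' @param noise_floor Baseline carrier amplitude relative to a unit burst.
#' @param seed Integer seed; identical seeds give bit-identical subjects.
#' @return An object of class `gait_sim_params`.
#' @export
#' @examples
#' p <- gait_sim_params(duration_s = 20, seed = 1)
gait_sim_params <- function(duration_s = 300,
                            sampling_rate = 2000,
                            stride_mean_ms = 1100,
                            stride_sd_ms = 60,
                            stance_fraction_mean = 0.60,
                            stance_fraction_sd = 0.02,
                            muscle_profiles = default_muscle_profiles(),
                            carrier_band = c(20, 450),
                            noise_floor = 0.05,
                            seed = 1L) {
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0)
    stopf("`duration_s` must be a single positive number, not %s",
          deparse(duration_s), class = "gaitphase_invalid_parameter")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    stopf("`sampling_rate` must be a single positive number",
          class = "gaitphase_invalid_parameter")
  if (stride_mean_ms <= 0 || stride_sd_ms < 0)
    stopf("stride duration statistics must satisfy mean > 0, sd >= 0",
          class = "gaitphase_invalid_parameter")
  if (stance_fraction_mean <= 0 || stance_fraction_mean >= 1)
    stopf("`stance_fraction_mean` must lie in (0, 1)",
          class = "gaitphase_invalid_parameter")
  if (stance_fraction_sd < 0)
    stopf("`stance_fraction_sd` must be >= 0",
          class = "gaitphase_invalid_parameter")
  if (!identical(sort(names(muscle_profiles)), sort(emg_channels())))
    stopf("`muscle_profiles` must have exactly one entry per channel (%s)",
          paste(emg_channels(), collapse = ", "),
          class = "gaitphase_invalid_parameter")
  muscle_profiles <- muscle_profiles[emg_channels()]
  for (ch in emg_channels()) {
    prof <- muscle_profiles[[ch]]
    if (is.null(prof) || nrow(prof) == 0)
      stopf("channel %s has an empty burst list", ch,
            class = "gaitphase_invalid_parameter")
    if (any(prof$center < 0 | prof$center >= 1))
      stopf("burst centers for %s must lie in [0, 1)", ch,
            class = "gaitphase_invalid_parameter")
    if (any(prof$width <= 0))
      stopf("burst widths for %s must be positive", ch,
            class = "gaitphase_invalid_parameter")
  }
  if (length(carrier_band) != 2 || carrier_band[1] <= 0 ||
      carrier_band[2] <= carrier_band[1] ||
      carrier_band[2] >= sampling_rate / 2)
    stopf("`carrier_band` must be 0 < low < high < sampling_rate/2",
          class = "gaitphase_invalid_parameter")
  structure(
    list(duration_s = duration_s, sampling_rate = sampling_rate,
         stride_mean_ms = stride_mean_ms, stride_sd_ms = stride_sd_ms,
         stance_fraction_mean = stance_fraction_mean,
         stance_fraction_sd = stance_fraction_sd,
         muscle_profiles = muscle_profiles,
         carrier_band = as.numeric(carrier_band),
         noise_floor = noise_floor, seed = as.integer(seed)),
    class = "gait_sim_params")
}

#' @export
print.gait_sim_params <- function(x, ...) {
  cat(sprintf(
    "<gait_sim_params> %.0f s @ %g Hz | stride %g +/- %g ms | stance %.2f +/- %.2f | seed %d\n",
    x$duration_s, x$sampling_rate, x$stride_mean_ms, x$stride_sd_ms,
    x$stance_fraction_mean, x$stance_fraction_sd, x$seed))
  invisible(x)
}

# draw from N(mean, sd) truncated at lo/hi by redrawing
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

# Build one leg's foot-floor-contact signal and per-sample cycle phase.
# start_frac shifts the first stride (0.5 for the contralateral leg).
# Consumes the current RNG stream.
build_leg_timeline <- function(n_samples, params, start_frac = 0) {
  fs <- params$sampling_rate
  baso <- integer(n_samples)
  phase <- numeric(n_samples)
  t <- 0L
  p0 <- start_frac
  while (t < n_samples) {
    L_ms <- rnorm_trunc(1, params$stride_mean_ms, params$stride_sd_ms,
                        params$stride_mean_ms - 3 * params$stride_sd_ms,
                        params$stride_mean_ms + 3 * params$stride_sd_ms)
    L <- max(2L, as.integer(round(L_ms / 1000 * fs)))
    f <- rnorm_trunc(1, params$stance_fraction_mean,
                     params$stance_fraction_sd, 0.45, 0.75)
    stance_n <- as.integer(round(L * f))
    skip <- as.integer(round(p0 * L))
    vis <- L - skip
    if (vis <= 0) { p0 <- 0; next }
    seg <- c(integer(max(0L, stance_n - skip)),
             rep(1L, vis - max(0L, stance_n - skip)))
    seg_phase <- (skip + seq_len(vis) - 1) / L
    take <- min(vis, n_samples - t)
    idx <- t + seq_len(take)
    baso[idx] <- seg[seq_len(take)]
    phase[idx] <- seg_phase[seq_len(take)]
    if (take < vis) {
      # truncated final stride: a partial trailing swing becomes stance so
      # the record ends on the ground
      if (baso[n_samples] == 1L) {
        run_start <- n_samples
        while (run_start > 1 && baso[run_start - 1] == 1L) run_start <- run_start - 1
        baso[run_start:n_samples] <- 0L
      }
    }
    t <- t + take
    p0 <- 0
  }
  list(baso = baso, phase = phase)
}

#' Simulate a foot-floor-contact timeline and its ground-truth events
#'
#' Draws stride durations and per-stride stance fractions (both from
#' truncated normal laws), lays down alternating stance (0) and swing (1)
#' runs, and reads heel-strikes (1 to 0) and toe-offs (0 to 1) off the
#' realized signal. The record starts and ends in stance; a final partial
#' stride is truncated.
#'
#' @param params A [gait_sim_params()] object.
#' @param start_frac Cycle fraction at which the first stride starts
#'   (0.5 for the contralateral leg).
#' @return A list with `timeline`, a tibble of `sample` (0-based), `baso`
#'   (0 stance / 1 swing) and `phase` (cycle fraction); and `events`, a
#'   tibble of `type` ("HS"/"TO"), `sample` and `time_ms`.
#' @export
#' @examples
#' tl <- simulate_timeline(gait_sim_params(duration_s = 10, seed = 1))
#' head(tl$events)
simulate_timeline <- function(params, start_frac = 0) {
  stopifnot(inherits(params, "gait_sim_params"))
  n <- as.integer(round(params$duration_s * params$sampling_rate))
  leg <- with_seed(params$seed, build_leg_timeline(n, params, start_frac))
  list(
    timeline = tibble(sample = seq_len(n) - 1L, baso = leg$baso,
                      phase = leg$phase),
    events = detect_events(leg$baso, params$sampling_rate)
  )
}

# zero-mean, unit-SD noise band-limited by a linear-phase FIR; consumes the
# current RNG stream
band_limited_noise <- function(n, sampling_rate, band, order = 500) {
  h <- signal::fir1(order, band / (sampling_rate / 2), type = "pass")
  x <- fir_apply(rnorm(n), h)
  x / sd(x)
}

# Gaussian bursts in circular cycle-fraction coordinates, truncated at 3 sigma
burst_envelope <- function(phase, profile) {
  env <- numeric(length(phase))
  for (i in seq_len(nrow(profile))) {
    d <- abs(phase - profile$center[i])
    d <- pmin(d, 1 - d)
    ok <- d <= 3 * profile$width[i]
    env[ok] <- env[ok] +
      profile$amplitude[i] * exp(-0.5 * (d[ok] / profile$width[i])^2)
  }
  env
}

#' Simulate a full subject recording
#'
#' Generates both legs' foot-floor-contact signals (the left leg offset by
#' half a gait cycle, as in contralateral walking) and ten raw-like sEMG
#' channels. Each channel is an amplitude-modulated broadband carrier:
#' the per-sample modulation is `noise_floor` plus the channel's summed
#' activation bursts evaluated at the owning leg's cycle phase, and the
#' carrier is zero-mean noise band-limited to `carrier_band`.
#'
#' @param params A [gait_sim_params()] object.
#' @param subject_id Identifier stored with the recording.
#' @return A `subject_recording`: a tibble with columns `sample`, the ten
#'   EMG channels ([emg_channels()]), and `FSW_R`, `FSW_L` (0 stance /
#'   1 swing), with attributes `subject_id`, `sampling_rate` and
#'   `truth_events` (tibble `leg`, `type`, `sample`, `time_ms`).
#' @export
#' @examples
#' rec <- simulate_subject(gait_sim_params(duration_s = 5, seed = 1))
#' dplyr::glimpse(rec)
simulate_subject <- function(params, subject_id = "S1") {
  stopifnot(inherits(params, "gait_sim_params"))
  n <- as.integer(round(params$duration_s * params$sampling_rate))
  with_seed(params$seed, {
    right <- build_leg_timeline(n, params, start_frac = 0)
    left <- build_leg_timeline(n, params, start_frac = 0.5)
    chans <- lapply(emg_channels(), function(ch) {
      leg <- if (startsWith(ch, "R_")) right else left
      env <- burst_envelope(leg$phase, params$muscle_profiles[[ch]])
      carrier <- band_limited_noise(n, params$sampling_rate,
                                    params$carrier_band)
      (params$noise_floor + env) * carrier
    })
    names(chans) <- emg_channels()
    rec <- tibble(sample = seq_len(n) - 1L, !!!chans,
                  FSW_R = right$baso, FSW_L = left$baso)
    ev_r <- detect_events(right$baso, params$sampling_rate)
    ev_l <- detect_events(left$baso, params$sampling_rate)
    truth <- dplyr::bind_rows(
      dplyr::mutate(ev_r, leg = "R", .before = 1),
      dplyr::mutate(ev_l, leg = "L", .before = 1))
    new_subject_recording(rec, subject_id = subject_id,
                          sampling_rate = params$sampling_rate,
                          truth_events = truth)
  })
}

new_subject_recording <- function(data, subject_id, sampling_rate,
                                  truth_events = NULL) {
  structure(data,
            class = c("subject_recording", class(tibble())),
            subject_id = subject_id,
            sampling_rate = sampling_rate,
            truth_events = truth_events)
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf("<subject_recording> %s | %d samples @ %g Hz | %d truth events\n",
              attr(x, "subject_id"), nrow(x), attr(x, "sampling_rate"),
              if (is.null(attr(x, "truth_events"))) 0L
              else nrow(attr(x, "truth_events"))))
  NextMethod()
}

# jitter one subject's parameters; magnitude scales with heterogeneity
jitter_params <- function(base, heterogeneity, subject_seed) {
  with_seed(subject_seed, {
    prof <- lapply(base$muscle_profiles, function(p) {
      dplyr::mutate(p,
        center = (.data$center + rnorm(dplyr::n(), 0, 0.05 * heterogeneity)) %% 1,
        amplitude = .data$amplitude *
          exp(rnorm(dplyr::n(), 0, 0.2 * heterogeneity)))
    })
    gait_sim_params(
      duration_s = base$duration_s,
      sampling_rate = base$sampling_rate,
      stride_mean_ms = base$stride_mean_ms *
        exp(rnorm(1, 0, 0.08 * heterogeneity)),
      stride_sd_ms = base$stride_sd_ms,
      stance_fraction_mean = min(0.72, max(0.48,
        base$stance_fraction_mean + rnorm(1, 0, 0.03 * heterogeneity))),
      stance_fraction_sd = base$stance_fraction_sd,
      muscle_profiles = prof,
      carrier_band = base$carrier_band,
      noise_floor = base$noise_floor,
      seed = subject_seed)
  })
}

#' Simulate a population of subjects
#'
#' Each subject receives jittered stride statistics, burst centers and burst
#' amplitudes; the jitter magnitude scales with `heterogeneity`, so
#' inter-subject variability exceeds intra-subject variability whenever
#' `heterogeneity > 0`. With `heterogeneity = 0` all subjects share the base
#' parameters and differ only through their noise seeds.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param base A [gait_sim_params()] object used as population mean.
#' @param heterogeneity Non-negative scale of between-subject jitter.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return List of `subject_recording` objects named `S1..Sn`.
#' @export
#' @examples
#' pop <- simulate_population(2, gait_sim_params(duration_s = 5), seed = 7)
simulate_population <- function(n_subjects, base = gait_sim_params(),
                                heterogeneity = 0, seed = base$seed) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 || n_subjects < 1)
    stopf("`n_subjects` must be >= 1", class = "gaitphase_invalid_parameter")
  if (heterogeneity < 0)
    stopf("`heterogeneity` must be >= 0",
          class = "gaitphase_invalid_parameter")
  n_subjects <- as.integer(n_subjects)
  subject_seeds <- as.integer(seed) + 1000L * seq_len(n_subjects)
  out <- lapply(seq_len(n_subjects), function(i) {
    p <- if (heterogeneity > 0)
      jitter_params(base, heterogeneity, subject_seeds[i])
    else {
      p0 <- base; p0$seed <- subject_seeds[i]; p0
    }
    simulate_subject(p, subject_id = paste0("S", i))
  })
  names(out) <- paste0("S", seq_len(n_subjects))
  out
}
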