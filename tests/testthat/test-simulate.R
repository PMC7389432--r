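test_that("zero-variance parameters give exact, regular strides", {
  p <- gait_sim_params(duration_s = 10, stride_mean_ms = 1000,
                       stride_sd_ms = 0, stance_fraction_sd = 0, seed = 1)
  tl <- simulate_timeline(p)
  r <- rle(tl$timeline$baso)
  expect_equal(sum(r$lengths), 20000)
  expect_equal(r$values, rep(c(0L, 1L), 10))
  expect_equal(r$lengths, rep(c(1200L, 800L), 10))
  # 9 interior HS (stride boundaries) + 10 TO
  expect_equal(sum(tl$events$type == "HS"), 9)
  expect_equal(sum(tl$events$type == "TO"), 10)
})

test_that("default 300-s walk has plausible stride count and stance fraction", {
  tl <- simulate_timeline(gait_sim_params(seed = 1))
  n_strides <- sum(tl$events$type == "HS") + 1
  expect_gte(n_strides, 240)
  expect_lte(n_strides, 310)
  stance_frac <- mean(tl$timeline$baso == 0)
  expect_lt(abs(stance_frac - 0.60), 0.02)
})

test_that("timeline generation is deterministic under a fixed seed", {
  p <- gait_sim_params(duration_s = 8, seed = 42)
  a <- simulate_timeline(p)
  b <- simulate_timeline(p)
  expect_identical(a$timeline$baso, b$timeline$baso)
  expect_identical(a$events, b$events)
})

test_that("run-length decoding of the basographic signal reproduces truth events", {
  rec <- small_subject()
  for (leg in c("L", "R")) {
    truth <- truth_events_leg(rec, leg)
    dec <- oracle_events_from_runs(rec[[paste0("FSW_", leg)]], 2000)
    expect_equal(truth$type, dec$type)
    expect_equal(truth$sample, dec$sample)
  }
})

test_that("recordings start in stance and carry 10 equal-length channels", {
  rec <- small_subject()
  expect_equal(rec$FSW_R[1], 0L)
  expect_equal(rec$FSW_L[1], 0L)
  expect_equal(rec$FSW_R[nrow(rec)], 0L)
  expect_true(all(emg_channels() %in% names(rec)))
  expect_equal(nrow(rec), 30 * 2000)
  expect_true(all(rec$FSW_L %in% 0:1))
})

test_that("zero-amplitude profiles leave only the scaled carrier", {
  prof <- default_muscle_profiles()
  prof <- lapply(prof, function(p) dplyr::mutate(p, amplitude = 0))
  p <- gait_sim_params(duration_s = 4, muscle_profiles = prof,
                       noise_floor = 0.05, seed = 3)
  rec <- simulate_subject(p)
  for (ch in emg_channels()) {
    expect_lt(abs(sd(rec[[ch]]) - 0.05), 0.05 * 0.2)
    expect_lt(abs(mean(rec[[ch]])), 0.01)
  }
  # and with a zero noise floor on top, the signal vanishes entirely
  p0 <- gait_sim_params(duration_s = 2, muscle_profiles = prof,
                        noise_floor = 0, seed = 3)
  rec0 <- simulate_subject(p0)
  expect_true(all(rec0$R_TA == 0))
})

test_that("a swing-centered burst concentrates energy in swing", {
  prof <- default_muscle_profiles()
  prof <- lapply(prof, function(p) dplyr::mutate(p, amplitude = 0))
  prof$R_TA <- tibble::tibble(center = 0.8, width = 0.06, amplitude = 1)
  p <- gait_sim_params(duration_s = 30, muscle_profiles = prof,
                       noise_floor = 0, seed = 1)
  rec <- simulate_subject(p)
  x <- abs(rec$R_TA)
  ev <- truth_events_leg(rec, "R")
  hs <- ev$sample[ev$type == "HS"]
  ok <- 0; n <- 0
  for (i in seq_len(length(hs) - 1)) {
    stride <- (hs[i] + 1):hs[i + 1]
    ph <- rec$FSW_R[stride]
    stance_e <- mean(x[stride[ph == 0]])
    swing_e <- mean(x[stride[ph == 1]])
    n <- n + 1
    if (swing_e > stance_e) ok <- ok + 1
  }
  expect_gte(ok / n, 0.95)
})

test_that("carrier power stays inside the configured band", {
  prof <- default_muscle_profiles()
  prof <- lapply(prof, function(p) dplyr::mutate(p, amplitude = 0))
  p <- gait_sim_params(duration_s = 10, muscle_profiles = prof,
                       noise_floor = 1, seed = 5)
  rec <- simulate_subject(p)
  x <- rec$R_TA
  spec <- Mod(stats::fft(x))^2
  freqs <- (seq_along(x) - 1) / length(x) * 2000
  half <- freqs <= 1000
  inside <- half & freqs >= 20 & freqs <= 450
  expect_lt(1 - sum(spec[inside]) / sum(spec[half]), 0.05)
})

test_that("parameter validation rejects impossible settings", {
  expect_error(gait_sim_params(duration_s = -1),
               class = "gaitphase_invalid_parameter")
  expect_error(gait_sim_params(sampling_rate = 0),
               class = "gaitphase_invalid_parameter")
  expect_error(gait_sim_params(stance_fraction_mean = 1.2),
               class = "gaitphase_invalid_parameter")
  prof <- default_muscle_profiles()
  prof$R_TA <- prof$R_TA[0, ]
  expect_error(gait_sim_params(muscle_profiles = prof),
               class = "gaitphase_invalid_parameter")
})

test_that("population generation jitters subjects with heterogeneity", {
  base <- gait_sim_params(duration_s = 3)
  expect_error(simulate_population(0, base),
               class = "gaitphase_invalid_parameter")

  hom <- simulate_population(2, base, heterogeneity = 0, seed = 7)
  expect_length(hom, 2)
  # same stride statistics, different noise realizations
  expect_identical(attr(hom$S1, "sampling_rate"),
                   attr(hom$S2, "sampling_rate"))
  expect_false(identical(hom$S1$R_TA, hom$S2$R_TA))

  het <- simulate_population(5, base, heterogeneity = 0.3, seed = 7)
  expect_length(het, 5)
  frac <- vapply(het, function(r) mean(r$FSW_L == 0), 0)
  expect_gt(max(frac) - min(frac), 0)  # stance fractions actually differ
})
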