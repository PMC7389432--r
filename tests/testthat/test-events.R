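test_that("label expansion rebuilds the foot-floor-contact signal", {
  out <- reconstruct_basographic(c(0, 0, 1, 1), window_len = 20)
  expect_identical(out, c(rep(0L, 40), rep(1L, 40)))
  expect_error(reconstruct_basographic(integer(0)),
               class = "gaitphase_validation_error")
  expect_error(reconstruct_basographic(c(0, NA, 1)),
               class = "gaitphase_validation_error")
  expect_length(reconstruct_basographic(rep(1, 7), 20), 140)
})

test_that("short phases are absorbed into their neighbours", {
  x <- rep(c(0L, 1L, 0L), c(500, 300, 700))
  r <- remove_short_phases(x, 2000)
  expect_identical(r$signal, rep(0L, 1500))
  expect_equal(nrow(r$spikes), 1)
  expect_equal(r$spikes$length, 300)
  expect_equal(r$spikes$duration_ms, 150)

  # exactly 175 ms (350 samples) survives the strict "less than" rule
  x2 <- rep(c(0L, 1L, 0L), c(500, 350, 700))
  r2 <- remove_short_phases(x2, 2000)
  expect_identical(r2$signal, x2)
  expect_equal(nrow(r2$spikes), 0)

  # fixed point: a clean signal is untouched
  x3 <- rep(c(0L, 1L, 0L, 1L), c(900, 600, 1000, 700))
  expect_identical(remove_short_phases(x3, 2000)$signal, x3)
  expect_identical(
    remove_short_phases(remove_short_phases(x, 2000)$signal, 2000)$signal,
    r$signal)
})

test_that("a violating first run takes the following phase's value", {
  x <- rep(c(1L, 0L), c(100, 800))
  r <- remove_short_phases(x, 2000)
  expect_identical(r$signal, rep(0L, 900))
})

test_that("cleaning agrees with the delete-shortest-run oracle", {
  set.seed(7)
  for (i in 1:60) {
    x <- random_runs_signal(sample(500:5000, 1))
    got <- remove_short_phases(x, 2000)$signal
    want <- oracle_remove_short(x, 350)
    expect_identical(got, want)
    runs <- rle(got)$lengths
    if (length(runs) > 1) expect_true(all(runs >= 350))
  }
})

test_that("transitions become HS and TO events at the new phase's first sample", {
  ev <- detect_events(rep(c(1L, 0L, 1L), c(400, 800, 400)), 2000)
  expect_equal(ev$type, c("HS", "TO"))
  expect_equal(ev$sample, c(400L, 1200L))
  expect_equal(ev$time_ms, c(200, 600))
  expect_equal(nrow(detect_events(rep(0L, 1000), 2000)), 0)
  # alternation on any cleaned signal
  x <- remove_short_phases(random_runs_signal(4000), 2000)$signal
  types <- detect_events(x, 2000)$type
  if (length(types) > 1)
    expect_true(all(types[-1] != types[-length(types)]))
})

test_that("events of window-aligned ground truth are recovered exactly", {
  p <- gait_sim_params(duration_s = 20, stride_mean_ms = 1000,
                       stride_sd_ms = 0, stance_fraction_sd = 0, seed = 2)
  rec <- simulate_subject(p)
  env <- preprocess_recording(rec)
  ds <- window_dataset(env, target_leg = "R")
  expect_equal(sum(ds$masked), 0)  # transitions fall on window boundaries
  ev <- detect_events(reconstruct_basographic(ds$label, 20), 2000)
  truth <- truth_events_leg(rec, "R")
  expect_equal(ev$type, truth$type)
  expect_equal(ev$sample, truth$sample)
})

test_that("tolerance matching pairs events one-to-one, strictly within T", {
  pred <- tibble::tibble(type = "HS", time_ms = c(1000, 2200))
  truth <- tibble::tibble(type = "HS", time_ms = c(1010, 2190, 3000))
  m <- match_events(pred, truth, tolerance_ms = 600)
  expect_equal(nrow(m$HS$pairs), 2)
  expect_length(m$HS$fp_ms, 0)
  expect_length(m$HS$fn_ms, 1)

  far <- match_events(tibble::tibble(type = "HS", time_ms = 1700),
                      tibble::tibble(type = "HS", time_ms = 1000), 600)
  expect_equal(nrow(far$HS$pairs), 0)
  expect_length(far$HS$fp_ms, 1)
  expect_length(far$HS$fn_ms, 1)

  # |t_g - t_p| == T exactly is not a pair
  edge <- match_events(tibble::tibble(type = "TO", time_ms = 1600),
                       tibble::tibble(type = "TO", time_ms = 1000), 600)
  expect_equal(nrow(edge$TO$pairs), 0)
})

test_that("greedy matching attains the optimal pair count on gait-like instances", {
  # events of one type are ~1 stride apart and prediction errors are tens
  # of ms, so greedy and exhaustive optimal matching agree on pair counts
  set.seed(21)
  for (i in 1:40) {
    inst <- random_gait_match_instance(max_events = 6)
    m <- match_events(tibble::tibble(type = "HS", time_ms = inst$pred),
                      tibble::tibble(type = "HS", time_ms = inst$truth),
                      600)
    opt <- oracle_match_optimal(inst$pred, inst$truth, 600)
    expect_equal(nrow(m$HS$pairs), opt$n_pairs)
  }
})

test_that("precision, recall, F1 and MAE follow their definitions", {
  mk <- function(tp, fp, fn, err = 10) {
    # construct well-separated events giving exactly tp/fp/fn
    truth_m <- seq_len(tp) * 3000
    pred <- c(truth_m + err, seq_len(fp) * 3000 + 100000)
    truth <- c(truth_m, seq_len(fn) * 3000 + 200000)
    match_events(tibble::tibble(type = "HS", time_ms = pred),
                 tibble::tibble(type = "HS", time_ms = truth), 600)
  }
  s <- score_events(mk(9, 1, 3))[1, ]
  expect_equal(s$precision, 0.9)
  expect_equal(s$recall, 0.75)
  expect_equal(s$f1, 2 * 0.9 * 0.75 / (0.9 + 0.75))
  expect_equal(s$mae_ms, 10)

  perfect <- score_events(mk(5, 0, 0, err = 0))[1, ]
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$mae_ms, 0)

  empty <- score_events(mk(0, 0, 4))[1, ]
  expect_true(is.na(empty$precision))  # TP+FP = 0: undefined, not zero
  expect_equal(empty$recall, 0)
  expect_true(is.na(empty$mae_ms))
})

test_that("evaluate_events chains reconstruction, cleaning and scoring", {
  p <- gait_sim_params(duration_s = 20, stride_mean_ms = 1000,
                       stride_sd_ms = 0, stance_fraction_sd = 0, seed = 2)
  rec <- simulate_subject(p)
  ds <- window_dataset(preprocess_recording(rec), target_leg = "R")
  labels <- ds$label
  labels[30] <- 1L - labels[30]  # inject one 10-ms spike in mid-stance
  res <- evaluate_events(labels, truth_events_leg(rec, "R"), 2000)
  expect_gte(nrow(res$spikes), 1)
  expect_true(all(res$scores$precision == 1))
  expect_true(all(res$scores$recall == 1))
  expect_true(all(res$scores$mae_ms == 0))
})
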