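# small config used throughout: tiny net, few epochs — structure is under
# test here, not asymptotic accuracy
proto_cfg <- function(seed = 1)
  mlp_config(hidden_sizes = c(32, 16), max_epochs = 6, patience = 3,
             seed = seed)

intra_report <- function() {
  fixture("intra_report", function()
    run_intra_subject(small_subject(), proto_cfg()))
}

test_that("the intra-subject protocol produces ten coherent folds", {
  rep <- intra_report()
  expect_equal(nrow(rep$folds), 10)
  expect_equal(sum(rep$folds$n_test), rep$n_windows)
  expect_equal(rep$test_accuracy, mean(rep$folds$test_accuracy))
  expect_equal(rep$test_accuracy_sd, sd(rep$folds$test_accuracy))
  expect_true(all(rep$folds$epochs_run <= 6))
  expect_true(all(c("HS", "TO") %in% rep$event_scores$type))
})

test_that("no test window leaks into training or validation in any fold", {
  rep <- intra_report()
  all_test <- integer(0)
  for (fi in rep$fold_indices) {
    expect_length(intersect(fi$train, fi$test), 0)
    expect_length(intersect(fi$val, fi$test), 0)
    expect_true(all(fi$val %in% fi$train))  # val is the tail of training
    all_test <- c(all_test, fi$test)
  }
  # across folds the test slots tile the whole record
  expect_identical(sort(all_test), seq_len(rep$n_windows))
})

test_that("perfectly separable envelopes yield accuracy 1 in every fold", {
  # stance windows sit at envelope 0.1, swing windows at 0.9: no noise, no
  # overlap, so each fold must classify its held-out slot perfectly
  n <- 600
  lab <- rep(rep(c(0L, 1L), times = 15), length.out = n)
  X <- matrix(0.1 + 0.8 * lab, n, 200)
  ds <- tibble::tibble(start = as.integer((seq_len(n) - 1) * 20),
                       label = lab, masked = FALSE, vector = X)
  slots <- split_slots(n, k = 10)
  accs <- vapply(seq_len(10), function(i) {
    test_idx <- seq(slots$from[i], slots$to[i])
    fit <- fit_mlp(ds[-test_idx, ],
                   mlp_config(hidden_sizes = c(32, 16), max_epochs = 50,
                              patience = 10, seed = i))
    mean(predict(fit, ds[test_idx, ])$label == ds$label[test_idx])
  }, 0)
  expect_equal(accs, rep(1, 10))
})

test_that("degenerate single-class folds are skipped with a warning", {
  rec <- small_subject()
  # constant swing-free basographic on the left leg forces degeneracy
  rec$FSW_L <- rep(0L, nrow(rec))
  attr(rec, "truth_events") <-
    attr(rec, "truth_events")[attr(rec, "truth_events")$leg == "R", ]
  w <- capture_warnings(out <- run_intra_subject(rec, proto_cfg(), k = 10))
  expect_true(any(grepl("skipped", w)))
  expect_equal(nrow(out$folds), 0)
  expect_true(is.na(out$test_accuracy))
})

test_that("leave-one-subject-out runs one fold per subject without leakage", {
  pop <- simulate_population(3, gait_sim_params(duration_s = 20),
                             heterogeneity = 0, seed = 5)
  study <- run_inter_subject(pop, proto_cfg())
  expect_s3_class(study, "gait_study")
  expect_equal(study$protocol, "inter")
  expect_equal(nrow(study$subjects), 3)
  expect_equal(study$subjects$subject, c("S1", "S2", "S3"))
  for (d in study$details)
    expect_false(d$test_subject %in% d$train_subjects)
  expect_error(run_inter_subject(pop[1], proto_cfg()),
               class = "gaitphase_validation_error")
})

test_that("homogeneous subjects score similarly under both protocols", {
  pop <- simulate_population(3, gait_sim_params(duration_s = 20),
                             heterogeneity = 0, seed = 5)
  inter <- run_inter_subject(pop, proto_cfg())
  intra <- run_intra_subject(pop$S1, proto_cfg())
  # same generating process: unseen-subject accuracy tracks within-subject
  # (band reflects per-fold accuracy SD of a few percent on 20-s records)
  expect_lt(abs(mean(inter$subjects$test_accuracy) - intra$test_accuracy),
            0.10)
})

test_that("study aggregation equals recomputation from per-subject values", {
  pop <- simulate_population(3, gait_sim_params(duration_s = 20),
                             heterogeneity = 0, seed = 5)
  study <- run_inter_subject(pop, proto_cfg())
  g <- glance(study)
  expect_equal(g$test_accuracy_mean, mean(study$subjects$test_accuracy))
  expect_equal(g$test_accuracy_sd, sd(study$subjects$test_accuracy))
  expect_equal(g$hs_mae_ms_mean, mean(study$subjects$hs_mae_ms))
  td <- tidy(study)
  expect_equal(nrow(td), 3)
})

test_that("the statistical comparison gates on Shapiro-Wilk normality", {
  set.seed(31)
  a <- rnorm(23, 10, 1)
  b <- rnorm(23, 20, 1)
  r <- compare_approaches(a, b, metric = "separated-normals")
  expect_equal(r$test, "t-test")
  expect_true(r$significant)
  expect_lt(r$p_value, 0.05)

  same <- compare_approaches(a, a)
  expect_false(same$significant)

  skew_a <- rexp(23, 0.2)^3
  skew_b <- rexp(23, 0.2)^3
  r2 <- compare_approaches(skew_a, skew_b)
  expect_equal(r2$test, "kruskal-wallis")

  expect_warning(r3 <- compare_approaches(rep(1, 10), rnorm(10)),
                 "constant")
  expect_equal(r3$test, "kruskal-wallis")

  expect_error(compare_approaches(1:2, 1:5),
               class = "gaitphase_validation_error")
})
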