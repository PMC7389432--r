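fold_seed <- function(master, fold) as.integer(master) + 97L * as.integer(fold)

pool_event_scores <- function(matches) {
  purrr::map_dfr(c("HS", "TO"), function(ty) {
    tp <- sum(vapply(matches, function(m) nrow(m[[ty]]$pairs), 0L))
    fp <- sum(vapply(matches, function(m) length(m[[ty]]$fp_ms), 0L))
    fn <- sum(vapply(matches, function(m) length(m[[ty]]$fn_ms), 0L))
    errs <- unlist(lapply(matches, function(m) m[[ty]]$pairs$error_ms))
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    tibble(type = ty, tp = tp, fp = fp, fn = fn, precision = precision,
           recall = recall, f1 = f1,
           mae_ms = if (length(errs)) mean(errs) else NA_real_)
  })
}

# truth events whose sample index falls inside [lo, hi) (0-based samples)
truth_in_span <- function(truth, lo, hi) {
  truth[truth$sample >= lo & truth$sample < hi, , drop = FALSE]
}

#' Intra-subject 10-fold evaluation of one recording
#'
#' Splits the subject's chronological window sequence into `k` contiguous
#' slots; each fold trains on the other `k - 1` slots (validation = the
#' chronological tail of that training sequence) and tests on the held-out
#' slot. Classification accuracy is averaged over folds; gait events from
#' every fold's test slot are pooled and scored against the ground-truth
#' events falling in that slot.
#'
#' @param rec A `subject_recording` with ground-truth events.
#' @param cfg An [mlp_config()]; per-fold seeds are derived from its seed.
#' @param target_leg Leg whose foot-floor-contact signal is predicted.
#' @param k Number of slots/folds.
#' @param window_len Window length in samples.
#' @param tolerance_ms Event-matching tolerance T in ms.
#' @param min_duration_ms Minimum phase duration for spike removal, ms.
#' @return A `gait_subject_report`: list with `folds` (per-fold tibble),
#'   `event_scores` (pooled HS/TO metrics), `fold_indices` (train/val/test
#'   window indices per fold, for audit), and summary fields.
#' @export
run_intra_subject <- function(rec, cfg = mlp_config(), target_leg = "L",
                              k = 10, window_len = 20, tolerance_ms = 600,
                              min_duration_ms = 175) {
  stopifnot(inherits(rec, "subject_recording"))
  fs <- attr(rec, "sampling_rate")
  env <- preprocess_recording(rec)
  ds <- window_dataset(env, target_leg, window_len)
  slots <- split_slots(nrow(ds), k)
  truth <- attr(rec, "truth_events")
  truth <- truth[truth$leg == target_leg, , drop = FALSE]

  folds <- vector("list", k)
  matches <- list()
  fold_indices <- vector("list", k)
  for (i in seq_len(k)) {
    test_idx <- seq(slots$from[i], slots$to[i])
    train_idx <- setdiff(seq_len(nrow(ds)), test_idx)
    stopifnot(length(intersect(train_idx, test_idx)) == 0)
    cfg_i <- cfg
    cfg_i$seed <- fold_seed(cfg$seed, i)
    fit <- tryCatch(fit_mlp(ds[train_idx, ], cfg_i),
                    gaitphase_degenerate_training = function(e) {
                      warn(sprintf("fold %d skipped: %s", i,
                                   conditionMessage(e)))
                      NULL
                    })
    if (is.null(fit)) next
    tr_unmasked <- train_idx[!ds$masked[train_idx]]
    tr_pred <- predict(fit, ds[tr_unmasked, ])
    test_pred <- predict(fit, ds[test_idx, ])
    test_acc <- classification_accuracy(test_pred$label,
                                        ds$label[test_idx],
                                        ds$masked[test_idx])
    lo <- ds$start[test_idx[1]]
    hi <- ds$start[test_idx[length(test_idx)]] + window_len
    ev <- evaluate_events(test_pred$label,
                          truth_in_span(truth, lo, hi), fs,
                          window_len = window_len,
                          offset_ms = lo / fs * 1000,
                          tolerance_ms = tolerance_ms,
                          min_duration_ms = min_duration_ms)
    matches[[length(matches) + 1]] <- ev$match
    folds[[i]] <- tibble(
      fold = i,
      n_train = fit$n_train, n_val = fit$n_val,
      n_test = length(test_idx),
      train_accuracy = mean(tr_pred$label == ds$label[tr_unmasked]),
      test_accuracy = test_acc,
      best_epoch = fit$best_epoch, epochs_run = fit$epochs_run,
      best_val_accuracy = fit$best_val_accuracy,
      spikes_removed = nrow(ev$spikes))
    # validation rows are the chronological tail of the (unmasked)
    # training sequence
    fold_indices[[i]] <- list(
      train = train_idx,
      val = tail(tr_unmasked, fit$n_val),
      test = test_idx)
  }
  folds <- dplyr::bind_rows(folds)
  ran <- nrow(folds) > 0
  structure(
    list(subject_id = attr(rec, "subject_id"), protocol = "intra",
         target_leg = target_leg, folds = folds,
         event_scores = pool_event_scores(matches),
         fold_indices = fold_indices,
         n_windows = nrow(ds),
         train_accuracy = if (ran) mean(folds$train_accuracy) else NA_real_,
         test_accuracy = if (ran) mean(folds$test_accuracy) else NA_real_,
         test_accuracy_sd = if (ran) sd(folds$test_accuracy) else NA_real_),
    class = "gait_subject_report")
}

#' @export
print.gait_subject_report <- function(x, ...) {
  cat(sprintf(
    "<gait_subject_report> %s (intra, leg %s): test accuracy %.4f +/- %.4f over %d folds\n",
    x$subject_id, x$target_leg, x$test_accuracy, x$test_accuracy_sd,
    nrow(x$folds)))
  print(x$event_scores)
  invisible(x)
}

subject_row <- function(subject_id, train_acc, test_acc, scores) {
  hs <- scores[scores$type == "HS", ]
  to <- scores[scores$type == "TO", ]
  tibble(subject = subject_id,
         train_accuracy = train_acc, test_accuracy = test_acc,
         hs_precision = hs$precision, hs_recall = hs$recall,
         hs_f1 = hs$f1, hs_mae_ms = hs$mae_ms,
         to_precision = to$precision, to_recall = to$recall,
         to_f1 = to$f1, to_mae_ms = to$mae_ms)
}

new_gait_study <- function(subjects, protocol, details) {
  structure(list(subjects = subjects, protocol = protocol,
                 details = details),
            class = "gait_study")
}

#' Intra-subject study over a population
#'
#' Runs [run_intra_subject()] on every recording and assembles the
#' per-subject fold-averaged results into a study report.
#'
#' @param recs List of `subject_recording` objects.
#' @inheritParams run_intra_subject
#' @return A `gait_study` (protocol `"intra"`); see [tidy.gait_study()].
#' @export
run_intra_study <- function(recs, cfg = mlp_config(), target_leg = "L",
                            k = 10, window_len = 20, tolerance_ms = 600,
                            min_duration_ms = 175) {
  reports <- lapply(recs, run_intra_subject, cfg = cfg,
                    target_leg = target_leg, k = k,
                    window_len = window_len, tolerance_ms = tolerance_ms,
                    min_duration_ms = min_duration_ms)
  subjects <- purrr::map_dfr(reports, function(r)
    subject_row(r$subject_id, r$train_accuracy, r$test_accuracy,
                r$event_scores))
  new_gait_study(subjects, "intra", reports)
}

#' Inter-subject leave-one-subject-out study
#'
#' Each fold trains one classifier on the concatenated window sequences of
#' all subjects but one (validation = the chronological tail of that
#' concatenation) and tests on the whole left-out subject: accuracy over
#' its unmasked windows, plus HS/TO event scores over its full record.
#'
#' @param recs List of at least two `subject_recording` objects.
#' @inheritParams run_intra_subject
#' @return A `gait_study` (protocol `"inter"`) with one row per left-out
#'   subject; `details` keeps per-fold fits and window-index audits.
#' @export
run_inter_subject <- function(recs, cfg = mlp_config(), target_leg = "L",
                              window_len = 20, tolerance_ms = 600,
                              min_duration_ms = 175) {
  if (length(recs) < 2)
    stopf("the leave-one-subject-out protocol needs at least 2 subjects",
          class = "gaitphase_validation_error")
  dss <- lapply(recs, function(r)
    window_dataset(preprocess_recording(r), target_leg, window_len))
  n_sub <- length(recs)
  rows <- vector("list", n_sub)
  details <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    train_ds <- dplyr::bind_rows(lapply(dss[-i], function(d)
      tibble(start = d$start, label = d$label, masked = d$masked,
             vector = d$vector)))
    cfg_i <- cfg
    cfg_i$seed <- fold_seed(cfg$seed, i)
    fit <- fit_mlp(train_ds, cfg_i)
    ds_test <- dss[[i]]
    fs <- attr(ds_test, "sampling_rate")
    pred <- predict(fit, ds_test)
    test_acc <- classification_accuracy(pred$label, ds_test$label,
                                        ds_test$masked)
    tr_unmasked <- !train_ds$masked
    train_acc <- mean(predict(fit, train_ds[tr_unmasked, ])$label ==
                        train_ds$label[tr_unmasked])
    truth <- attr(recs[[i]], "truth_events")
    truth <- truth[truth$leg == target_leg, , drop = FALSE]
    ev <- evaluate_events(pred$label, truth, fs, window_len = window_len,
                          tolerance_ms = tolerance_ms,
                          min_duration_ms = min_duration_ms)
    sid <- attr(recs[[i]], "subject_id")
    rows[[i]] <- subject_row(sid, train_acc, test_acc, ev$scores)
    details[[i]] <- list(subject_id = sid, fit_glance = glance(fit),
                         test_subject = i,
                         train_subjects = setdiff(seq_len(n_sub), i),
                         scores = ev$scores, spikes = nrow(ev$spikes))
  }
  new_gait_study(dplyr::bind_rows(rows), "inter", details)
}

#' @export
print.gait_study <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<gait_study> %s-subject | %d subjects | test accuracy %.4f +/- %.4f | HS MAE %.1f ms | TO MAE %.1f ms\n",
    x$protocol, nrow(x$subjects), g$test_accuracy_mean,
    g$test_accuracy_sd, g$hs_mae_ms_mean, g$to_mae_ms_mean))
  invisible(x)
}

#' Per-subject results of a gait study
#'
#' @param x A `gait_study`.
#' @param ... Unused.
#' @return Tibble with one row per subject: train/test accuracy and HS/TO
#'   precision, recall, F1 and MAE.
#' @export
tidy.gait_study <- function(x, ...) x$subjects

#' Population summary of a gait study (mean and SD per metric)
#'
#' @param x A `gait_study`.
#' @param ... Unused.
#' @return One-row tibble: protocol, number of subjects, and mean/SD of
#'   test accuracy and of each event metric.
#' @export
glance.gait_study <- function(x, ...) {
  s <- x$subjects
  num <- s[setdiff(names(s), "subject")]
  means <- lapply(num, mean, na.rm = TRUE)
  sds <- lapply(num, sd, na.rm = TRUE)
  names(means) <- paste0(names(num), "_mean")
  names(sds) <- paste0(names(num), "_sd")
  tibble(protocol = x$protocol, n_subjects = nrow(s), !!!means, !!!sds)
}

#' Compare a metric between two approaches
#'
#' Normality of each group is assessed with the Shapiro-Wilk test; if both
#' groups are compatible with normality at the 5% level, a two-tailed
#' unpaired Student's t test is used, otherwise a Kruskal-Wallis test.
#' Constant groups (Shapiro-Wilk undefined) fall back to Kruskal-Wallis
#' with a warning. Significance is declared at p < 0.05.
#'
#' @param values_a,values_b Per-subject metric values (length >= 3 each).
#' @param metric Label stored with the result.
#' @param alpha Significance level for both the normality gate and the
#'   final test.
#' @return One-row tibble: `metric`, `shapiro_p_a`, `shapiro_p_b`, `test`
#'   ("t-test" or "kruskal-wallis"), `statistic`, `p_value`,
#'   `significant`.
#' @export
#' @examples
#' compare_approaches(rnorm(23, 10), rnorm(23, 20), metric = "demo")
compare_approaches <- function(values_a, values_b, metric = "metric",
                               alpha = 0.05) {
  if (length(values_a) < 3 || length(values_b) < 3)
    stopf("need at least 3 values per group to compare",
          class = "gaitphase_validation_error")
  sw <- function(v) tryCatch(shapiro.test(v)$p.value,
                             error = function(e) NA_real_)
  p_a <- sw(values_a)
  p_b <- sw(values_b)
  if (anyNA(c(p_a, p_b)))
    warn("Shapiro-Wilk undefined for a constant group; using Kruskal-Wallis")
  both_normal <- !anyNA(c(p_a, p_b)) && p_a >= alpha && p_b >= alpha
  if (both_normal) {
    ht <- t.test(values_a, values_b, var.equal = TRUE,
                 alternative = "two.sided", paired = FALSE)
    test <- "t-test"
  } else {
    ht <- kruskal.test(list(values_a, values_b))
    test <- "kruskal-wallis"
  }
  tibble(metric = metric, shapiro_p_a = p_a, shapiro_p_b = p_b,
         test = test, statistic = unname(ht$statistic),
         p_value = ht$p.value, significant = ht$p.value < alpha)
}
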