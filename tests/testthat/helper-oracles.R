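# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive results by naive enumeration / explicit
# vector surgery, never by calling the functions they check.

# Minimum-phase-duration cleaning: repeatedly re-encode the whole signal
# and delete the shortest violating run (leftmost on ties). Deleting an
# interior/final run hands its samples to the preceding phase; deleting
# the first run hands them to the following phase.
oracle_remove_short <- function(x, min_len) {
  x <- as.integer(x)
  repeat {
    r <- rle(x)
    if (length(r$lengths) <= 1) return(x)
    viol <- which(r$lengths < min_len)
    if (length(viol) == 0) return(x)
    i <- viol[which.min(r$lengths[viol])]
    fill <- if (i == 1) r$values[2] else r$values[i - 1]
    run_start <- sum(r$lengths[seq_len(i - 1)]) + 1
    x[run_start:(run_start + r$lengths[i] - 1)] <- fill
  }
}

# Exhaustive optimal one-to-one event matching for tiny instances:
# enumerate every injection of a subset of predictions into truths,
# maximize the number of tolerance-satisfying pairs, then minimize the
# total absolute error.
oracle_match_optimal <- function(pred_ms, truth_ms, tol_ms) {
  np <- length(pred_ms)
  nt <- length(truth_ms)
  best_pairs <- 0
  best_cost <- Inf
  if (np == 0 || nt == 0)
    return(list(n_pairs = 0, total_error = 0))
  p_subsets <- unlist(lapply(0:np, function(k)
    utils::combn(np, k, simplify = FALSE)), recursive = FALSE)
  for (ps in p_subsets) {
    k <- length(ps)
    if (k > nt || k < best_pairs) next
    t_subsets <- utils::combn(nt, k, simplify = FALSE)
    for (ts in t_subsets) {
      for (tperm in perms_of(ts)) {
        d <- abs(pred_ms[ps] - truth_ms[tperm])
        if (all(d < tol_ms)) {
          cost <- sum(d)
          if (k > best_pairs || (k == best_pairs && cost < best_cost)) {
            best_pairs <- k
            best_cost <- cost
          }
        }
      }
    }
  }
  list(n_pairs = best_pairs,
       total_error = if (is.finite(best_cost)) best_cost else 0)
}

# value-level permutations, small k only
perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_of(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# events by explicit run-length decoding (independent of detect_events)
oracle_events_from_runs <- function(x, fs) {
  r <- rle(as.integer(x))
  starts <- c(0, cumsum(r$lengths))[seq_along(r$lengths)]
  types <- character(0)
  samples <- integer(0)
  if (length(r$lengths) > 1) {
    for (i in 2:length(r$lengths)) {
      types <- c(types, if (r$values[i] == 0) "HS" else "TO")
      samples <- c(samples, starts[i])
    }
  }
  data.frame(type = types, sample = samples,
             time_ms = samples / fs * 1000)
}

# brute-force per-window labels by scanning the raw basographic samples
oracle_window_labels <- function(baso, window_len) {
  nw <- length(baso) %/% window_len
  vapply(seq_len(nw), function(w) {
    s <- baso[((w - 1) * window_len + 1):(w * window_len)]
    if (all(s == 0)) 0L else if (all(s == 1)) 1L else NA_integer_
  }, integer(1))
}

# a matching instance with stride-like spacing: same-type ground-truth
# events ~1 s apart, predictions = truth +/- tens of ms, some events
# dropped (false negatives) or spurious (false positives)
random_gait_match_instance <- function(max_events = 6) {
  nt <- sample(0:max_events, 1)
  truth <- cumsum(stats::runif(nt, 850, 1250))
  detected <- truth[stats::runif(nt) < 0.9]
  pred <- detected + pmax(-150, pmin(150, stats::rnorm(length(detected), 0, 30)))
  n_fp <- stats::rbinom(1, 2, 0.15)
  if (n_fp > 0 && nt > 0)
    pred <- c(pred, sample(truth, n_fp) + stats::runif(n_fp, 250, 350))
  pred <- utils::head(sort(pred), max_events)
  list(pred = pred, truth = truth)
}

# random gait-like binary signal: alternating runs with occasional short
# spikes, used for cleaning/matching property tests
random_runs_signal <- function(n_max = 5000) {
  x <- integer(0)
  v <- sample(0:1, 1)
  while (length(x) < n_max) {
    len <- if (stats::runif(1) < 0.3) sample(1:349, 1)
    else sample(350:1500, 1)
    x <- c(x, rep(v, len))
    v <- 1L - v
  }
  x[seq_len(n_max)]
}
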