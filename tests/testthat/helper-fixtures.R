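# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# 30-second default-parameter subject: enough for ~27 strides
small_subject <- function() {
  fixture("small_subject", function()
    simulate_subject(gait_sim_params(duration_s = 30, seed = 1), "S1"))
}

small_envelopes <- function() {
  fixture("small_envelopes", function() preprocess_recording(small_subject()))
}

small_windows <- function() {
  fixture("small_windows", function() window_dataset(small_envelopes()))
}

truth_events_leg <- function(rec, leg = "L") {
  tr <- attr(rec, "truth_events")
  tr[tr$leg == leg, , drop = FALSE]
}

# linearly separable toy window set: label 1 iff vector mean > 0.6, with a
# 0.2 margin around the boundary
toy_separable <- function(n = 2000, width = 200, seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(0:1, length.out = n)
    mu <- ifelse(lab == 1, 0.75, 0.45)
    X <- matrix(stats::runif(n * width, -0.2, 0.2), n, width) + mu
    tibble::tibble(start = as.integer((seq_len(n) - 1) * 20),
                   label = as.integer(lab),
                   masked = FALSE,
                   vector = X)
  })
}
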