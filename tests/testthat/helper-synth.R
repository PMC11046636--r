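# Small simulated sessions used across the tests.  The tracker in the
# emulated setup samples at 1000 Hz; the tests run at a 100 Hz grid so that
# window medians still rest on dozens of samples while whole cohorts stay
# cheap to simulate.

quick_config <- function(domain = "number", n_trials = 40L, coupling = 60,
                         noise_sd = 30, drift_sd = 1, seed = 1L, ...) {
  session_config(domain = domain, n_trials = n_trials,
                 sample_rate_hz = 100, coupling = coupling,
                 noise_sd = noise_sd, drift_sd = drift_sd, seed = seed, ...)
}

ring_chords <- function() {
  as.matrix(dist(make_geometry("color")$coords))
}

# brute-force Spearman via the ranked Pearson definition
spearman_oracle <- function(x, y) cor(rank(x), rank(y))

# partial rank correlation via residuals of rank regressions (independent
# of the closed-form first-order formula used by the implementation)
partial_oracle <- function(x, y, control) {
  rx <- rank(x); ry <- rank(y); rc <- rank(control)
  cor(resid(lm(rx ~ rc)), resid(lm(ry ~ rc)))
}

# gaze recording built directly from a sample table
rec_df <- function(time_ms, x, y, valid = TRUE) {
  data.frame(time_ms = time_ms, x_px = x, y_px = y, valid = valid)
}

events_df <- function(onsets, words = as.character(seq_along(onsets)),
                      block = 1L) {
  data.frame(subject = "s01", block = block, word = words,
             onset_ms = onsets, offset_ms = onsets + 200)
}
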