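# Shared fixtures. Heavy end-to-end runs are memoised per seed so the
# acceptance tests for suppression and detection reuse one computation.

.run_cache <- new.env(parent = emptyenv())

# Full default chain for one seed: synthesize -> cancel -> detect.
default_chain <- function(seed, ...) {
  key <- paste0("s", seed, "_", paste(unlist(list(...)), collapse = "_"))
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  syn <- compose_abdominal(synth_config(seed = seed, ...))
  canc <- suppressMessages(cancel_maternal(syn$record))
  fetal <- suppressMessages(detect_fetal_beats(canc))
  out <- list(syn = syn, canc = canc, fetal = fetal)
  .run_cache[[key]] <- out
  out
}

# Baseline-relative R amplitude at the exact beat sample.
amp_at_beats <- function(sig, times, fs, baseline = NULL) {
  if (is.null(baseline)) baseline <- fhrv:::baseline_trace(sig, fs)
  vapply(times, function(tau) {
    i <- as.integer(round(tau * fs)) + 1L
    abs(sig[i] - baseline[i])
  }, numeric(1))
}

# A clean single-lead maternal-only record (no noise terms).
maternal_only_record <- function(seed = 3, duration = 60) {
  compose_abdominal(synth_config(seed = seed, duration = duration,
                                 fetal_amp_ratio = 0, emg_snr_db = Inf,
                                 wander_amp = 0, artifact_rate = 0))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps),
            tol)
}
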