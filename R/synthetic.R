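#' Configuration for the synthetic abdominal-ECG generator
#'
#' Bundles every knob of the composite-signal generator with validated
#' defaults. The defaults describe a typical term pregnancy recorded from
#' abdominal electrodes: a dominant maternal ECG near 75 bpm whose QRS
#' amplitude is modulated by respiration, a fetal ECG near 135 bpm at 20%
#' of the maternal peak amplitude with its QRS energy concentrated in the
#' 10-20 Hz band, slow baseline wander, band-limited (20-150 Hz) EMG noise
#' at 15 dB below the maternal QRS power, and sparse high-amplitude motion
#' artifacts.
#'
#' @param fs sampling rate (Hz).
#' @param duration record length (s).
#' @param maternal_hr mean maternal heart rate (bpm).
#' @param maternal_sdnn maternal RR standard deviation (ms).
#' @param fetal_hr_mean mean fetal heart rate (bpm).
#' @param fetal_sdnn fetal RR standard deviation (ms).
#' @param fetal_amp_ratio fetal/maternal R-peak amplitude ratio, in (0, 1).
#' @param resp_mod_depth fractional respiration amplitude modulation of the
#'   maternal complex.
#' @param resp_rate respiration rate (breaths/min).
#' @param emg_snr_db maternal-QRS-power to EMG-power ratio (dB); `Inf`
#'   disables EMG noise.
#' @param wander_amp baseline-wander amplitude (mV).
#' @param artifact_rate motion-artifact event rate (events/min).
#' @param rr_correlation lag-1 autocorrelation of both RR series.
#' @param seed RNG seed fixing the full output.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(fs = 1000, duration = 60,
                         maternal_hr = 75, maternal_sdnn = 30,
                         fetal_hr_mean = 135, fetal_sdnn = 20,
                         fetal_amp_ratio = 0.2,
                         resp_mod_depth = 0.25, resp_rate = 15,
                         emg_snr_db = 15, wander_amp = 0.15,
                         artifact_rate = 0.5, rr_correlation = 0.6,
                         seed = 1L) {
  cfg <- list(fs = fs, duration = duration, maternal_hr = maternal_hr,
              maternal_sdnn = maternal_sdnn, fetal_hr_mean = fetal_hr_mean,
              fetal_sdnn = fetal_sdnn, fetal_amp_ratio = fetal_amp_ratio,
              resp_mod_depth = resp_mod_depth, resp_rate = resp_rate,
              emg_snr_db = emg_snr_db, wander_amp = wander_amp,
              artifact_rate = artifact_rate, rr_correlation = rr_correlation,
              seed = as.integer(seed))
  pos <- c("fs", "duration", "maternal_hr", "fetal_hr_mean", "resp_rate")
  for (nm in pos) if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
    abort(paste0("`", nm, "` must be positive and finite."))
  }
  nonneg <- c("maternal_sdnn", "fetal_sdnn", "resp_mod_depth", "wander_amp",
              "artifact_rate")
  for (nm in nonneg) if (is.na(cfg[[nm]]) || cfg[[nm]] < 0) {
    abort(paste0("`", nm, "` must be non-negative."))
  }
  if (!(cfg$fetal_amp_ratio >= 0 && cfg$fetal_amp_ratio < 1)) {
    abort("`fetal_amp_ratio` must lie in [0, 1).")
  }
  if (is.na(cfg$emg_snr_db)) abort("`emg_snr_db` must not be NA.")
  if (abs(cfg$rr_correlation) >= 1) abort("`rr_correlation` must satisfy |r| < 1.")
  structure(cfg, class = "synth_config")
}

#' Generate an autocorrelated NN-interval series
#'
#' Draws `n` inter-beat intervals from a stationary lag-1 autoregressive
#' process with Gaussian innovations: target mean `mean_rr`, marginal
#' standard deviation `sdnn`, lag-1 autocorrelation `correlation`. Draws
#' falling outside mean +/- 4 SD are rejected and redrawn, so the series
#' contains no non-physiological outliers.
#'
#' @param mean_rr target mean interval (ms), positive.
#' @param sdnn target interval standard deviation (ms), non-negative.
#' @param n number of intervals.
#' @param correlation lag-1 autocorrelation, |r| < 1.
#' @param seed RNG seed.
#' @return numeric vector of `n` intervals (ms).
#' @examples
#' rr <- generate_rr_series(444, 20, 500, seed = 7)
#' c(mean(rr), sd(rr))
#' @export
generate_rr_series <- function(mean_rr, sdnn, n, correlation = 0.6, seed = 1L) {
  if (!is.finite(mean_rr) || mean_rr <= 0) abort("`mean_rr` must be positive and finite.")
  if (!is.finite(sdnn) || sdnn < 0) abort("`sdnn` must be non-negative and finite.")
  if (!is.finite(correlation) || abs(correlation) >= 1) abort("|correlation| must be < 1.")
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be at least 1.")
  if (sdnn == 0) return(rep(mean_rr, n))
  with_seed(seed, {
    innov_sd <- sdnn * sqrt(1 - correlation^2)
    draw <- function(mu, sd_, lo, hi) {
      repeat {
        v <- rnorm(1L, mu, sd_)
        if (v >= lo && v <= hi) return(v)
      }
    }
    lo <- mean_rr - 4 * sdnn
    hi <- mean_rr + 4 * sdnn
    x <- numeric(n)
    x[1L] <- draw(mean_rr, sdnn, lo, hi)
    for (i in seq_len(n - 1L)) {
      mu <- mean_rr + correlation * (x[i] - mean_rr)
      x[i + 1L] <- draw(mu, innov_sd, lo, hi)
    }
    x
  })
}

# Default per-wave morphology tables: Gaussian bumps (center offset from the
# R apex in s, amplitude relative to R, width sigma in s). The fetal QRS is
# triphasic and narrow so that >60% of the complex's spectral energy falls
# in the 10-20 Hz band; the maternal complex is wider and lower-frequency.
#' @rdname render_ecg_from_beats
#' @export
maternal_morphology <- function() {
  tibble::tibble(
    wave   = c("P", "Q", "R", "S", "T"),
    center = c(-0.180, -0.035, 0.000, 0.035, 0.260),
    amp    = c(0.12, -0.18, 1.00, -0.25, 0.30),
    sigma  = c(0.030, 0.012, 0.016, 0.014, 0.060)
  )
}

#' @rdname render_ecg_from_beats
#' @export
fetal_morphology <- function() {
  tibble::tibble(
    wave   = c("P", "Q", "R", "S", "T"),
    center = c(-0.100, -0.022, 0.000, 0.022, 0.150),
    amp    = c(0.08, -0.45, 1.00, -0.45, 0.18),
    sigma  = c(0.018, 0.013, 0.010, 0.013, 0.035)
  )
}

#' Render an ECG trace from beat times and a sum-of-Gaussians morphology
#'
#' Places one P-QRS-T complex, built as a sum of Gaussian bumps, at every
#' beat time. The R-bump apex lands within one sample of each beat time by
#' construction.
#'
#' @param beats a [beat_times] (or numeric vector of beat times, s).
#' @param fs sampling rate (Hz).
#' @param duration trace length (s); defaults to last beat + 0.5 s.
#' @param morphology a tibble with columns `wave`, `center` (s, offset from
#'   the R apex), `amp` (mV) and `sigma` (s); see [maternal_morphology()]
#'   and [fetal_morphology()].
#' @return numeric vector of length `round(duration * fs)` (mV).
#' @export
render_ecg_from_beats <- function(beats, fs, duration = NULL,
                                  morphology = maternal_morphology()) {
  tt <- if (is.data.frame(beats)) beats$time else as.numeric(beats)
  stopifnot(all(is.finite(morphology$amp)), all(morphology$sigma > 0))
  if (is.null(duration)) duration <- if (length(tt)) max(tt) + 0.5 else 1
  n <- as.integer(round(duration * fs))
  x <- numeric(n)
  if (!length(tt)) return(x)
  span <- max(abs(morphology$center)) + 5 * max(morphology$sigma)
  if (length(tt) > 1L && min(diff(tt)) < 2 * max(morphology$sigma)) {
    abort("Beats are denser than the complex width permits.")
  }
  tgrid <- (seq_len(n) - 1L) / fs
  for (tau in tt) {
    i0 <- max(1L, floor((tau - span) * fs) + 1L)
    i1 <- min(n, ceiling((tau + span) * fs) + 1L)
    if (i0 > i1) next
    tl <- tgrid[i0:i1] - tau
    bump <- numeric(length(tl))
    for (k in seq_len(nrow(morphology))) {
      bump <- bump + morphology$amp[k] *
        exp(-0.5 * ((tl - morphology$center[k]) / morphology$sigma[k])^2)
    }
    x[i0:i1] <- x[i0:i1] + bump
  }
  x
}

#' Compose a synthetic abdominal ECG with ground truth
#'
#' Builds the additive composite: respiration-modulated maternal ECG +
#' scaled fetal ECG + sinusoidal baseline wander + band-limited (20-150 Hz)
#' Gaussian EMG noise at the configured SNR + sparse random-polarity
#' raised-cosine motion artifacts (50-200 ms wide, 2-5 times the maternal R
#' amplitude). Fully deterministic under `cfg$seed`.
#'
#' @param cfg a [synth_config].
#' @return a list of class `synthetic_ecg` with elements `record` (an
#'   [ecg_record], single lead `abd`), and `truth`: a list with
#'   `maternal_beats`, `fetal_beats` ([beat_times]), `clean_fetal` (the
#'   scaled noise-free fetal trace), `fetal_rr_ms`, and the pure
#'   `components` (maternal, fetal, wander, emg, artifact traces).
#' @export
compose_abdominal <- function(cfg = synth_config()) {
  if (!inherits(cfg, "synth_config")) cfg <- do.call(synth_config, cfg)
  fs <- cfg$fs
  n <- as.integer(round(cfg$duration * fs))
  tgrid <- (seq_len(n) - 1L) / fs

  with_seed(cfg$seed, {
    # beat schedules (~10% head-room so beats cover the whole record)
    n_m <- ceiling(cfg$duration * cfg$maternal_hr / 60 * 1.1) + 2L
    n_f <- ceiling(cfg$duration * cfg$fetal_hr_mean / 60 * 1.1) + 2L
    rr_m <- generate_rr_series(60000 / cfg$maternal_hr, cfg$maternal_sdnn,
                               n_m, cfg$rr_correlation,
                               seed = sample.int(2^30, 1L))
    rr_f <- generate_rr_series(60000 / cfg$fetal_hr_mean, cfg$fetal_sdnn,
                               n_f, cfg$rr_correlation,
                               seed = sample.int(2^30, 1L))
    tm <- 0.4 + cumsum(rr_m) / 1000
    tf <- 0.3 + runif(1L) * 0.4 + cumsum(rr_f) / 1000
    margin <- 0.35  # keep full complexes inside the record
    tm <- tm[tm < cfg$duration - margin]
    tf <- tf[tf < cfg$duration - margin]

    maternal <- render_ecg_from_beats(tm, fs, cfg$duration, maternal_morphology())
    resp <- 1 + cfg$resp_mod_depth * sin(2 * pi * cfg$resp_rate / 60 * tgrid)
    maternal_mod <- maternal * resp

    fetal_unit <- render_ecg_from_beats(tf, fs, cfg$duration, fetal_morphology())
    clean_fetal <- cfg$fetal_amp_ratio * fetal_unit

    wander <- cfg$wander_amp *
      (sin(2 * pi * 0.22 * tgrid + runif(1L, 0, 2 * pi)) +
         0.5 * sin(2 * pi * 0.05 * tgrid + runif(1L, 0, 2 * pi)))

    # EMG: white Gaussian noise band-limited to 20-150 Hz, scaled so that
    # (maternal QRS-window power) / (EMG power) = emg_snr_db
    if (is.infinite(cfg$emg_snr_db)) {
      emg <- numeric(n)
    } else {
      raw <- rnorm(n)
      emg <- bandpass(raw, fs, c(20, min(150, fs / 2 * 0.9)), order = 4L)
      qrs_idx <- unlist(lapply(tm, function(tau) {
        j <- time_to_index(tau, fs)
        max(1L, j - round(0.06 * fs)):min(n, j + round(0.06 * fs))
      }))
      p_qrs <- mean(maternal_mod[qrs_idx]^2)
      p_target <- p_qrs / 10^(cfg$emg_snr_db / 10)
      emg <- emg * sqrt(p_target / mean(emg^2))
    }

    # motion artifacts: random-polarity raised-cosine transients
    artifact <- numeric(n)
    n_art <- rpois(1L, cfg$artifact_rate * cfg$duration / 60)
    r_amp <- max(abs(maternal_mod))
    if (n_art > 0L) {
      for (k in seq_len(n_art)) {
        width <- runif(1L, 0.05, 0.2)
        amp <- runif(1L, 2, 5) * r_amp * sample(c(-1, 1), 1L)
        t0 <- runif(1L, 0, cfg$duration - width)
        i0 <- time_to_index(t0, fs)
        i1 <- min(n, i0 + round(width * fs))
        ph <- seq(0, 2 * pi, length.out = i1 - i0 + 1L)
        artifact[i0:i1] <- artifact[i0:i1] + amp * 0.5 * (1 - cos(ph))
      }
    }

    x <- maternal_mod + clean_fetal + wander + emg + artifact
    rec <- ecg_record(matrix(x, ncol = 1L), fs = fs, lead_names = "abd")

    truth <- list(
      maternal_beats = beat_times(tm, source = "maternal"),
      fetal_beats = beat_times(tf, source = "fetal"),
      clean_fetal = clean_fetal,
      fetal_rr_ms = diff(tf) * 1000,
      components = list(maternal = maternal_mod, fetal = clean_fetal,
                        wander = wander, emg = emg, artifact = artifact)
    )
    structure(list(record = rec, truth = truth, config = cfg),
              class = "synthetic_ecg")
  })
}
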