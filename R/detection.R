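# Fetal beat detection on the maternal-cancelled trace.
#
# The cleaned signal is mapped to a Gaussian-windowed short-time Fourier
# (Gabor) power representation; fetal QRS events show up as intermittent
# bursts in roughly the 10-20 Hz band. The per-frame power integrated over
# that band is compared against an adaptive envelope built by an
# order-statistic filter (sliding maximum of Tukey-window-weighted values):
# frames where the series touches its own envelope are beat candidates.

#' Gabor (Gaussian-window STFT) power spectrogram
#'
#' One-sided power spectrogram with a Gaussian analysis window of length
#' `window_len` seconds (window sigma = len/6 samples), hop `hop` seconds,
#' frame times at the window centre. Power is normalised so that the sum of
#' a frame's one-sided power bins equals the energy (sum of squares) of the
#' windowed slice (Parseval, conjugate bins folded in).
#'
#' @param x numeric trace.
#' @param fs sampling rate (Hz).
#' @param window_len analysis window length (s).
#' @param hop frame step (s), at most `window_len`.
#' @param nfft FFT length (samples); defaults to four times the window
#'   length, i.e. 4x zero-padding, so frequency bins are fine enough to
#'   delimit a 10 Hz band meaningfully (the true spectral resolution is
#'   still set by the window).
#' @return a list of class `gabor_spectrogram`: `power` (frames x
#'   frequency), `frame_times` (s), `freqs` (Hz), `window_len`, `hop`,
#'   `fs`, `window` (the analysis window).
#' @export
gabor_spectrogram <- function(x, fs, window_len = 0.128, hop = 0.004,
                              nfft = NULL) {
  if (!length(x)) abort("Empty input trace.")
  lw <- as.integer(round(window_len * fs))
  if (lw < 4L) abort("`window_len` must span at least 4 samples.")
  hp <- max(1L, as.integer(round(hop * fs)))
  if (hp > lw) abort("`hop` must not exceed `window_len`.")
  if (length(x) < lw) abort("Trace shorter than one analysis window.")
  if (is.null(nfft)) nfft <- 4L * lw
  nfft <- as.integer(nfft)
  if (nfft < lw) abort("`nfft` must be at least the window length.")
  w <- gaussian_window(lw, (lw + 1) / 2, lw / 6)
  starts <- seq.int(1L, length(x) - lw + 1L, by = hp)
  idx <- outer(seq_len(lw) - 1L, starts, `+`)
  frames <- matrix(0, nrow = nfft, ncol = length(starts))
  frames[seq_len(lw), ] <- matrix(x[idx], nrow = lw) * w
  ft <- mvfft(frames)
  nb <- nfft %/% 2L + 1L
  mult <- rep(2, nb)
  mult[1L] <- 1
  if (nfft %% 2L == 0L) mult[nb] <- 1
  power <- t(Mod(ft[seq_len(nb), , drop = FALSE])^2 * (mult / nfft))
  structure(
    list(power = power,
         frame_times = (starts - 1L + (lw - 1L) / 2) / fs,
         freqs = (seq_len(nb) - 1L) * fs / nfft,
         window_len = window_len, hop = hp / fs, fs = fs, window = w,
         nfft = nfft),
    class = "gabor_spectrogram"
  )
}

#' Select the fetal QRS frequency band from a spectrogram
#'
#' Scans 10-Hz-wide candidate bands inside `search_range` and returns the
#' one whose integrated band power is most intermittent in time, measured
#' as the excess kurtosis of the band-power series on the amplitude
#' (square-root) scale: a sparse fetal beat train maximises it, while for
#' featureless noise the root of the integrated band power is close to
#' Gaussian (Wilson-Hilferty), so the statistic sits near 0. Bands whose
#' kurtosis comes within 0.5 of the maximum are treated as tied and the
#' most energetic of them wins (the spikiness estimate is noisy; given a
#' tie, the band actually containing the QRS energy is the right choice).
#' When no candidate is appreciably super-Gaussian (excess kurtosis below
#' `min_excess_kurtosis`), the anchor band `default_band` is returned with
#' a fallback flag.
#'
#' @param spec a [gabor_spectrogram].
#' @param default_band fallback band (Hz), default `c(10, 20)`.
#' @param search_range band search limits (Hz), default `c(8, 30)`.
#' @param band_width candidate band width (Hz).
#' @param min_excess_kurtosis flat-kurtosis fallback threshold.
#' @return list with `band` (c(f_lo, f_hi)), `fallback` (logical),
#'   `kurtosis` (amplitude-scale excess kurtosis of the chosen band).
#' @export
select_fetal_band <- function(spec, default_band = c(10, 20),
                              search_range = c(8, 30), band_width = 10,
                              min_excess_kurtosis = 0.5) {
  ny <- spec$fs / 2
  if (search_range[2L] > ny || default_band[2L] > ny) {
    abort("Requested band extends beyond the Nyquist frequency.")
  }
  los <- seq(search_range[1L], search_range[2L] - band_width, by = 1)
  if (!length(los)) abort("Search range narrower than the band width.")
  stat <- vapply(los, function(lo) {
    v <- integrate_band_power(spec, c(lo, lo + band_width))$power
    if (sd(v) == 0) return(c(-Inf, 0))
    # winsorise the top 1% of frames: a single high-amplitude motion
    # artifact (a few dozen frames) would otherwise dominate the
    # kurtosis and hijack the band choice, while a beat train occupies
    # far more than 1% of frames and keeps its spikiness
    vw <- pmin(v, quantile(v, 0.99, names = FALSE))
    if (sd(vw) == 0) return(c(-Inf, sum(v)))
    c(e1071::kurtosis(sqrt(vw), type = 1), sum(v))
  }, numeric(2))
  kurt <- stat[1L, ]
  energy <- stat[2L, ]
  if (!any(is.finite(kurt)) || max(kurt) < min_excess_kurtosis) {
    v <- integrate_band_power(spec, default_band)$power
    k0 <- if (sd(v) == 0) NA_real_ else e1071::kurtosis(sqrt(v), type = 1)
    return(list(band = default_band, fallback = TRUE, kurtosis = k0))
  }
  tied <- which(kurt >= max(kurt) - 0.5)
  best <- tied[which.max(energy[tied])]
  list(band = c(los[best], los[best] + band_width), fallback = FALSE,
       kurtosis = kurt[best])
}

#' Integrate spectrogram power over a frequency band
#'
#' @param spec a [gabor_spectrogram].
#' @param band `c(f_lo, f_hi)` in Hz, inclusive.
#' @return a tibble of class `band_power_series` with columns `frame_time`
#'   and `power`; the band is carried as an attribute.
#' @export
integrate_band_power <- function(spec, band) {
  if (band[1L] >= band[2L]) abort("`band` must satisfy f_lo < f_hi.")
  cols <- which(spec$freqs >= band[1L] & spec$freqs <= band[2L])
  if (!length(cols)) abort("No spectrogram bins inside the requested band.")
  out <- tibble::tibble(
    frame_time = spec$frame_times,
    power = rowSums(spec$power[, cols, drop = FALSE])
  )
  attr(out, "band") <- band
  attr(out, "hop") <- spec$hop
  class(out) <- c("band_power_series", class(out))
  out
}

#' Order-statistic (sliding Tukey-weighted maximum) envelope
#'
#' For each position k, weights the series inside a window centred at k by
#' a unit-peak Tukey window and takes the maximum of the weighted values,
#' shifting one point at a time; at the edges the window is truncated. With
#' a unit-peak window the envelope dominates the series pointwise, and a
#' non-negative series touches its envelope exactly at locally dominant
#' samples -- the property the beat picker exploits.
#'
#' @param values numeric series (typically integrated band power).
#' @param window_len odd window length in frames, >= 3.
#' @param tukey_alpha Tukey taper fraction in [0, 1] (0 = rectangular,
#'   1 = Hann).
#' @return numeric envelope, same length as `values`.
#' @export
order_statistic_envelope <- function(values, window_len = 21L, tukey_alpha = 0.5) {
  n <- length(values)
  if (!n) return(numeric(0))
  window_len <- as.integer(window_len)
  if (window_len < 3L || window_len %% 2L == 0L) abort("`window_len` must be odd and >= 3.")
  if (tukey_alpha < 0 || tukey_alpha > 1) abort("`tukey_alpha` must lie in [0, 1].")
  if (window_len > n) {
    inform("Envelope window longer than the series; using one global window.")
    window_len <- if (n %% 2L == 1L) n else n - 1L
    if (window_len < 3L) return(values)
  }
  h <- window_len %/% 2L
  w <- tukey_window(window_len, tukey_alpha)
  env <- rep(-Inf, n)
  for (d in -h:h) {
    wk <- w[d + h + 1L]
    src <- seq_len(n) + d
    ok <- src >= 1L & src <= n
    shifted <- rep(-Inf, n)
    shifted[ok] <- values[src[ok]] * wk
    env <- pmax(env, shifted)
  }
  env
}

#' Detect fetal beats from integrated band power and its envelope
#'
#' Beat candidates are frames where the band-power series equals its
#' order-statistic envelope (within a relative tie tolerance) and exceeds
#' the noise floor (median band power) by `min_prominence_ratio`. A
#' refractory period `min_rr` is enforced greedily, keeping the larger
#' peak. Peak times are refined by parabolic interpolation of the
#' band-power maximum across three frames, giving sub-frame resolution.
#' All thresholds are relative, so detection is invariant to global
#' amplitude scaling of the input trace.
#'
#' @param bp a `band_power_series` with an `envelope` column (add one via
#'   [order_statistic_envelope]), or lacking it, `envelope_len`/`tukey_alpha`
#'   are used to compute it.
#' @param min_rr refractory period (s), default 0.25 (<= 240 bpm).
#' @param min_prominence_ratio detection threshold as a multiple of the
#'   median band power.
#' @param envelope_len envelope window length (s) when the envelope is
#'   computed here.
#' @param tukey_alpha Tukey taper for the envelope.
#' @param tie_tol relative tolerance for "value equals envelope".
#' @param refine parabolic sub-frame peak-time refinement (default TRUE).
#' @return a [beat_times] with `source = "fetal"` and a `power` column;
#'   the band-power tibble (with envelope) is attached as attribute
#'   `band_power`.
#' @export
detect_fetal_peaks <- function(bp, min_rr = 0.25, min_prominence_ratio = 3,
                               envelope_len = 0.25, tukey_alpha = 0.5,
                               tie_tol = 1e-9, refine = TRUE) {
  hop <- attr(bp, "hop")
  if (is.null(hop)) hop <- median(diff(bp$frame_time))
  v <- bp$power
  if (!"envelope" %in% names(bp)) {
    wl <- as.integer(round(envelope_len / hop))
    if (wl %% 2L == 0L) wl <- wl + 1L
    bp$envelope <- order_statistic_envelope(v, max(3L, wl), tukey_alpha)
  }
  env <- bp$envelope
  floor_ <- median(v)
  cand <- which(v >= env * (1 - tie_tol) & v > floor_ * min_prominence_ratio)
  refr <- min(0.2, 0.8 * min_rr)  # validator bound; greedy step enforces min_rr
  out_empty <- beat_times(numeric(0), source = "fetal", refractory = refr,
                          power = numeric(0))
  attr(out_empty, "band_power") <- bp
  if (!length(cand)) return(out_empty)
  # collapse runs of adjacent candidate frames to their maximum
  # (earliest frame on a tied plateau)
  grp <- cumsum(c(1L, diff(cand) > 1L))
  cand <- vapply(split(cand, grp), function(ix) ix[which.max(v[ix])], integer(1))
  keep <- enforce_refractory(bp$frame_time[cand], v[cand], min_rr)
  cand <- sort(cand[keep])
  # search-back: a gap of about two median RR intervals means a beat was
  # masked (e.g. by a maternal residue peak winning the envelope locally);
  # recover the strongest in-gap band-power maximum above a relaxed
  # threshold
  if (length(cand) >= 5L) {
    thr_back <- 0.4 * floor_ * min_prominence_ratio
    lmax <- local_maxima(v)
    repeat {
      tt <- bp$frame_time[cand]
      med_rr <- median(diff(tt))
      gaps <- which(diff(tt) > 1.6 * med_rr & diff(tt) < 2.6 * med_rr)
      added <- FALSE
      for (gi in gaps) {
        lo <- tt[gi] + 0.5 * med_rr
        hi <- tt[gi + 1L] - 0.5 * med_rr
        inside <- lmax[bp$frame_time[lmax] > lo & bp$frame_time[lmax] < hi]
        inside <- inside[v[inside] > thr_back]
        if (length(inside)) {
          cand <- sort(c(cand, inside[which.max(v[inside])]))
          added <- TRUE
        }
      }
      if (!added) break
    }
  }
  times <- bp$frame_time[cand]
  if (refine) {
    for (k in seq_along(cand)) {
      i <- cand[k]
      if (i > 1L && i < length(v)) {
        denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
        if (denom < 0) {
          dt <- 0.5 * (v[i - 1L] - v[i + 1L]) / denom
          times[k] <- times[k] + max(-1, min(1, dt)) * hop
        }
      }
    }
  }
  ord <- order(times)
  out <- beat_times(times[ord], source = "fetal", refractory = refr,
                    power = v[cand][ord])
  attr(out, "band_power") <- bp
  out
}

#' Reject pseudo fetal peaks
#'
#' Two guards against spurious detections: (1) peaks whose band power is
#' below a quarter of the median peak power are dropped as EMG/noise
#' flukes; (2) peaks within `coincidence_tol` of a maternal beat are
#' re-examined by re-fitting and subtracting the maternal two-basis
#' template locally and recomputing the local band power -- if the peak
#' loses more than half its power it is attributed to maternal QRS residue
#' and dropped.
#'
#' @param beats fetal [beat_times] with a `power` column.
#' @param bp the `band_power_series` used for detection.
#' @param maternal_beats maternal [beat_times] (may be empty / NULL).
#' @param x_f cleaned trace (needed for the maternal-residue re-check).
#' @param fs sampling rate (Hz).
#' @param template the maternal `qrs_template` (optional; without it the
#'   residue re-check is skipped).
#' @param coincidence_tol maternal coincidence window (s), default 0.03.
#' @param prominence_divisor peaks below `median(power)/divisor` are
#'   dropped.
#' @return the filtered [beat_times]; removals (with reasons) are attached
#'   as attribute `removed`.
#' @export
reject_pseudo_peaks <- function(beats, bp, maternal_beats = NULL,
                                x_f = NULL, fs = NULL, template = NULL,
                                coincidence_tol = 0.03,
                                prominence_divisor = 4) {
  if (!nrow(beats)) {
    attr(beats, "removed") <- tibble::tibble(time = numeric(0), reason = character(0))
    return(beats)
  }
  reason <- rep(NA_character_, nrow(beats))
  med_p <- median(beats$power)
  reason[beats$power < med_p / prominence_divisor] <- "low_prominence"
  # rhythm-context insertion check: a peak splitting an otherwise plausible
  # RR interval into two implausibly short ones is a pseudo peak sitting
  # between two genuine fetal beats -- drop it when it coincides with a
  # maternal beat or is much weaker than its neighbours
  if (nrow(beats) >= 5L) {
    tt <- beats$time
    med_rr <- median(diff(tt))
    for (k in 2:(nrow(beats) - 1L)) {
      if (!is.na(reason[k])) next
      span <- tt[k + 1L] - tt[k - 1L]
      if (span > 0.8 * med_rr && span < 1.3 * med_rr &&
          (tt[k] - tt[k - 1L]) < 0.65 * med_rr &&
          (tt[k + 1L] - tt[k]) < 0.65 * med_rr) {
        coincident <- !is.null(maternal_beats) && nrow(maternal_beats) &&
          min(abs(maternal_beats$time - tt[k])) <= coincidence_tol
        weak <- beats$power[k] <
          0.33 * min(beats$power[k - 1L], beats$power[k + 1L])
        if (coincident || weak) reason[k] <- "rr_insertion"
      }
    }
  }
  if (!is.null(maternal_beats) && nrow(maternal_beats) &&
      !is.null(x_f) && !is.null(fs) && !is.null(template)) {
    band <- attr(bp, "band")
    wl_s <- length(template$template) / fs
    for (k in which(is.na(reason))) {
      dt <- abs(maternal_beats$time - beats$time[k])
      if (min(dt) > coincidence_tol) next
      mt <- maternal_beats$time[which.min(dt)]
      # second-pass local re-subtraction: re-fit the maternal template on
      # the cleaned trace around this beat, with a small lag search (the
      # first pass used one global alignment; residue is often a small
      # alignment/shape error the lag-free fit could not capture)
      len <- length(template$template)
      ml <- as.integer(round(0.01 * fs))
      best <- NULL
      best_en <- -Inf
      for (d in -ml:ml) {
        seg <- extract_qrs_segments(x_f, fs, mt + d / fs, wl_s)
        if (!length(seg$kept)) next
        fit <- fit_beat_projection(as.numeric(seg$segments[1L, ]), template)
        en <- sum(fit$fitted^2)
        if (en > best_en) {
          best_en <- en
          best <- list(fit = fit, start = seg$starts[1L])
        }
      }
      if (is.null(best)) next
      x_loc <- x_f
      ix <- best$start:(best$start + len - 1L)
      x_loc[ix] <- x_loc[ix] - best$fit$fitted
      half_ctx <- 0.25
      i0 <- max(1L, time_to_index(beats$time[k] - half_ctx, fs))
      i1 <- min(length(x_f), time_to_index(beats$time[k] + half_ctx, fs))
      sp_loc <- tryCatch(
        gabor_spectrogram(x_loc[i0:i1], fs, window_len = 0.128, hop = 0.004),
        error = function(e) NULL
      )
      if (is.null(sp_loc)) next
      bp_loc <- integrate_band_power(sp_loc, band)
      t_rel <- beats$time[k] - index_to_time(i0, fs)
      j <- which.min(abs(bp_loc$frame_time - t_rel))
      if (bp_loc$power[j] < 0.5 * beats$power[k]) reason[k] <- "maternal_residue"
    }
  }
  removed <- tibble::tibble(time = beats$time[!is.na(reason)],
                            reason = reason[!is.na(reason)])
  if (nrow(removed)) {
    inform(sprintf("Rejected %d pseudo peak(s): %s.", nrow(removed),
                   paste(sprintf("%.3f s (%s)", removed$time, removed$reason),
                         collapse = ", ")))
  }
  out <- beats[is.na(reason), , drop = FALSE]
  class(out) <- class(beats)
  attr(out, "band_power") <- attr(beats, "band_power")
  attr(out, "removed") <- removed
  out
}

# Refine fetal beat times on the cleaned trace by matched filtering: build
# an average fetal QRS template from the beat-aligned segments, realign
# each beat to the lag maximising its cross-correlation with the template,
# and iterate. Band-power frame times carry the analysis-window smearing;
# waveform-domain alignment removes it.
refine_fetal_times <- function(x_f, fs, times, width = 0.08, max_lag = 0.05,
                               iterations = 2L, align_band = c(5, 35)) {
  if (length(times) < 8L) return(times)
  # align on a band-limited copy: the fetal QRS lives near 10-20 Hz, and
  # discarding out-of-band EMG sharpens the matched-filter timing several-
  # fold (zero-phase filtering, so no lag is introduced)
  x_f <- bandpass(x_f, fs, align_band)
  len <- as.integer(round(width * fs))
  center <- len %/% 2L + 1L
  ml <- as.integer(round(max_lag * fs))
  for (it in seq_len(iterations)) {
    ci <- time_to_index(times, fs)
    starts <- ci - center + 1L
    ok <- starts >= 1L & (starts + len - 1L) <= length(x_f)
    if (sum(ok) < 8L) return(times)
    segs <- t(vapply(which(ok), function(i) x_f[starts[i]:(starts[i] + len - 1L)],
                     numeric(len)))
    tmpl <- colMeans(segs)
    tmpl <- tmpl - mean(tmpl)
    if (sqrt(sum(tmpl^2)) < .Machine$double.eps * len) return(times)
    new_t <- times
    for (i in which(ok)) {
      best <- 0L
      best_cc <- -Inf
      for (d in -ml:ml) {
        s0 <- ci[i] + d - center + 1L
        s1 <- s0 + len - 1L
        if (s0 < 1L || s1 > length(x_f)) next
        seg <- x_f[s0:s1]
        cc <- sum((seg - mean(seg)) * tmpl)
        if (cc > best_cc) {
          best_cc <- cc
          best <- d
        }
      }
      new_t[i] <- index_to_time(ci[i] + best, fs)
    }
    ord <- order(new_t)
    new_t <- new_t[ord]
    keep <- c(TRUE, diff(new_t) > 0.2)
    times <- new_t[keep]
  }
  times
}

#' Detect fetal beats in a maternal-cancelled trace
#'
#' Convenience wrapper chaining [gabor_spectrogram], [select_fetal_band],
#' [integrate_band_power], [order_statistic_envelope],
#' [detect_fetal_peaks] and [reject_pseudo_peaks].
#'
#' @param x_f cleaned trace (numeric) or a `maternal_cancellation` object.
#' @param fs sampling rate (Hz); taken from the cancellation object when
#'   omitted.
#' @param band `"auto"` for kurtosis-based selection, or `c(f_lo, f_hi)`.
#' @param window_len,hop Gabor analysis parameters (s).
#' @param envelope_len,tukey_alpha order-statistic envelope parameters.
#' @param min_rr,min_prominence_ratio peak-picking parameters.
#' @param maternal_beats,template forwarded to [reject_pseudo_peaks];
#'   filled in automatically from a `maternal_cancellation` input.
#' @return a fetal [beat_times] with attributes `band`, `band_fallback`,
#'   `band_power`, `removed`.
#' @export
detect_fetal_beats <- function(x_f, fs = NULL, band = "auto",
                               window_len = 0.128, hop = 0.004,
                               envelope_len = 0.25, tukey_alpha = 0.5,
                               min_rr = 0.25, min_prominence_ratio = 3,
                               maternal_beats = NULL, template = NULL) {
  if (inherits(x_f, "maternal_cancellation")) {
    fs <- x_f$fs
    maternal_beats <- maternal_beats %||% x_f$beats
    template <- template %||% x_f$template
    x_f <- x_f$x_f
  }
  if (is.null(fs)) abort("`fs` is required when `x_f` is a bare trace.")
  sp <- gabor_spectrogram(x_f, fs, window_len = window_len, hop = hop)
  if (identical(band, "auto")) {
    sel <- select_fetal_band(sp)
    band_used <- sel$band
    fallback <- sel$fallback
  } else {
    band_used <- band
    fallback <- FALSE
  }
  bpow <- integrate_band_power(sp, band_used)
  wl <- as.integer(round(envelope_len / sp$hop))
  if (wl %% 2L == 0L) wl <- wl + 1L
  # detect, reject pseudo peaks, then mask the rejected peaks' band-power
  # support and redetect: a rejected residue peak may have suppressed a
  # genuine neighbouring beat through the refractory rule
  bp_work <- bpow
  removed_all <- tibble::tibble(time = numeric(0), reason = character(0))
  for (pass in 1:3) {
    bp_work$envelope <- order_statistic_envelope(bp_work$power, max(3L, wl),
                                                 tukey_alpha)
    pk <- detect_fetal_peaks(bp_work, min_rr = min_rr,
                             min_prominence_ratio = min_prominence_ratio)
    pk <- reject_pseudo_peaks(pk, bp_work, maternal_beats = maternal_beats,
                              x_f = x_f, fs = fs, template = template)
    rem <- attr(pk, "removed")
    if (is.null(rem) || !nrow(rem)) break
    removed_all <- dplyr::bind_rows(removed_all, rem)
    for (t0 in rem$time) {
      mask <- abs(bp_work$frame_time - t0) <= 0.06
      bp_work$power[mask] <- pmin(bp_work$power[mask], median(bpow$power))
    }
  }
  # waveform-domain matched-filter alignment of the beat times (the frame
  # grid carries the analysis-window smearing; the RR series needs better),
  # then morphology screening: a detection whose aligned waveform does not
  # correlate with the average fetal QRS is residue or noise, not a beat
  if (nrow(pk) >= 8L) {
    t_ref <- refine_fetal_times(x_f, fs, pk$time)
    pw <- pk$power[vapply(t_ref, function(t) which.min(abs(pk$time - t)),
                          integer(1))]
    len <- as.integer(round(0.08 * fs))
    center <- len %/% 2L + 1L
    ci <- time_to_index(t_ref, fs)
    starts <- ci - center + 1L
    inb <- starts >= 1L & (starts + len - 1L) <= length(x_f)
    if (sum(inb) >= 8L) {
      segs <- t(vapply(which(inb), function(i)
        x_f[starts[i]:(starts[i] + len - 1L)], numeric(len)))
      segs <- segs - rowMeans(segs)
      tmpl_f <- colMeans(segs)
      cors <- rep(1, length(t_ref))
      if (sd(tmpl_f) > 0) {
        cors[inb] <- apply(segs, 1L, function(s)
          if (sd(s) == 0) 0 else stats::cor(s, tmpl_f))
      }
      drop <- cors < 0.3
      if (any(drop)) {
        inform(sprintf("Dropped %d detection(s) with non-QRS morphology.", sum(drop)))
        t_ref <- t_ref[!drop]
        pw <- pw[!drop]
      }
    }
    pk <- beat_times(t_ref, source = "fetal",
                     refractory = min(0.2, 0.8 * min_rr), power = pw)
  }
  attr(pk, "removed") <- removed_all
  attr(pk, "band_power") <- bpow
  attr(pk, "band") <- band_used
  attr(pk, "band_fallback") <- fallback
  pk
}
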