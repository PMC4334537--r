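# Adaptive maternal P-QRS-T cancellation.
#
# The maternal complex is removed in two passes. First, every detected
# maternal QRS is fitted as a linear combination of two orthogonal bases --
# the Gaussian-weighted average QRS template and its Hilbert-transform
# quadrature -- and the fitted complex is subtracted beat by beat. The
# two-basis fit absorbs beat-to-beat amplitude and phase drift (e.g. the
# respiration-driven change in the projection of the cardiac vector onto
# the electrodes) that defeats a fixed template. Second, the remaining P
# and T waves, which are low-frequency and far less variable, are removed
# by subtracting the average of all beat-aligned P-T segments.

# Moving-integrated squared-derivative detection function (Pan-Tompkins
# family): band-pass, differentiate, square, integrate over `integ_w` s.
detection_function <- function(x, fs, band = c(5, 25), integ_w = 0.12) {
  xf <- bandpass(x, fs, band)
  d <- c(0, diff(xf)) * fs
  moving_average(d^2, max(3L, as.integer(round(integ_w * fs))))
}

#' Detect maternal R peaks
#'
#' Standard energy-based QRS detection (band-pass 5-25 Hz, squared
#' derivative, moving-window integration, adaptive threshold with a 250 ms
#' refractory period), followed by apex refinement on the lead itself so
#' each reported time sits on the R apex.
#'
#' @param rec an [ecg_record].
#' @param lead lead name or index.
#' @param band detection band-pass corners (Hz).
#' @param refractory minimum inter-beat separation (s).
#' @param threshold_frac adaptive threshold as a fraction of the upper
#'   detection-function level.
#' @return a [beat_times] with `source = "maternal"`; empty (with a
#'   warning) when nothing resembling a QRS is found.
#' @export
detect_maternal_rpeaks <- function(rec, lead = 1L, band = c(5, 25),
                                   refractory = 0.25, threshold_frac = 0.3) {
  fs <- record_fs(rec)
  if (record_duration(rec) < 5) abort("Record shorter than 5 s; too short for reliable maternal detection.")
  x <- lead_signal(rec, lead)
  if (all(abs(x - x[1L]) < .Machine$double.eps * 100)) {
    warn("Flat lead: no maternal beats found.")
    return(beat_times(numeric(0), source = "maternal"))
  }
  g <- detection_function(x, fs, band = band)
  pk <- local_maxima(g)
  if (!length(pk)) {
    warn("No maternal beats found.")
    return(beat_times(numeric(0), source = "maternal"))
  }
  # robust beat-level amplitude: median of the top-N detection peaks, with
  # N set by the plausible maternal rate, so a handful of huge motion
  # artifacts cannot drag the threshold up
  n_exp <- max(5L, as.integer(round(record_duration(rec) * 1.4)))
  top <- head(sort(g[pk], decreasing = TRUE), n_exp)
  a_med <- median(top)
  thr <- threshold_frac * a_med
  art_thr <- 10 * a_med
  art_pk <- pk[g[pk] > art_thr]
  pk <- pk[g[pk] > thr & g[pk] <= art_thr]
  # candidates riding on an artifact's flank are unrecoverable: drop them
  # rather than place a mistimed beat there
  if (length(art_pk)) {
    near_art <- vapply(pk, function(i) any(abs(i - art_pk) < 0.15 * fs), logical(1))
    pk <- pk[!near_art]
  }
  keep <- enforce_refractory(index_to_time(pk, fs), g[pk], refractory)
  pk <- sort(pk[keep])
  if (!length(pk)) {
    warn("No maternal beats above threshold.")
    return(beat_times(numeric(0), source = "maternal"))
  }
  # apex refinement: largest |band-passed| excursion near the energy peak,
  # then the signed apex on the lead itself within +/-10 ms
  bp <- bandpass(x, fs, band)
  half <- as.integer(round(0.10 * fs))
  half2 <- as.integer(round(0.01 * fs))
  apex <- vapply(pk, function(i) {
    j <- max(1L, i - half):min(length(x), i + half)
    j0 <- j[which.max(abs(bp[j]))]
    s <- sign(bp[j0])
    k <- max(1L, j0 - half2):min(length(x), j0 + half2)
    k[which.max(s * x[k])]
  }, integer(1))
  apex <- sort(unique(apex))
  if (length(apex) > 1L) {
    keep <- enforce_refractory(index_to_time(apex, fs), g[apex], refractory)
    apex <- sort(apex[keep])
  }
  # search-back: an RR gap of about twice the median hides a beat the
  # threshold or an artifact swallowed; recover it from the detection
  # function inside the gap if anything beat-like is there
  if (length(apex) >= 4L) {
    med_rr <- median(diff(apex))
    repeat {
      gaps <- which(diff(apex) > 1.6 * med_rr & diff(apex) < 2.6 * med_rr)
      if (!length(gaps)) break
      ins <- integer(0)
      for (gi in gaps) {
        lo <- apex[gi] + as.integer(round(0.5 * med_rr))
        hi <- apex[gi + 1L] - as.integer(round(0.5 * med_rr))
        if (lo >= hi) next
        j <- (lo:hi)[which.max(g[lo:hi])]
        if (g[j] >= 0.15 * a_med) {
          jj <- max(1L, j - half):min(length(x), j + half)
          j0 <- jj[which.max(abs(bp[jj]))]
          s <- sign(bp[j0])
          k <- max(1L, j0 - half2):min(length(x), j0 + half2)
          ins <- c(ins, k[which.max(s * x[k])])
        }
      }
      if (!length(ins)) break
      apex2 <- sort(unique(c(apex, ins)))
      if (length(apex2) == length(apex)) break
      apex <- apex2
    }
  }
  beat_times(index_to_time(apex, fs), source = "maternal")
}

#' Extract beat-aligned QRS segments
#'
#' Cuts a rectangular window of width `W` seconds, centred on each beat
#' time, out of the trace. All segments have the identical length
#' `round(W * fs)` samples, with the beat sample mapped to the centre
#' sample `floor(len/2) + 1` (round-half-up convention). Beats whose
#' window would cross a record edge are dropped and reported.
#'
#' @param x numeric trace.
#' @param fs sampling rate (Hz).
#' @param beats a [beat_times] (or numeric times, s).
#' @param W window width (s), positive.
#' @return a list with `segments` (matrix, one row per kept beat), `center`
#'   (centre sample index within a segment), `kept` (indices into `beats`
#'   of the retained beats), `starts` (1-based start sample of each
#'   segment in `x`).
#' @export
extract_qrs_segments <- function(x, fs, beats, W) {
  if (!is.numeric(W) || W <= 0) abort("`W` must be positive.")
  tt <- if (is.data.frame(beats)) beats$time else as.numeric(beats)
  len <- as.integer(round(W * fs))
  if (len < 2L) abort("`W` is shorter than two samples at this sampling rate.")
  center <- len %/% 2L + 1L
  ci <- time_to_index(tt, fs)
  starts <- ci - center + 1L
  ends <- starts + len - 1L
  ok <- starts >= 1L & ends <= length(x)
  if (any(!ok)) {
    inform(sprintf("Dropped %d edge beat(s) whose %.0f ms window crosses a record boundary.",
                   sum(!ok), W * 1000))
  }
  segs <- t(vapply(which(ok), function(i) x[starts[i]:ends[i]], numeric(len)))
  if (sum(ok) == 1L) segs <- matrix(segs, nrow = 1L)
  list(segments = segs, center = center, kept = which(ok), starts = starts[ok])
}

#' Build the Gaussian-weighted maternal QRS template and its quadrature
#'
#' Averages the aligned QRS segments, applies a unit-peak Gaussian weight
#' centred on the segment centre (taming edge discontinuities so the
#' subtraction splices smoothly), and attaches the Hilbert-transform
#' quadrature companion as the second basis. The quadrature carries no DC
#' component, so the two bases are numerically orthogonal (inner product
#' after mean removal below 1e-6 of the norm product) without altering the
#' template's own mean.
#'
#' @param segments segment matrix (or the list returned by
#'   [extract_qrs_segments]).
#' @param fs sampling rate (Hz).
#' @param gauss_sigma Gaussian weight standard deviation (s); default W,
#'   i.e. a gentle taper that leaves the QRS support nearly unweighted
#'   while still rolling the window edges off smoothly.
#' @param weights optional per-beat averaging weights (e.g. to exclude
#'   ectopic beats); default equal.
#' @return a list of class `qrs_template`: `template`, `ortho`, `W`,
#'   `gauss_sigma`, `center`, `fs`, `n_beats_averaged`.
#' @export
build_qrs_template <- function(segments, fs, gauss_sigma = NULL, weights = NULL) {
  if (is.list(segments) && !is.data.frame(segments) && !is.matrix(segments)) {
    segments <- segments$segments
  }
  if (!is.matrix(segments) || nrow(segments) < 2L) {
    abort("Need at least 2 aligned segments to build a template.")
  }
  len <- ncol(segments)
  W <- len / fs
  if (is.null(gauss_sigma)) gauss_sigma <- W
  center <- len %/% 2L + 1L
  if (is.null(weights)) weights <- rep(1, nrow(segments))
  if (length(weights) != nrow(segments) || any(weights < 0) || sum(weights) == 0) {
    abort("`weights` must be non-negative with a positive sum, one per segment.")
  }
  avg <- colSums(segments * (weights / sum(weights)))
  g <- gaussian_window(len, center, gauss_sigma * fs)
  tmpl <- avg * g
  # note: the template keeps its natural mean -- the DFT quadrature has no
  # DC component, so <template, ortho> vanishes regardless, and removing
  # the mean here would inject a DC pedestal into every subtracted fit
  nrm <- sqrt(sum(tmpl^2))
  if (nrm <= .Machine$double.eps * len) {
    abort("Degenerate template: the weighted average QRS is (numerically) zero.")
  }
  ortho <- hilbert_orthogonal_basis(tmpl)
  structure(
    list(template = tmpl, ortho = ortho, W = W, gauss_sigma = gauss_sigma,
         center = center, fs = fs, n_beats_averaged = nrow(segments)),
    class = "qrs_template"
  )
}

#' Hilbert-transform orthogonal companion of a template
#'
#' The imaginary part of the discrete analytic signal of the template. For
#' a real sequence the cross-spectrum with its quadrature is odd across
#' frequency (and zero at DC), so the inner product vanishes: the two
#' waveforms form an orthogonal basis whose span absorbs amplitude and
#' phase drift of the maternal QRS.
#'
#' @param template non-zero numeric vector.
#' @return numeric vector, same length, numerically orthogonal to the
#'   input.
#' @export
hilbert_orthogonal_basis <- function(template) {
  if (sqrt(sum(template^2)) <= .Machine$double.eps * length(template)) {
    abort("Cannot build a quadrature basis from a zero template.")
  }
  analytic_quadrature(template)
}

# Running-median baseline-wander estimate. The window is long relative to
# the QRS complex (so the median ignores it) but short against respiratory
# and electrode drift, which it tracks. The estimate is used only to
# de-bias template building and the per-beat projections -- it is never
# subtracted from the signal itself, so the output trace stays continuous.
baseline_trace <- function(x, fs, width = 0.4) {
  k <- as.integer(round(width * fs))
  if (k %% 2L == 0L) k <- k + 1L
  k <- max(3L, min(k, if (length(x) %% 2L == 1L) length(x) else length(x) - 1L))
  as.numeric(stats::runmed(x, k = k, endrule = "median"))
}

# Shift each beat time by the integer-sample lag (within +/- max_lag) that
# maximises the cross-correlation of its (baseline-corrected) segment with
# the template.
refine_beat_alignment <- function(x, fs, beats, tmpl, max_lag = 0.01,
                                  baseline = NULL) {
  tt <- if (is.data.frame(beats)) beats$time else as.numeric(beats)
  len <- length(tmpl$template)
  center <- tmpl$center
  ml <- as.integer(round(max_lag * fs))
  lags <- -ml:ml
  if (is.null(baseline)) baseline <- baseline_trace(x, fs)
  xc <- x - baseline
  new_t <- tt
  for (i in seq_along(tt)) {
    ci <- time_to_index(tt[i], fs)
    best <- 0L
    best_cc <- -Inf
    for (d in lags) {
      s0 <- ci + d - center + 1L
      s1 <- s0 + len - 1L
      if (s0 < 1L || s1 > length(x)) next
      cc <- sum(xc[s0:s1] * tmpl$template)
      if (cc > best_cc) {
        best_cc <- cc
        best <- d
      }
    }
    new_t[i] <- index_to_time(ci + best, fs)
  }
  ord <- order(new_t)
  new_t <- new_t[ord]
  dup <- c(FALSE, diff(new_t) <= 0)
  beat_times(new_t[!dup], source = "maternal",
             refractory = attr(beats, "refractory") %||% 0.2)
}

#' Project one beat segment onto the two-basis template
#'
#' Independent projections onto the template and its quadrature
#' (legitimate because the bases are numerically orthogonal):
#' `a = <segment, template> / ||template||^2`,
#' `b = <segment, ortho> / ||ortho||^2`, and the fitted maternal complex is
#' `a * template + b * ortho`.
#'
#' @param segment numeric vector, same length as the template.
#' @param tmpl a `qrs_template`.
#' @return list with `a`, `b`, `fitted`, `residual_energy`.
#' @export
fit_beat_projection <- function(segment, tmpl) {
  if (length(segment) != length(tmpl$template)) {
    abort("Segment length does not match the template length.")
  }
  a <- sum(segment * tmpl$template) / sum(tmpl$template^2)
  b <- sum(segment * tmpl$ortho) / sum(tmpl$ortho^2)
  fitted <- a * tmpl$template + b * tmpl$ortho
  list(a = a, b = b, fitted = fitted,
       residual_energy = sum((segment - fitted)^2))
}

#' Subtract the per-beat adaptive QRS fit from a trace
#'
#' For every beat with a full window inside the record, fits the two-basis
#' template to the local segment and subtracts the fit in place. Samples
#' outside all QRS windows are untouched (sample-exact).
#'
#' @inheritParams extract_qrs_segments
#' @param tmpl a `qrs_template` built at the same sampling rate.
#' @return list with `x_dqrs` (trace after QRS subtraction) and
#'   `coefficients`: a tibble (`beat_time`, `a`, `b`, `residual_energy`)
#'   for the subtracted beats.
#' @export
subtract_qrs <- function(x, fs, beats, tmpl) {
  len <- length(tmpl$template)
  ex <- extract_qrs_segments(x, fs, beats, len / fs)
  tt <- if (is.data.frame(beats)) beats$time else as.numeric(beats)
  x_d <- x
  coefs <- vector("list", length(ex$kept))
  bt <- baseline_trace(x, fs)
  for (k in seq_along(ex$kept)) {
    ix <- ex$starts[k]:(ex$starts[k] + len - 1L)
    seg <- x_d[ix]
    # coefficients come from the baseline-corrected segment; only the
    # fitted complex is subtracted, so the baseline stays continuous
    fit <- fit_beat_projection(seg - bt[ix], tmpl)
    x_d[ix] <- seg - fit$fitted
    coefs[[k]] <- tibble::tibble(beat_time = tt[ex$kept[k]], a = fit$a,
                                 b = fit$b,
                                 residual_energy = fit$residual_energy)
  }
  list(x_dqrs = x_d, coefficients = dplyr::bind_rows(coefs))
}

#' Subtract the average P-T segment at every beat
#'
#' The P and T waves are low-frequency and nearly invariant from beat to
#' beat, so a single beat-aligned average of all P-T windows is computed
#' once and subtracted at every beat. The P-T window of beat i starts at
#' the end of its QRS window (beat time + W/2) and extends `W_PT` seconds,
#' i.e. it covers the T wave through the next P wave when
#' `W_PT = median RR - W`. Samples outside all P-T windows are untouched.
#'
#' @param x_dqrs trace after QRS subtraction.
#' @param fs sampling rate (Hz).
#' @param beats a [beat_times] (>= 2 beats).
#' @param W QRS window width used in the QRS pass (s).
#' @param W_PT P-T window width (s); default `median(RR) - W`.
#' @return list with `x_f` (the cleaned trace) and `pt_average` (the
#'   subtracted waveform).
#' @export
subtract_pt <- function(x_dqrs, fs, beats, W, W_PT = NULL) {
  tt <- if (is.data.frame(beats)) beats$time else as.numeric(beats)
  if (length(tt) < 2L) abort("Need at least 2 beats to average P-T segments.")
  rr <- diff(tt)
  if (is.null(W_PT)) W_PT <- median(rr) - W
  if (W_PT <= 0) abort("`W_PT` must be positive (median RR must exceed W).")
  len_q <- as.integer(round(W * fs))
  center <- len_q %/% 2L + 1L
  len_pt <- as.integer(round(W_PT * fs))
  if (len_pt < 2L) abort("`W_PT` shorter than two samples.")
  ci <- time_to_index(tt, fs)
  starts <- ci + (len_q - center) + 1L  # first sample after the QRS window
  ends <- starts + len_pt - 1L
  ok <- starts >= 1L & ends <= length(x_dqrs)
  if (any(!ok)) {
    inform(sprintf("Dropped %d beat(s) whose P-T window crosses a record boundary.", sum(!ok)))
  }
  if (sum(ok) < 2L) abort("Fewer than 2 complete P-T windows; cannot average.")
  segs <- t(vapply(which(ok), function(i) x_dqrs[starts[i]:ends[i]],
                   numeric(len_pt)))
  pt_avg <- colMeans(segs)
  x_f <- x_dqrs
  for (i in which(ok)) {
    x_f[starts[i]:ends[i]] <- x_f[starts[i]:ends[i]] - pt_avg
  }
  list(x_f = x_f, pt_average = pt_avg, W_PT = W_PT)
}

#' Adaptive maternal P-QRS-T cancellation
#'
#' End-to-end maternal removal on one lead: detect maternal R peaks, build
#' the Gaussian-weighted template and its quadrature (excluding
#' template-dissimilar ectopic beats from the average, correlation < 0.5,
#' though those beats are still subtracted with their own fit), subtract
#' the per-beat two-basis QRS fit, then subtract the mean P-T segment.
#'
#' @param rec an [ecg_record].
#' @param lead lead name or index.
#' @param W QRS window width (s), default 0.12.
#' @param gauss_sigma Gaussian weight SD (s), default `W`.
#' @param W_PT P-T window width (s), default `median(RR) - W`.
#' @param beats optional pre-computed maternal [beat_times]; detected when
#'   missing.
#' @param ectopic_cor_min template-correlation threshold below which a beat
#'   is flagged ectopic and excluded from template averaging.
#' @return an object of class `maternal_cancellation`: list with `x_f`,
#'   `x_dqrs`, `beats` (quality-annotated), `template`, `coefficients`
#'   tibble, `pt_average`, `fs`, `lead`, `W`, `W_PT`.
#' @export
cancel_maternal <- function(rec, lead = 1L, W = 0.12, gauss_sigma = W,
                            W_PT = NULL, beats = NULL,
                            ectopic_cor_min = 0.5) {
  fs <- record_fs(rec)
  x <- lead_signal(rec, lead)
  if (is.null(beats)) beats <- detect_maternal_rpeaks(rec, lead)
  if (nrow(beats) < 2L) abort("Fewer than 2 maternal beats; cannot build a template.")
  bt <- baseline_trace(x, fs)
  debase <- function(ex) {
    t(vapply(seq_along(ex$kept), function(k) {
      ix <- ex$starts[k]:(ex$starts[k] + ncol(ex$segments) - 1L)
      ex$segments[k, ] - bt[ix]
    }, numeric(ncol(ex$segments))))
  }
  ex <- extract_qrs_segments(x, fs, beats, W)
  # first-pass template from all beats, then refine each beat's alignment
  # by template cross-correlation (matched-filter timing is far less noisy
  # than single-sample apex picking) and rebuild
  tmpl0 <- build_qrs_template(debase(ex), fs, gauss_sigma)
  beats <- refine_beat_alignment(x, fs, beats, tmpl0, baseline = bt)
  ex <- extract_qrs_segments(x, fs, beats, W)
  segs_bc <- debase(ex)
  tmpl0 <- build_qrs_template(segs_bc, fs, gauss_sigma)
  g <- gaussian_window(ncol(ex$segments), ex$center, gauss_sigma * fs)
  cors <- apply(segs_bc, 1L, function(s) {
    sw <- s * g
    if (sd(sw) == 0 || sd(tmpl0$template) == 0) 0 else stats::cor(sw, tmpl0$template)
  })
  normal <- cors >= ectopic_cor_min
  # correlation below `artifact_cor_max` means the window is dominated by
  # something other than a maternal complex (e.g. a motion artifact);
  # fitting and subtracting the template there would inject garbage
  artifact_cor_max <- 0.2
  corrupt <- cors < artifact_cor_max
  if (sum(normal) >= 2L) {
    tmpl <- build_qrs_template(segs_bc, fs, gauss_sigma,
                               weights = as.numeric(normal))
  } else {
    warn("Too few template-consistent beats; using all beats in the template.")
    tmpl <- tmpl0
    normal <- rep(TRUE, length(cors))
    corrupt <- rep(FALSE, length(cors))
  }
  quality <- rep("normal", nrow(beats))
  quality[ex$kept[!normal]] <- "ectopic"
  quality[ex$kept[corrupt]] <- "artifact"
  beats_q <- beat_times(beats$time, source = "maternal", quality = quality,
                        refractory = attr(beats, "refractory") %||% 0.2)
  sub_beats <- beats_q[beats_q$quality != "artifact", , drop = FALSE]
  if (nrow(sub_beats) < 2L) sub_beats <- beats_q
  sq <- subtract_qrs(x, fs, sub_beats, tmpl)
  pt <- subtract_pt(sq$x_dqrs, fs, sub_beats, W = W, W_PT = W_PT)
  structure(
    list(x_f = pt$x_f, x_dqrs = sq$x_dqrs, beats = beats_q, template = tmpl,
         coefficients = sq$coefficients, pt_average = pt$pt_average,
         fs = fs, lead = lead, W = W, W_PT = pt$W_PT,
         n_ectopic = sum(!normal)),
    class = "maternal_cancellation"
  )
}

#' @export
print.maternal_cancellation <- function(x, ...) {
  cat(sprintf(
    "<maternal_cancellation> %d beats (%d ectopic-flagged), W = %.0f ms, W_PT = %.0f ms, fs = %g Hz\n",
    nrow(x$beats), x$n_ectopic, x$W * 1000, x$W_PT * 1000, x$fs))
  invisible(x)
}

#' @export
tidy.maternal_cancellation <- function(x, ...) {
  x$coefficients
}

#' @export
glance.maternal_cancellation <- function(x, ...) {
  tibble::tibble(
    n_beats = nrow(x$beats),
    n_ectopic = x$n_ectopic,
    W_s = x$W,
    W_PT_s = x$W_PT,
    mean_a = mean(x$coefficients$a),
    mean_abs_b = mean(abs(x$coefficients$b)),
    median_residual_energy = median(x$coefficients$residual_energy)
  )
}
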