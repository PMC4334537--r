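# Fetal heart-rate-variability battery: cleaned NN series, time-domain
# indices with quartile-mean heart-rate extrema, Poincare SD1/SD2, and
# symbolic dynamics (6 equal levels, word length 3, categories 0V/1V/2V).

#' Build a cleaned NN-interval series from beat times
#'
#' Successive inter-beat intervals within the analysis window, with an
#' automated ectopic/outlier rejection standing in for visual inspection:
#' an interval is rejected when it falls outside `reject_lo`-`reject_hi`
#' times the running median of the last 9 accepted intervals. The series
#' is flagged as qualified only when more than `qualified_min` of the
#' window's intervals survive (by default >95%, the usual
#' qualified-sinus-beat requirement for a 90-s analysis segment).
#'
#' @param beats a [beat_times] (>= 3 beats inside the window).
#' @param window `c(t_start, t_end)` in seconds; default spans all beats.
#' @param reject_lo,reject_hi fixed acceptance band around the running
#'   median (outer bound, always enforced).
#' @param adaptive_k additionally reject intervals further than
#'   `adaptive_k` running MADs from the running median -- on a
#'   low-variability series the fixed-ratio band is far wider than the
#'   physiological spread, so mistimed beats would pass it unchecked.
#'   `Inf` disables the adaptive band.
#' @param adaptive_min_band_ms floor of the adaptive band half-width (ms),
#'   guarding against degenerate (near-constant) series.
#' @param qualified_min minimum accepted fraction for the qualified flag.
#' @return a tibble of class `rr_series` with columns `interval_ms` and
#'   `time` (interval end, s); attributes `n_rejected`,
#'   `qualified_fraction`, `qualified`.
#' @export
build_rr_series <- function(beats, window = NULL, reject_lo = 0.7,
                            reject_hi = 1.3, adaptive_k = 4,
                            adaptive_min_band_ms = 4,
                            qualified_min = 0.95) {
  tt <- if (is.data.frame(beats)) beats$time else as.numeric(beats)
  if (!is.null(window)) tt <- tt[tt >= window[1L] & tt <= window[2L]]
  if (length(tt) < 3L) abort("Need at least 3 beats in the window to form an NN series.")
  iv <- diff(tt) * 1000
  ends <- tt[-1L]
  accepted <- logical(length(iv))
  acc_hist <- numeric(0)
  # adaptive scale from the whole window's robust spread: the median
  # absolute deviation tolerates the occasional mistimed beat, and a
  # global scale cannot collapse the way a running scale of the accepted
  # subset can
  band <- max(adaptive_k * mad(iv), adaptive_min_band_ms)
  for (i in seq_along(iv)) {
    hist9 <- if (length(acc_hist) >= 3L) tail(acc_hist, 9L) else head(iv, 9L)
    ref <- median(hist9)
    ok <- iv[i] >= reject_lo * ref && iv[i] <= reject_hi * ref &&
      (is.infinite(adaptive_k) || abs(iv[i] - ref) <= band)
    if (ok) {
      accepted[i] <- TRUE
      acc_hist <- c(acc_hist, iv[i])
    }
  }
  qf <- mean(accepted)
  out <- tibble::tibble(interval_ms = iv[accepted], time = ends[accepted])
  class(out) <- c("rr_series", class(out))
  attr(out, "n_rejected") <- sum(!accepted)
  attr(out, "qualified_fraction") <- qf
  attr(out, "qualified") <- qf > qualified_min
  if (qf <= qualified_min) {
    warn(sprintf("Only %.1f%% of intervals qualified (need > %.0f%%); metrics will be flagged.",
                 100 * qf, 100 * qualified_min))
  }
  out
}

#' Time-domain HRV metrics
#'
#' Mean heart rate, SDNN (sample SD of NN intervals, n-1 denominator), and
#' quartile-mean extrema: the maximum heart rate is the mean of the upper
#' quartile of beatwise heart rates (the `ceiling(n/4)` largest) and the
#' minimum the mean of the lower quartile -- robust analogues of max/min
#' for short fetal segments.
#'
#' @param rr an `rr_series` (or numeric intervals, ms).
#' @return a one-row tibble: `mean_hr`, `min_hr`, `max_hr` (bpm),
#'   `sdnn_ms`, `n_intervals`, `qualified`.
#' @export
time_domain_metrics <- function(rr) {
  iv <- if (is.data.frame(rr)) rr$interval_ms else as.numeric(rr)
  if (length(iv) < 2L) abort("Need at least 2 NN intervals.")
  hr <- 60000 / iv
  k <- ceiling(length(hr) / 4)
  hs <- sort(hr)
  tibble::tibble(
    mean_hr = mean(hr),
    min_hr = mean(hs[seq_len(k)]),
    max_hr = mean(hs[seq.int(length(hs) - k + 1L, length(hs))]),
    sdnn_ms = sd(iv),
    n_intervals = length(iv),
    qualified = isTRUE(attr(rr, "qualified")) || is.null(attr(rr, "qualified"))
  )
}

#' Poincare-plot descriptors SD1 and SD2
#'
#' From the scatter of each NN interval against the previous one, SD1 is
#' the dispersion across the identity line (short-term, vagally mediated
#' variability) and SD2 the dispersion along it (long-term variability):
#' `SD1 = sd((x[n] - x[n+1]) / sqrt(2))`,
#' `SD2 = sd((x[n] + x[n+1]) / sqrt(2))` over successive pairs. The ratio
#' SD1/SD2 is `NA` (flagged undefined) when SD2 = 0.
#'
#' @param rr an `rr_series` (or numeric intervals, ms), >= 3 intervals.
#' @return a one-row tibble: `sd1_ms`, `sd2_ms`, `sd1_sd2`,
#'   `ratio_defined`.
#' @export
poincare_metrics <- function(rr) {
  iv <- if (is.data.frame(rr)) rr$interval_ms else as.numeric(rr)
  if (length(iv) < 3L) abort("Need at least 3 NN intervals for a Poincare plot.")
  a <- iv[-length(iv)]
  b <- iv[-1L]
  sd1 <- sd((a - b) / sqrt(2))
  sd2 <- sd((a + b) / sqrt(2))
  tibble::tibble(
    sd1_ms = sd1,
    sd2_ms = sd2,
    sd1_sd2 = if (sd2 > 0) sd1 / sd2 else NA_real_,
    ratio_defined = sd2 > 0
  )
}

# Quantise intervals into 6 equal levels spanning [min, max]; a value equal
# to the maximum maps to level 5 (clip), avoiding a spurious 7th level.
symbolic_levels <- function(iv) {
  rng <- range(iv)
  if (rng[1L] == rng[2L]) return(rep(0L, length(iv)))
  lev <- floor(6 * (iv - rng[1L]) / (rng[2L] - rng[1L]))
  pmin(as.integer(lev), 5L)
}

# Classify one length-3 symbol word: 0V (no level change), 1V (exactly one
# of the two transitions changes level), 2V (both change).
classify_word <- function(s1, s2, s3) {
  c12 <- s1 != s2
  c23 <- s2 != s3
  if (!c12 && !c23) "0V" else if (c12 && c23) "2V" else "1V"
}

#' Symbolic-dynamics HRV metrics (0V / 1V / 2V)
#'
#' NN intervals are quantised into 6 equally spaced levels between the
#' series minimum and maximum; all overlapping length-3 words are
#' classified by their number of level changes: 0V (none; sympathetic
#' predominance marker), 1V (one), 2V (two; vagal marker). Proportions sum
#' to 1 over the word set.
#'
#' @param rr an `rr_series` (or numeric intervals, ms), >= 3 intervals.
#' @return a one-row tibble: `p0v`, `p1v`, `p2v`, `n_words`.
#' @export
symbolic_dynamics <- function(rr) {
  iv <- if (is.data.frame(rr)) rr$interval_ms else as.numeric(rr)
  if (length(iv) < 3L) abort("Need at least 3 NN intervals for length-3 words.")
  s <- symbolic_levels(iv)
  n <- length(s) - 2L
  cls <- vapply(seq_len(n), function(i) classify_word(s[i], s[i + 1L], s[i + 2L]),
                character(1))
  tibble::tibble(
    p0v = mean(cls == "0V"),
    p1v = mean(cls == "1V"),
    p2v = mean(cls == "2V"),
    n_words = n
  )
}

#' Full HRV battery for one NN series
#'
#' @param rr an `rr_series`.
#' @return an object of class `fhr_hrv`: list with the `rr` series and the
#'   three metric tibbles; `tidy()` gives a long metric table, `glance()`
#'   a one-row wide summary.
#' @export
hrv_metrics <- function(rr) {
  structure(
    list(rr = rr,
         time_domain = time_domain_metrics(rr),
         poincare = poincare_metrics(rr),
         symbolic = symbolic_dynamics(rr),
         qualified_fraction = attr(rr, "qualified_fraction") %||% NA_real_),
    class = "fhr_hrv"
  )
}

#' @export
print.fhr_hrv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<fhr_hrv> %d NN intervals | HR %.1f (%.1f-%.1f) bpm | SDNN %.2f ms | SD1 %.2f SD2 %.2f | 0V %.2f 1V %.2f 2V %.2f\n",
    g$n_intervals, g$mean_hr, g$min_hr, g$max_hr, g$sdnn_ms, g$sd1_ms,
    g$sd2_ms, g$p0v, g$p1v, g$p2v))
  invisible(x)
}

#' @export
glance.fhr_hrv <- function(x, ...) {
  dplyr::bind_cols(
    x$time_domain[c("mean_hr", "min_hr", "max_hr", "sdnn_ms", "n_intervals", "qualified")],
    x$poincare[c("sd1_ms", "sd2_ms", "sd1_sd2")],
    x$symbolic[c("p0v", "p1v", "p2v", "n_words")],
    tibble::tibble(qualified_fraction = x$qualified_fraction)
  )
}

#' @export
tidy.fhr_hrv <- function(x, ...) {
  g <- glance(x)
  tidyr::pivot_longer(g[setdiff(names(g), c("qualified", "n_intervals", "n_words"))],
                      dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' Per-stage HRV report
#'
#' Computes the full HRV battery over labelled time windows (analysis
#' stages, e.g. baseline / after anesthesia / before delivery). Each stage
#' uses the first qualified `segment_len`-second sub-window (default 90 s,
#' stepping by 10 s) when the stage is longer than `segment_len`; stages
#' with too few beats yield a flagged row rather than an error.
#'
#' @param beats fetal [beat_times].
#' @param stages a data frame with columns `label`, `t_start`, `t_end`
#'   (s).
#' @param segment_len analysis segment length (s), default 90; `NULL`
#'   uses each whole stage window.
#' @param segment_step search step for a qualified segment (s).
#' @return a tibble, one row per stage: stage columns, `n_beats`,
#'   `qualified_fraction`, all HRV metrics, and a `flags` column
#'   (`""`, `"unqualified"`, or `"too_few_beats"`).
#' @export
stage_report <- function(beats, stages, segment_len = 90, segment_step = 10) {
  stopifnot(all(c("label", "t_start", "t_end") %in% names(stages)))
  rows <- lapply(seq_len(nrow(stages)), function(i) {
    st <- stages[i, ]
    base <- tibble::tibble(stage = st$label, t_start = st$t_start, t_end = st$t_end)
    empty <- dplyr::bind_cols(base, tibble::tibble(
      n_beats = 0L, qualified_fraction = NA_real_, mean_hr = NA_real_,
      min_hr = NA_real_, max_hr = NA_real_, sdnn_ms = NA_real_,
      sd1_ms = NA_real_, sd2_ms = NA_real_, sd1_sd2 = NA_real_,
      p0v = NA_real_, p1v = NA_real_, p2v = NA_real_,
      flags = "too_few_beats"))
    inwin <- beats$time[beats$time >= st$t_start & beats$time <= st$t_end]
    if (length(inwin) < 4L) return(empty)
    empty$n_beats <- length(inwin)
    # choose the analysis sub-window: first qualified segment, else the
    # best-qualified one
    stage_span <- st$t_end - st$t_start
    starts <- if (is.null(segment_len) || segment_len >= stage_span) {
      st$t_start
    } else {
      seq(st$t_start, st$t_end - segment_len, by = segment_step)
    }
    seg_len_i <- if (is.null(segment_len)) stage_span else min(segment_len, stage_span)
    best <- NULL
    for (s0 in starts) {
      rr <- tryCatch(
        suppressWarnings(build_rr_series(beats, window = c(s0, s0 + seg_len_i))),
        error = function(e) NULL
      )
      if (is.null(rr) || nrow(rr) < 3L) next
      if (is.null(best) ||
          attr(rr, "qualified_fraction") > attr(best, "qualified_fraction")) {
        best <- rr
      }
      if (isTRUE(attr(rr, "qualified"))) break
    }
    if (is.null(best)) return(empty)
    h <- glance(hrv_metrics(best))
    dplyr::bind_cols(base, tibble::tibble(
      n_beats = length(inwin),
      qualified_fraction = attr(best, "qualified_fraction"),
      mean_hr = h$mean_hr, min_hr = h$min_hr, max_hr = h$max_hr,
      sdnn_ms = h$sdnn_ms, sd1_ms = h$sd1_ms, sd2_ms = h$sd2_ms,
      sd1_sd2 = h$sd1_sd2, p0v = h$p0v, p1v = h$p1v, p2v = h$p2v,
      flags = if (isTRUE(attr(best, "qualified"))) "" else "unqualified"))
  })
  dplyr::bind_rows(rows)
}
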