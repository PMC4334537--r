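test_that("a pure tone concentrates spectrogram power at its frequency", {
  fs <- 1000
  t <- (0:(2 * fs - 1)) / fs
  sp <- gabor_spectrogram(sin(2 * pi * 15 * t), fs)
  interior <- which(sp$frame_times > 0.2 & sp$frame_times < 1.8)
  bin15 <- which.min(abs(sp$freqs - 15))
  dfreq <- sp$freqs[2] - sp$freqs[1]
  for (k in interior[seq(1, length(interior), by = 25)]) {
    expect_lte(abs(sp$freqs[which.max(sp$power[k, ])] - sp$freqs[bin15]),
               dfreq + 1e-9)
  }
})

test_that("an impulse excites only the frames that cover it", {
  fs <- 1000
  x <- numeric(fs)
  x[500] <- 1
  sp <- gabor_spectrogram(x, fs)
  tot <- rowSums(sp$power)
  covered <- abs(sp$frame_times - 0.499) <= sp$window_len / 2
  expect_gt(sum(tot[covered]), 0)
  expect_equal(sum(tot[!covered]), 0, tolerance = 1e-20)
})

test_that("each frame equals the brute-force windowed DFT magnitude", {
  fs <- 500
  set.seed(21)
  x <- rnorm(2 * fs)
  sp <- gabor_spectrogram(x, fs, window_len = 0.128, hop = 0.016)
  lw <- round(0.128 * fs)
  w <- fhrv:::gaussian_window(lw, (lw + 1) / 2, lw / 6)
  nfft <- sp$nfft
  nb <- nfft %/% 2 + 1
  mult <- rep(2, nb); mult[1] <- 1
  if (nfft %% 2 == 0) mult[nb] <- 1
  starts <- seq(1, length(x) - lw + 1, by = round(0.016 * fs))
  for (k in seq(1, length(starts), by = 7)) {
    slice <- c(x[starts[k]:(starts[k] + lw - 1)] * w, numeric(nfft - lw))
    ref <- Mod(fft(slice)[1:nb])^2 * mult / nfft
    expect_lt(max(abs(sp$power[k, ] - ref)), 1e-9)
  }
  # Parseval: one-sided power sums to the windowed-slice energy
  k <- 3
  slice <- x[starts[k]:(starts[k] + lw - 1)] * w
  expect_rel_equal(sum(sp$power[k, ]), sum(slice^2), 1e-6)
})

test_that("band selection finds the fetal band and falls back on noise", {
  fs <- 1000
  withr::with_seed(22, {
    tt <- cumsum(rep(0.444, 40))
    xf <- 0.2 * render_ecg_from_beats(tt, fs, duration = 19,
                                      morphology = fetal_morphology()) +
      rnorm(19000, sd = 0.02)
    sel <- select_fetal_band(gabor_spectrogram(xf, fs))
    expect_false(sel$fallback)
    expect_true(sel$band[1] <= 15 && sel$band[2] >= 15)

    noise <- select_fetal_band(gabor_spectrogram(rnorm(15000), fs))
    expect_true(noise$fallback)
    expect_equal(noise$band, c(10, 20))
  })
  # band beyond Nyquist must error
  expect_error(select_fetal_band(gabor_spectrogram(rnorm(400), 40)), "Nyquist")
})

test_that("band integration equals brute-force bin summation", {
  fs <- 1000
  t <- (0:(2 * fs - 1)) / fs
  sp <- gabor_spectrogram(sin(2 * pi * 15 * t), fs)
  inb <- integrate_band_power(sp, c(10, 20))
  outb <- integrate_band_power(sp, c(30, 40))
  interior <- sp$frame_times > 0.2 & sp$frame_times < 1.8
  expect_gt(min(inb$power[interior]), 100 * max(outb$power[interior]))
  # interior frames of a stationary tone are near-constant
  expect_lt(sd(inb$power[interior]) / mean(inb$power[interior]), 0.01)

  set.seed(23)
  spr <- gabor_spectrogram(rnorm(1500), fs)
  cols <- which(spr$freqs >= 12 & spr$freqs <= 27)
  expect_equal(integrate_band_power(spr, c(12, 27))$power,
               rowSums(spr$power[, cols]))
  expect_error(integrate_band_power(spr, c(20, 20)), "band")
})

test_that("order-statistic envelope matches a nested-loop oracle", {
  brute <- function(v, wl, alpha) {
    h <- wl %/% 2
    w <- fhrv:::tukey_window(wl, alpha)
    vapply(seq_along(v), function(k) {
      m <- -Inf
      for (j in max(1, k - h):min(length(v), k + h)) {
        m <- max(m, v[j] * w[j - k + h + 1])
      }
      m
    }, numeric(1))
  }
  set.seed(24)
  for (r in 1:10) {
    v <- abs(rnorm(500))
    env <- order_statistic_envelope(v, 21L, 0.5)
    expect_identical(env, brute(v, 21L, 0.5))
    expect_true(all(env >= v))
  }
  # constant series: unit-peak window keeps the envelope at the constant
  expect_equal(order_statistic_envelope(rep(3, 100), 21L, 0.5), rep(3, 100))
  # rectangular limit dilates a spike over the window span
  v <- numeric(101); v[51] <- 1
  env <- order_statistic_envelope(v, 21L, 0)
  expect_true(all(env[41:61] == 1))
  expect_true(all(env[c(1:40, 62:101)] == 0))
  # widening the window can only raise the envelope
  set.seed(25)
  v <- abs(rnorm(300))
  e1 <- order_statistic_envelope(v, 11L, 0.5)
  e2 <- order_statistic_envelope(v, 31L, 0.5)
  expect_true(all(e2 >= e1 - 1e-12))
  expect_error(order_statistic_envelope(v, 10L, 0.5), "odd")
})

test_that("peak picking respects the refractory rule and bump apexes", {
  hop <- 0.004
  tgrid <- seq(0, 4, by = hop)
  mk_bp <- function(v) {
    bp <- tibble::tibble(frame_time = tgrid, power = v)
    attr(bp, "hop") <- hop
    class(bp) <- c("band_power_series", class(bp))
    bp
  }
  # one Gaussian bump -> one beat at its apex
  v <- exp(-0.5 * ((tgrid - 2) / 0.03)^2) + 1e-3
  pk <- detect_fetal_peaks(mk_bp(v), refine = FALSE)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$time, 2, tolerance = hop)
  # two bumps 0.1 s apart with min_rr 0.25 -> the larger survives
  v2 <- exp(-0.5 * ((tgrid - 2) / 0.02)^2) +
    0.6 * exp(-0.5 * ((tgrid - 2.1) / 0.02)^2) + 1e-3
  pk2 <- detect_fetal_peaks(mk_bp(v2), refine = FALSE)
  expect_equal(nrow(pk2), 1L)
  expect_equal(pk2$time, 2, tolerance = hop)
})

test_that("detection is invariant to global amplitude scaling", {
  run <- default_chain(41)
  fs <- run$canc$fs
  a <- suppressMessages(detect_fetal_beats(run$canc$x_f, fs = fs))
  b <- suppressMessages(detect_fetal_beats(run$canc$x_f * 37.5, fs = fs))
  expect_equal(a$time, b$time, tolerance = 1e-9)
})

test_that("pseudo-peak rejection drops weak peaks and keeps uniform ones", {
  bp <- tibble::tibble(frame_time = seq(0, 10, by = 0.004),
                       power = rep(1e-3, 2501))
  class(bp) <- c("band_power_series", class(bp))
  attr(bp, "hop") <- 0.004
  # uniform prominences, no maternal beats: a no-op
  beats <- beat_times(seq(0.5, 9.5, by = 0.45), source = "fetal",
                      power = rep(1, 21))
  out <- reject_pseudo_peaks(beats, bp)
  expect_equal(out$time, beats$time)
  # one grossly weak peak violates the prominence rule
  pw <- rep(1, 21); pw[11] <- 0.01
  weak <- beat_times(seq(0.5, 9.5, by = 0.45), source = "fetal", power = pw)
  out2 <- suppressMessages(reject_pseudo_peaks(weak, bp))
  expect_equal(nrow(out2), 20L)
  expect_equal(attr(out2, "removed")$reason, "low_prominence")
  # empty input passes through
  empty <- beat_times(numeric(0), source = "fetal", power = numeric(0))
  expect_equal(nrow(reject_pseudo_peaks(empty, bp)), 0L)
})

test_that("a maternal-residue coincident peak is rejected, true beats kept", {
  # construct a cleaned trace whose only content is fetal beats plus one
  # maternal-template residue spike at a known maternal time
  fs <- 1000
  msyn <- maternal_only_record(seed = 6, duration = 30)
  ex <- extract_qrs_segments(lead_signal(msyn$record, 1), fs,
                             msyn$truth$maternal_beats, 0.12)
  tmpl <- build_qrs_template(ex, fs)
  tf <- cumsum(c(1, rep(0.45, 40)))
  x_f <- 0.2 * render_ecg_from_beats(tf, fs, duration = 21,
                                     morphology = fetal_morphology())
  mt <- 10.11  # residue injection instant, well away from fetal beats
  stopifnot(min(abs(tf - mt)) > 0.1)
  i0 <- round(mt * fs) + 1L - (tmpl$center - 1L)
  ix <- i0:(i0 + length(tmpl$template) - 1L)
  x_f[ix] <- x_f[ix] + 0.35 * tmpl$template
  maternal <- beat_times(mt, source = "maternal")
  det <- suppressMessages(detect_fetal_beats(
    x_f, fs = fs, maternal_beats = maternal, template = tmpl))
  # the injected residue must not survive as a fetal beat
  expect_false(any(abs(det$time - mt) < 0.05))
  m <- match_beats(det, tf[tf > 0.5 & tf < 20.5], tol = 0.05)
  expect_gt(m$sensitivity, 0.95)
})
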