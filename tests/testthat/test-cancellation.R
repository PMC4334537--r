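test_that("maternal R peaks are found within 10 ms on clean input", {
  syn <- maternal_only_record(seed = 3)
  truth <- syn$truth$maternal_beats
  mb <- detect_maternal_rpeaks(syn$record)
  expect_equal(nrow(mb), nrow(truth))
  err <- vapply(truth$time, function(t) min(abs(mb$time - t)), numeric(1))
  expect_true(all(err <= 0.010))
})

test_that("degenerate inputs give empty maternal detections with a warning", {
  flat <- ecg_record(matrix(0, 10000, 1), fs = 1000)
  expect_warning(mb <- detect_maternal_rpeaks(flat), "maternal")
  expect_equal(nrow(mb), 0L)
  short <- ecg_record(matrix(rnorm(1000), ncol = 1), fs = 1000)
  expect_error(detect_maternal_rpeaks(short), "short")
})

test_that("maternal detection does not report fetal beats on composites", {
  run <- default_chain(41)
  mb <- run$canc$beats
  tf <- run$syn$truth$fetal_beats$time
  tm <- run$syn$truth$maternal_beats$time
  # fetal truth times isolated from any true maternal beat
  isolated <- tf[vapply(tf, function(t) min(abs(tm - t)) > 0.1, logical(1))]
  near_fetal <- vapply(isolated, function(t) min(abs(mb$time - t)) < 0.03,
                       logical(1))
  expect_equal(sum(near_fetal), 0L)
})

test_that("segment extraction obeys length, centring and edge rules", {
  fs <- 2000
  x <- rnorm(2 * fs)
  ex <- extract_qrs_segments(x, fs, c(0.5, 1.0), W = 0.1)
  expect_equal(ncol(ex$segments), 200L)
  expect_equal(ex$center, 101L)

  # an edge beat is dropped with a message
  expect_message(ex2 <- extract_qrs_segments(x, fs, c(0.01, 1.0), W = 0.1),
                 "Dropped")
  expect_equal(ex2$kept, 2L)

  # delta spikes at the beat samples land on the centre sample
  xs <- numeric(2 * fs)
  beats <- c(0.5, 0.9, 1.4)
  xs[round(beats * fs) + 1L] <- 1
  ex3 <- extract_qrs_segments(xs, fs, beats, W = 0.1)
  expect_true(all(ex3$segments[, ex3$center] == 1))
  expect_equal(rowSums(ex3$segments), rep(1, 3))
  expect_error(extract_qrs_segments(x, fs, 0.5, W = 0), "W")
})

test_that("the template is the Gaussian-weighted average of the segments", {
  fs <- 1000
  s <- sin(seq(0, 3 * pi, length.out = 120)) * exp(-((1:120) - 60)^2 / 500)
  segs <- rbind(s, s, s)
  tmpl <- build_qrs_template(segs, fs, gauss_sigma = 0.024)
  g <- fhrv:::gaussian_window(120, 61, 0.024 * fs)
  expect_equal(tmpl$template, s * g, tolerance = 1e-12)
  expect_equal(tmpl$n_beats_averaged, 3L)

  # opposite-sign pair averages to zero: degenerate, must error
  expect_error(build_qrs_template(rbind(s, -s), fs), "zero")
  expect_error(build_qrs_template(segs[1, , drop = FALSE], fs), "2 aligned")
})

test_that("template noise shrinks like 1/sqrt(L)", {
  fs <- 1000
  s <- sin(seq(0, 3 * pi, length.out = 120)) * exp(-((1:120) - 60)^2 / 500)
  g <- fhrv:::gaussian_window(120, 61, 0.024 * fs)
  rms_err <- function(L, seed) {
    set.seed(seed)
    segs <- t(replicate(L, s + rnorm(120, sd = 0.3)))
    tmpl <- build_qrs_template(segs, fs, gauss_sigma = 0.024)
    sqrt(mean((tmpl$template - s * g)^2))
  }
  # average over replications so the ratio estimate is stable
  e4 <- mean(vapply(1:12, function(r) rms_err(4L, r), numeric(1)))
  e16 <- mean(vapply(1:12, function(r) rms_err(16L, 100 + r), numeric(1)))
  e64 <- mean(vapply(1:12, function(r) rms_err(64L, 200 + r), numeric(1)))
  expect_gt(e4 / e16, 2 / 1.5)
  expect_lt(e4 / e16, 2 * 1.5)
  expect_gt(e16 / e64, 2 / 1.5)
  expect_lt(e16 / e64, 2 * 1.5)
})

test_that("the quadrature of a cosine burst is the sine burst", {
  fs <- 1000
  n <- 512
  t <- (0:(n - 1)) / fs
  w <- fhrv:::tukey_window(n, 0.4)
  x <- cos(2 * pi * 25 * t) * w
  q <- analytic_quadrature(x)
  ref <- sin(2 * pi * 25 * t) * w
  interior <- 60:(n - 60)
  expect_lt(max(abs(q[interior] - ref[interior])), 0.01 * max(abs(ref)))
})

test_that("template and quadrature are numerically orthogonal", {
  set.seed(4)
  for (r in 1:20) {
    len <- sample(80:300, 1)
    tmpl <- rnorm(len) * fhrv:::gaussian_window(len, len %/% 2 + 1, len / 6)
    o <- hilbert_orthogonal_basis(tmpl)
    tc <- tmpl - mean(tmpl)
    ip <- abs(sum(tc * o)) / (sqrt(sum(tc^2)) * sqrt(sum(o^2)))
    expect_lt(ip, 1e-6)
  }
  expect_error(hilbert_orthogonal_basis(numeric(100)), "zero")
})

test_that("beat projection reproduces the least-squares solution", {
  syn <- maternal_only_record(seed = 6, duration = 30)
  fs <- record_fs(syn$record)
  x <- lead_signal(syn$record, 1)
  ex <- extract_qrs_segments(x, fs, syn$truth$maternal_beats, 0.12)
  tmpl <- build_qrs_template(ex, fs)

  # self-projection and quadrature projection are exact unit vectors
  f1 <- fit_beat_projection(tmpl$template, tmpl)
  expect_equal(c(f1$a, f1$b), c(1, 0), tolerance = 1e-9)
  expect_lt(f1$residual_energy, 1e-18)
  f2 <- fit_beat_projection(tmpl$ortho, tmpl)
  expect_equal(c(f2$a, f2$b), c(0, 1), tolerance = 1e-9)

  # random segments match the 2x2 normal-equation oracle
  set.seed(8)
  G <- rbind(c(sum(tmpl$template^2), sum(tmpl$template * tmpl$ortho)),
             c(sum(tmpl$template * tmpl$ortho), sum(tmpl$ortho^2)))
  for (r in 1:50) {
    seg <- rnorm(length(tmpl$template))
    fit <- fit_beat_projection(seg, tmpl)
    ab <- solve(G, c(sum(seg * tmpl$template), sum(seg * tmpl$ortho)))
    expect_rel_equal(fit$a, ab[1], 1e-6)
    expect_rel_equal(fit$b, ab[2], 1e-6)
  }
  expect_error(fit_beat_projection(rnorm(10), tmpl), "length")
})

test_that("subtracting exact template copies cancels them to round-off", {
  fs <- 1000
  syn <- maternal_only_record(seed = 6, duration = 30)
  x0 <- lead_signal(syn$record, 1)
  ex <- extract_qrs_segments(x0, fs, syn$truth$maternal_beats, 0.12)
  tmpl <- build_qrs_template(ex, fs)
  beats <- seq(1, 19, by = 0.8)
  x <- numeric(20 * fs)
  for (tau in beats) {
    i0 <- round(tau * fs) + 1L - (tmpl$center - 1L)
    x[i0:(i0 + length(tmpl$template) - 1L)] <- tmpl$template
  }
  res <- subtract_qrs(x, fs, beats, tmpl)
  expect_lt(sqrt(mean(res$x_dqrs^2)), 1e-9 * sqrt(mean(x^2)))
  expect_equal(res$coefficients$a, rep(1, length(beats)), tolerance = 1e-6)
})

test_that("two-basis subtraction beats fixed-template subtraction per beat", {
  syn <- compose_abdominal(synth_config(seed = 12, fetal_amp_ratio = 0,
                                        emg_snr_db = Inf, wander_amp = 0,
                                        artifact_rate = 0, resp_mod_depth = 0.25))
  fs <- record_fs(syn$record)
  x <- lead_signal(syn$record, 1)
  ex <- extract_qrs_segments(x, fs, syn$truth$maternal_beats, 0.12)
  tmpl <- build_qrs_template(ex, fs)
  bt <- fhrv:::baseline_trace(x, fs)
  worse <- 0L
  for (k in seq_along(ex$kept)) {
    ix <- ex$starts[k]:(ex$starts[k] + length(tmpl$template) - 1L)
    seg <- x[ix] - bt[ix]
    fit <- fit_beat_projection(seg, tmpl)
    res_fixed <- sum((seg - tmpl$template)^2)
    if (fit$residual_energy > res_fixed + 1e-9) worse <- worse + 1L
    expect_lte(fit$residual_energy, res_fixed + 1e-9)
  }
  expect_equal(worse, 0L)

  # the optimality is structural: it holds for arbitrary input too
  set.seed(13)
  xr <- rnorm(length(x))
  exr <- extract_qrs_segments(xr, fs, syn$truth$maternal_beats, 0.12)
  for (k in seq_len(min(20, nrow(exr$segments)))) {
    seg <- as.numeric(exr$segments[k, ])
    fit <- fit_beat_projection(seg, tmpl)
    expect_lte(fit$residual_energy, sum((seg - tmpl$template)^2) + 1e-9)
  }
})

test_that("the signal outside all QRS windows is untouched, sample-exact", {
  run <- default_chain(41)
  x <- lead_signal(run$syn$record, 1)
  fs <- record_fs(run$syn$record)
  canc <- run$canc
  len_q <- round(canc$W * fs)
  center <- len_q %/% 2 + 1
  len_pt <- round(canc$W_PT * fs)
  inside <- logical(length(x))
  for (tau in canc$beats$time) {
    ci <- round(tau * fs) + 1
    s0 <- ci - center + 1
    s1 <- s0 + len_q + len_pt - 1  # QRS window plus abutting P-T window
    inside[max(1, s0):min(length(x), s1)] <- TRUE
  }
  expect_identical(canc$x_f[!inside], x[!inside])
})

test_that("a maternal template barely touches a fetal-only trace", {
  fs <- 1000
  msyn <- maternal_only_record(seed = 6, duration = 30)
  ex <- extract_qrs_segments(lead_signal(msyn$record, 1), fs,
                             msyn$truth$maternal_beats, 0.12)
  tmpl <- build_qrs_template(ex, fs)

  tf <- cumsum(c(0.7, rep(0.43, 60)))
  xf <- 0.2 * render_ecg_from_beats(tf, fs, duration = 28,
                                    morphology = fetal_morphology())
  fake_maternal <- seq(1, 26, by = 0.8)
  res <- subtract_qrs(xf, fs, fake_maternal, tmpl)
  before <- amp_at_beats(xf, tf[tf < 27], fs)
  after <- amp_at_beats(res$x_dqrs, tf[tf < 27], fs)
  expect_lt(median(1 - after / before), 0.10)
})

test_that("mean P-T subtraction removes identical P-T morphology exactly", {
  fs <- 1000
  beats <- seq(1, 29, by = 1)
  x <- numeric(30 * fs)
  tg <- (seq_len(length(x)) - 1) / fs
  for (tau in beats) x <- x + 0.3 * exp(-0.5 * ((tg - tau - 0.3) / 0.06)^2)
  pt <- subtract_pt(x, fs, beats, W = 0.12, W_PT = 0.8)
  # inside the P-T windows the identical bump is gone
  idx <- unlist(lapply(beats, function(tau) {
    (round(tau * fs) + 250):(round(tau * fs) + 600)
  }))
  idx <- idx[idx <= length(x)]
  expect_lt(max(abs(pt$x_f[idx])), 1e-9)
})

test_that("a single outlier P-T segment leaves the (1 - 1/L) residual", {
  fs <- 1000
  L <- 50
  beats <- seq(1, by = 1, length.out = L)
  x <- numeric((L + 2) * fs)
  tg <- (seq_len(length(x)) - 1) / fs
  for (k in seq_len(L)) {
    amp <- if (k == 25) 2 else 1
    x <- x + amp * exp(-0.5 * ((tg - beats[k] - 0.3) / 0.05)^2)
  }
  pt <- subtract_pt(x, fs, beats, W = 0.12, W_PT = 0.8)
  i_out <- round((beats[25] + 0.3) * fs) + 1L
  i_typ <- round((beats[10] + 0.3) * fs) + 1L
  expect_equal(pt$x_f[i_out], (1 - 1 / L) * (2 - 1), tolerance = 1e-6)
  expect_equal(pt$x_f[i_typ], -(1 / L) * (2 - 1), tolerance = 1e-6)
})

test_that("mean P-T subtraction does not inflate white-noise variance", {
  fs <- 500
  set.seed(15)
  for (r in 1:5) {
    x <- rnorm(20 * fs)
    beats <- sort(runif(18, 1, 18))
    beats <- beats[c(TRUE, diff(beats) > 0.5)]
    if (length(beats) < 3) next
    w_pt <- min(diff(beats)) - 0.15
    pt <- suppressMessages(subtract_pt(x, fs, beats, W = 0.12, W_PT = w_pt))
    len_q <- round(0.12 * fs)
    idx <- unlist(lapply(beats, function(tau) {
      s0 <- round(tau * fs) + 1 + (len_q - (len_q %/% 2 + 1)) + 1
      s0:(s0 + round(w_pt * fs) - 1)
    }))
    idx <- idx[idx >= 1 & idx <= length(x)]
    L <- length(beats)
    expect_lte(var(pt$x_f[idx]), var(x[idx]) * (1 + 2 / L))
  }
})

test_that("cancel_maternal suppresses maternal complexes on clean input", {
  syn <- maternal_only_record(seed = 3)
  fs <- record_fs(syn$record)
  x <- lead_signal(syn$record, 1)
  canc <- suppressMessages(cancel_maternal(syn$record))
  red <- 1 - amp_at_beats(canc$x_f, syn$truth$maternal_beats$time, fs) /
    amp_at_beats(x, syn$truth$maternal_beats$time, fs)
  expect_gt(median(red), 0.95)
  # orthogonality invariant of the shipped template
  tc <- canc$template$template - mean(canc$template$template)
  o <- canc$template$ortho
  expect_lt(abs(sum(tc * o)) / (sqrt(sum(tc^2)) * sqrt(sum(o^2))), 1e-6)
})
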