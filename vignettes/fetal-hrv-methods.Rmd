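---
title: "Extracting fetal heart rate and its variability from abdominal ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting fetal heart rate and its variability from abdominal ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Electrodes on a pregnant woman's abdomen record a superposition of the
maternal electrocardiogram, a fetal electrocardiogram some five to ten
times smaller, baseline drift from respiration and electrode motion,
broadband electromyographic (EMG) noise from abdominal muscle, and, in an
operating-room setting, occasional large motion artifacts. The fetal
R peaks — the events that carry fetal heart rate (FHR) and its
variability — are invisible to simple thresholding of the raw trace. The
package implements a two-stage extraction: adaptive cancellation of the
maternal P-QRS-T complex, then time-frequency detection of the fetal QRS
in the cleaned residual, followed by a standard fetal heart-rate
variability (HRV) battery.

## Maternal P-QRS-T cancellation

Maternal R peaks are first detected with an energy detector from the
Pan-Tompkins family (band-pass 5–25 Hz, squared derivative, 120 ms
moving integration, adaptive threshold, 250 ms refractory), hardened in
three standard ways: the threshold centre is the median of the top-N
detection peaks with N set by a plausible maternal rate, so a few huge
motion artifacts cannot inflate it; detection peaks more than ten times
the beat level are classed as artifacts and their neighbourhood excluded;
and double-length RR gaps trigger a search-back at reduced threshold.

For each beat, a rectangular window of width `W` (default 120 ms) centred
on the R apex is cut out. The Gaussian-weighted average of these windows
is the QRS template; its Hilbert-transform quadrature — the imaginary
part of the discrete analytic signal — supplies a second basis that is
numerically orthogonal to the template (the cross-spectrum of a real
sequence with its quadrature is odd across frequency and zero at DC, so
the inner product vanishes to round-off). Each beat is then fitted as
`a * template + b * quadrature` by independent projections (legitimate
because the bases are orthogonal), and the fitted complex is subtracted
in place. The two degrees of freedom absorb the beat-to-beat amplitude
and phase drift that respiration imposes on the projection of the cardiac
vector, which is exactly what defeats a fixed template.

Three numerical choices matter and are worth recording:

* **Gaussian weight width.** The taper `G(t)` applied to the averaged
  wave has standard deviation `gauss_sigma`, default `W`. A much narrower
  taper visibly narrows the template's R lobe relative to the true beat,
  and the resulting width-mismatch residue concentrates at 10–20 Hz —
  precisely the fetal detection band. With `gauss_sigma = W` the weight
  is nearly flat over the QRS support and still rolls the window edges
  off smoothly.
* **Template mean.** The template keeps its natural (nonzero) mean. The
  quadrature has no DC component, so orthogonality does not require mean
  removal — and subtracting a mean-removed template injects a DC pedestal
  into every beat window, whose edges then ring across the spectrum.
* **Baseline de-biasing.** Because the template mean is nonzero, a local
  baseline offset of `delta` biases the fitted scale by roughly
  `0.93 * delta` here — a template-shaped, in-band error. A running-median
  baseline trace (0.4 s window: long against a QRS, short against drift)
  is therefore subtracted before template building, beat alignment and
  projection. It is never subtracted from the signal itself, so the
  output trace stays continuous and the subtraction stays sample-exact
  outside the beat windows.

Beat times are refined by cross-correlation of each (baseline-corrected)
window with the template: matched-filter timing is far less noisy than
single-sample apex picking under EMG (about 2.5 ms of apex jitter at the
default noise level, versus well under 1 ms for the matched filter), and
subtraction accuracy is first-order in timing error. Beats whose windowed
waveform correlates with the template below 0.5 are flagged ectopic and
excluded from the template average but still subtracted with their own
fit; below 0.2 the window is considered artifact-corrupted and left
untouched, since subtracting a wild fit does more harm than leaving the
beat in place.

The maternal P and T waves are low-frequency and nearly invariant from
beat to beat, so a single beat-aligned average of all P-T windows
(`W_PT`, default median RR − W, covering the T wave through the next P
wave) is computed once and subtracted at every beat.

## Fetal beat detection

The cleaned trace is mapped to a Gabor (Gaussian-window short-time
Fourier) power spectrogram: window 128 ms, hop 4 ms, frame times at the
window centre, FFT zero-padded fourfold so that frequency bins (about
2 Hz) are fine enough to delimit a 10 Hz band — the true resolution is of
course still set by the window. Power is normalised so a frame's
one-sided bins sum to the windowed slice's energy.

Fetal QRS complexes are short (tens of milliseconds) and narrow-band,
concentrating energy at roughly 10–20 Hz, where the maternal residue is
small after cancellation. The detection band is chosen adaptively: among
10-Hz-wide candidates in 8–30 Hz, the band whose integrated power series
is most intermittent wins. Intermittency is measured as excess kurtosis
of the band-power series on the amplitude (square-root) scale — on that
scale featureless noise is close to Gaussian, so a fallback threshold of
0.5 above Gaussian is meaningful, while the raw power of Gaussian noise
is gamma-distributed with excess kurtosis near 2 and would never fall
back. The series is winsorised at its 99th percentile first (a single
motion artifact occupies well under 1% of frames but would otherwise
dominate the fourth moment), and bands within 0.5 of the maximal
kurtosis are treated as tied, the most energetic of them winning. When
nothing is appreciably super-Gaussian the anchor band 10–20 Hz is used
and flagged.

The adaptive threshold is an order-statistic envelope: at every frame the
band-power series is weighted by a unit-peak Tukey window (default span
250 ms, taper 0.5) centred there, and the maximum of the weighted values
is the envelope — computed with a one-frame shift at a time. A unit-peak
window makes the envelope dominate the series pointwise, so a
non-negative series touches its envelope exactly at locally dominant
frames: those are the beat candidates, additionally required to exceed
three times the median band power. A 250 ms refractory keeps the larger
of any closer pair; double-RR gaps are re-searched at a relaxed
threshold; candidates splitting a plausible RR interval into two
implausibly short ones are rejected as insertions; and candidates within
30 ms of a maternal beat are re-examined by a second-pass, lag-searched
local template fit (dropping them when the local band power halves).
Because a rejected residue peak may have suppressed a genuine neighbour
through the refractory, rejected peaks have their band-power support
masked and detection is repeated (up to three passes).

Beat times are finally aligned in the waveform domain: an average fetal
QRS is built from the beat-aligned segments of the cleaned trace
(band-limited to 5–35 Hz for alignment, which sharpens matched-filter
timing severalfold by discarding out-of-band EMG), each beat is shifted
to its maximal cross-correlation lag, and the procedure iterates once
more. Detections whose aligned waveform correlates with the average
fetal QRS below 0.3 are dropped — the same morphologic-comparison logic
that is standard for ectopic rejection. All thresholds are relative, so
the whole detector is invariant to global amplitude scaling.

## The HRV battery

From the detected beats, successive intervals inside the analysis window
form the NN series. Intervals outside 0.7–1.3 times the running median
of the last nine accepted intervals are rejected; in addition, intervals
further than four robust MADs (of all window intervals, 4 ms floor) from
the running median are rejected. The fixed-ratio band alone admits
±130 ms timing errors — absurd when the true beat-to-beat variability is
5 ms — and adaptive bands are standard HRV artifact-rejection practice;
the MAD is taken over the whole window rather than the accepted history
because a running scale of the accepted subset can self-truncate and
reject everything. A series qualifies for metric computation when more
than 95% of its intervals survive; analysis windows default to the first
qualified 90 s segment per stage.

The battery itself:

* **Time domain** — mean heart rate (mean of beatwise rates
  `60000 / NN`); SDNN (sample standard deviation, n − 1 denominator);
  the maximum and minimum heart rate reported as the mean of the upper
  and lower quartile (the `ceiling(n/4)` largest/smallest beatwise
  rates) — robust extrema for short fetal segments.
* **Poincaré** — from the scatter of each interval against its
  predecessor, `SD1 = sd((x[n] - x[n+1]) / sqrt(2))` (short-term,
  vagally mediated) and `SD2 = sd((x[n] + x[n+1]) / sqrt(2))`
  (long-term); their squares sum to the variance of the first elements
  plus the variance of the second elements of the pairs, an identity the
  tests verify to 1e-9. The ratio is flagged undefined when SD2 = 0
  rather than reported as infinite.
* **Symbolic dynamics** — intervals quantised into six equally spaced
  levels between the series minimum and maximum (a value equal to the
  maximum clips to level 5, avoiding a spurious seventh level); all
  overlapping length-3 words classified by their number of level
  changes: 0V (none; sympathetic predominance marker), 1V (one), 2V
  (two; vagal marker). Proportions sum to one exactly.

## The synthetic generator, and what passing its tests means

Every stage is testable offline against a seed-deterministic generator
that emulates the recording conditions: a dominant maternal ECG (default
75 bpm, SDNN 30 ms) whose complexes are amplitude-modulated by
respiration (depth 0.25 at 15 breaths/min); a fetal ECG (default
135 bpm, SDNN 20 ms) at 0.2 of the maternal R amplitude, whose triphasic
QRS — Q and S lobes at ±22 ms, −0.45 relative amplitude — places just
over 60% of its spectral energy in 10–20 Hz; sinusoidal baseline wander
(0.15 mV at 0.22 and 0.05 Hz); EMG noise band-limited to 20–150 Hz at
15 dB below the maternal QRS-window power; and sparse random-polarity
raised-cosine motion transients (50–200 ms, two to five times the
maternal R, 0.5 events/min). NN series follow a stationary lag-1
autoregression (coefficient 0.6) with Gaussian innovations and ±4 SD
rejection. Defaults are 60 s records at 1 kHz — the reader honours
higher rates such as the 2 kHz of typical acquisition hardware, and the
10–20 Hz band is fully resolved at 1 kHz; tests and the acceptance
script use these sizes throughout.

Beat morphology is a sum of Gaussian bumps rather than a dynamical-system
ECG model: ground-truth verifiability (exact apex locations, exact
component traces) matters more here than waveform realism. Consequently,
passing these tests shows that the chain recovers beats and variability
under controlled amplitude ratios, noise levels and artifact rates; it
does not certify performance on real abdominal recordings, where fetal
position changes, electrode quality, maternal ectopy and non-Gaussian
noise add failure modes the generator does not emulate.

## Open choices made here

The lead-quality score (the acquisition literature says only "select the
highest quality signal") is the ratio of the median maternal-R detection
amplitude to the MAD of the detection function on the 5–40 Hz band-passed
lead — an SNR proxy that rewards sparse, consistent R peaks; it is
documented and swappable. Analysis uses one best lead per segment.
Ectopic handling is automated (template correlation) rather than visual.
The template is estimated once per analysis segment; "adaptive" refers
to the per-beat coefficients. Fetal beat times are refined by parabolic
interpolation across band-power frames and then by waveform-domain
matched filtering, because the frame grid alone (4 ms hop) would add
avoidable quantisation jitter to the RR series. The 90 s
analysis window is placed at the first qualified position within each
stage, stepping by 10 s.

## Known limitations

Detection degrades gracefully but measurably when fetal and maternal
QRS complexes coincide within about 10 ms (the two-basis fit absorbs
part of the overlapped fetal beat); at the default rates this affects a
few percent of beats and is the dominant residual error source. Motion
artifacts larger than a few millivolts locally blind both detectors for
their duration. The maternal-coincident pseudo-peak re-subtraction check
is retained for completeness but is a weak discriminator in practice —
the rhythm-context and morphology screens do the real work. Only beat
times are claimed for the fetal signal: no morphological (ST-segment)
reconstruction is attempted, and frequency-domain HRV is out of scope.
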