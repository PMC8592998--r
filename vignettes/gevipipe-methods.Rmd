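---
title: "Analysing GEVI-imaged cortical oscillations with gevipipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing GEVI-imaged cortical oscillations with gevipipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(gevipipe)
```

## The problem

Genetically encoded voltage indicators (GEVIs) report membrane potential
as a fractional change in fluorescence. Imaged at 1 kHz over an 80 × 80
pixel field of a disinhibited motor-cortex slice, they reveal
spontaneous population oscillations: a large initial deflection followed
by a handful of amplitude-decrementing fluctuations in the ~5–50 Hz
band, either sweeping across the slice ("waving") or punctate and in
place. `gevipipe` implements the full analysis chain for such
recordings — masking, filtering, normalisation, representative-waveform
construction, oscillation features, k-nearest-neighbour anomaly
scoring, amplitude-symmetry analysis, and spatial-origin statistics —
together with a forward simulator that generates movies with known
ground truth, so that every stage of the pipeline can be validated
quantitatively without access to slice data.

## The signal model

The simulator composes three layers:

1. **Voltage.** Each oscillation is the closed-form stereotype
   $s(u) = A\,e^{-u/\tau_d}\,\sin(2\pi f u)$ for
   $u \in [0, (n+\tfrac12)/f]$: an initial half-cycle deflection of
   amplitude $A$ (mV) followed by $n$ full cycles whose envelope decays
   with time constant $\tau_d$. Spatially, a *waving* event assigns each
   participating pixel an onset that grows linearly along a randomly
   oriented axis at the propagation speed; *in-place* events start
   synchronously on scattered (punctate) or contiguous (decrementing)
   participant sets. Deviations from a −70 mV resting potential add
   across events.

2. **GEVI kinetics.** The steady-state fluorescence–voltage curve is a
   Boltzmann sigmoid
   $F_{ss}(V) = \Delta F_{max} / (1 + e^{-(V - V_{1/2})/k})$,
   baselined to zero at rest; $\Delta F_{max} < 0$ for the ArcLight
   family, so depolarisation dims the probe. The temporal response is
   the weighted sum of two parallel first-order relaxations toward
   $F_{ss}(V(t))$, using the probe's on-kinetics while the target
   deviation exceeds the current response deviation and its off-kinetics
   otherwise. This is the simplest dynamical model whose step responses
   reproduce the published bi-exponential fits (fast/slow time constant
   plus fast fraction) of ArcLight-A242, Bongwoori-Pos6 and
   Bongwoori-R3, available as `geviPresets()`. The sigmoid steepness $k$
   is **not** a published probe constant; the default of 20 mV is a
   simulator convention, exposed as a parameter, and no quantitative
   validation target depends on it.

3. **Camera.** Counts are
   $B\,e^{-t/\tau_b}\,(1 + \Delta F/F_0 / 100)$ with single-exponential
   photobleaching, Gaussian read noise, optional Poisson shot noise,
   and optionally a *shared multiplicative illumination (lamp) noise*.
   The lamp term matters: read noise averages away across pixels, so
   with read noise alone the representative (pixel-averaged) waveform's
   SNR would grow without bound with member count, which real widefield
   recordings do not show. A common-mode noise floor is physically real
   and is also consistent with published reference SNRs of order 7–22
   for correlated-pixel signals. Out-of-slice pixels are rendered dark
   (2 % of baseline) as a contiguous border region; the default count,
   389, is the median masked-pixel count of the recordings being
   emulated. Helper functions `noiseSdForSnr()` and `commonCvForSnr()`
   calibrate the two noise sources so that a given response peak lands
   at a chosen SNR *after* the analysis bandpass.

What the generator deliberately does **not** emulate: optical scattering
and point-spread blur, motion, hemodynamic artefacts, conductance-level
biophysics, and non-exponential bleaching. Passing the recovery tests
therefore shows that the pipeline's estimators are correct under the
stated signal model, not that they are robust to every artefact of real
tissue.

## Preprocessing

`preprocessMovie()` masks dark pixels (temporal mean below 10 % of the
99th-percentile mean — a rule invariant to exposure scaling), fits each
pixel's photobleaching baseline $F_0(t) = a\,e^{-t/\tau} + c$, and
converts to percent dF/F0 with a zero-phase 5th-order Butterworth
high-pass (5 Hz) and low-pass (50 Hz) cascade. Three numerical choices
deserve explanation:

* **Zero-phase filtering.** The analysis is offline and peak/initiation
  timing must be undistorted, so the cascade is applied forward and
  backward; the effective magnitude response is the squared single-pass
  response (`butterCascadeGain()` documents the closed form, which the
  test suite uses as its oracle). Inputs are odd-reflect padded by one
  warm-up length.

* **Baseline before filter.** The fitted baseline is subtracted before
  filtering and the filtered signal is then divided by the baseline.
  In the passband this equals the filter-then-divide order (the filter
  is linear), but it avoids the filter's start-up transient on the
  bleaching trend. That transient is identical in every pixel, so it
  would survive pixel averaging and put a hard ceiling (~40 in our
  measurements) on the representative waveform's SNR.

* **Robust sigma.** The per-pixel Gaussian baseline-noise SD is
  estimated by the median absolute deviation over the whole recording
  rather than the SD of the first 500 ms. The oscillation occupies a
  minority of samples and barely moves the MAD, while a 500 ms window
  holds only ~25 independent draws of the band-limited noise — far too
  few for a stable per-pixel threshold — and the filter's edge
  transients would bias it. The 500 ms baseline window itself remains
  the training convention of the k-NN stage.

The exponential fit uses variable projection: for fixed $\tau$ the
$(a, c)$ are linear, and the profiled residual is minimised over
$\log\tau$ with `optimize()` on a decimated trace. Degenerate pixels
(near-constant, or dark pixels whose fit would go non-positive) fall
back to a constant baseline at their mean count.

## The representative oscillation waveform and its features

The reference pixel is the unmasked pixel with the largest |dF/F0|
(edge-guarded; ties broken row-major). Pixels are ranked by Pearson
correlation with the reference over the full recording and averaged
greedily in that order; the running SNR (smoothed |peak| over the
baseline-window SD of the average) rises while correlated pixels cancel
noise and falls once uncorrelated pixels dilute the signal. Averaging
stops when the SNR stays below 99 % of its running maximum for several
consecutive additions, and the average at the best SNR becomes the
representative waveform. The smoothing (10 ms) and patience (5
additions) exist because the literal one-sample peak makes the stopping
rule fire on noise jitter after a handful of pixels.

Bounds are the first and last *sustained* exceedances of ±3σ — runs of
at least 5 ms, gap-merged within 100 ms, anchored at the event carrying
the largest excursion. The sustain criterion mirrors the per-pixel
initiation-time rule; without it, chance exceedances of band-limited
noise (probability ≈ 0.0027 per sample at 3σ) would set the bounds of
any long recording regardless of SNR. A 250 ms edge guard keeps the
zero-phase filter's warm-up transients out of every peak search and
bound. "No sample ever qualifies" is a *no-oscillation-detected*
outcome, not an error.

Features follow: duration (end − start), peak time (absolute maximum
within bounds, relative to start), complete-cycle count
(zero-crossing pairs in the first 200 ms of the event, floored),
a short-segment dominant-frequency track (Hann-windowed, zero-padded
periodogram peak in 5–50 Hz per 10 ms segment by default), and the
full-oscillation PSD (|FFT|²). Two caveats are documented rather than
hidden: a 10 ms window cannot natively resolve the 5–50 Hz band, so the
track is a short-window *estimate* whose segment length is a parameter;
and for a single overall frequency the PSD argmax
(`dominantFrequency()`), which resolves ~1/duration Hz, is the right
estimator. Waving-mode events additionally smear the representative
across onsets, so duration recovery is a property of in-place events;
propagating events are characterised by their initiation maps instead.

## k-nearest-neighbour anomaly scoring

Each 4 × 4 pixel group (400 groups at the native 80 × 80 geometry) is
represented by its 16-pixel mean waveform — all pixels, regardless of
mask, with no further filtering. Per group, every stride-1 window of
300 ms inside the first 500 ms forms the training set (201 windows at
1 kHz; "saturation sampling"), and each later 300 ms window is scored
by the Euclidean distance to its nearest training window (k = 1).
Scores are translation-covariant (a constant offset shifts training and
scored windows equally), and scoring the training region itself returns
zeros. The scoring stride is 1 by default; score maps for whole movies
can use a wider stride, which subsamples the same track.

## Amplitude symmetry

Unmasked pixels are correlated with the reference over the oscillation
window, sorted, and cut into 5 (configurable 5–7) equal-size rank
groups of at most 18 % of the unmasked pixels each; when the cap binds,
each rank block keeps the members nearest its own extreme. The most
positively ranked group is paired with the most negatively ranked, and
so on inward; an odd middle group is dropped. For each pair,
$S = \lVert (A - B)/2 \rVert \,/\, (\lVert (A-B)/2 \rVert + \lVert (A+B)/2 \rVert)$
on the groups' mean waveforms: 1 for perfect mirror symmetry, 0 for
identical waveforms, and exactly 0.5 for orthogonal equal-norm
waveforms. An alternative pairing by most-anticorrelated group mean
waveforms is available behind `pairing = "waveform"`.

## Spatial origin and shared substrates

A pixel's initiation time is the earliest time its waveform stays
beyond 3σ for at least 5 ms (configurable to 10 ms). By default the
rule is anchored to the pixel's own oscillation: sustained runs chained
within 60 ms, taking the start of the event that carries the pixel's
largest excursion. The literal earliest-sustained-crossing variant is
available (`mode = "first"`) and appropriate for short windowed
searches; over a full 10 s trace it locks onto chance noise excursions
at a rate of order one per second per pixel.

Latencies relative to the oscillation start are binned 1 ms (1–10 ms),
5 ms (11–40 ms), 10 ms (41–80 ms) and 20 ms (81–200 ms) — 26 bins.
Per bin, the Hopkins statistic is computed 20 times and averaged: with
$n$ initiating pixels, draw $n$ comparison pixels without replacement
from the remaining unmasked pixels; $u$ sums each comparison pixel's
distance to its nearest initiating pixel, $w$ sums the initiating
pixels' within-set nearest-neighbour distances, and $H = u/(u+w)$.
The orientation is the standard cluster-tendency one — clustered
initiation sites give $H \to 1$, exchangeable sites give
$H \approx 0.5$, regular lattices give $H < 0.5$.

Recordings with several oscillations are compared by ranking pixels
against each oscillation's reference, cutting four equal-rank groups,
and taking the Jaccard overlap of top groups between oscillations
(shared when ≥ 0.5, configurable); the joint grouping over all
oscillation windows is reported alongside.

## Validation fixtures and problem sizes

The package validates itself on simulated study conditions chosen once:

* **Parameter recovery** — twenty 80 × 80, 10 s fixtures at 1 kHz:
  a 12 Hz oscillation with 10 fluctuations (875 ms true span), envelope
  decay 600 ms, read noise calibrated so active pixels sit at SNR 20
  after the bandpass and lamp noise so the representative's SNR ceiling
  sits near 25. In-place fixtures check duration (±10 %), PSD dominant
  frequency (±1 Hz) and cycle count (±1); waving fixtures (0.5 px/ms)
  check that recovered initiation maps are affine in position with
  R² > 0.95; planted-origin fixtures check early-bin Hopkins > 0.7
  against ≈ 0.5 for scattered participants. The envelope is designed to
  sit near 6σ at the true end so the 3σ end-crossing is sharp; duration
  is summarised across seeds by the median, the appropriate robust
  summary for a stochastic fixture set.

* **Probe ordering** — 40 × 40, 4 s voltage fields (a large fast 30 Hz
  early phase followed by a slower 12 Hz decaying tail, the recorded
  stereotype) rendered through all three probe presets at sigmoid
  steepness 10 mV, each with its own reference-SNR-calibrated noise.
  The steeper sigmoid is needed for the fixture to expose the
  half-activation difference between Bongwoori-Pos6 (−28 mV) and
  Bongwoori-R3 (−3 mV): at 20 mV steepness their response curves are
  too shallow to separate within the fixture's 55 mV dynamic range.
  Expected orderings: measured duration ArcLight ≥ Pos6 ≥ R3 (slow off
  kinetics and high SNR extend ArcLight's visible tail; R3's
  right-shifted activation curve silences the decaying tail first) and
  k-NN detectability (fraction of oscillation windows above each
  group's own 99th-percentile baseline score) highest for ArcLight,
  both asserted on one field; and early mean frequency highest for
  Pos6 — its fast kinetics preserve the fast phase that ArcLight's
  22/74 ms off kinetics smear into a low-frequency envelope, while
  R3's compressed response partially hides it. The Pos6-vs-R3
  frequency margin is genuinely modest (their kinetics are equally
  fast, so only the activation-voltage difference separates them), so
  the frequency ordering is compared on the mean over three paired
  fields rather than a single realization.

These sizes keep the full suite within an ordinary desktop run while
exercising the native recording geometry where it matters.

## A worked example

```{r example}
im <- imagingParams(n_frames = 3000, height = 20, width = 20,
                    n_masked_pixels = 30)
spec <- oscillationSpec(onset_time = 1000, amplitude = 40,
                        n_fluctuations = 10, base_frequency = 12,
                        decay_tau = 600, active_fraction = 0.6)
sim <- generateVoltageField(spec, im, seed = 3)
gevi <- geviPresets()$ArcLight

# calibrate noise to per-pixel SNR 20 with a representative-SNR ceiling
act <- which(!is.na(perPixelOnset(sim$truth)), arr.ind = TRUE)[1, ]
pk <- max(abs(bandpass(geviTransfer(
  voltageValues(sim$field)[, act[1], act[2]], gevi, dt = 1),
  frame_rate = 1000)))
im <- imagingParams(n_frames = 3000, height = 20, width = 20,
                    n_masked_pixels = 30,
                    noise_sd = noiseSdForSnr(pk, im, 20),
                    common_noise_cv = commonCvForSnr(pk, 25))
mv <- renderMovie(sim$field, gevi, im, seed = 3, truth = sim$truth)

wf <- preprocessMovie(mv$movie)
rec <- detectBounds(buildRepresentativeWaveform(wf))
rec
oscillationFeatures(rec)
c(true_duration = trueDuration(sim$truth),
  dominant_freq = dominantFrequency(rec))
```

```{r plot, fig.alt = "Representative oscillation waveform with bounds"}
plot((seq_along(representative(rec)) - 1), representative(rec),
     type = "l", xlab = "time (ms)", ylab = "%dF/F0",
     main = "Representative oscillation waveform")
abline(v = oscillationBounds(rec)[c("start_ms", "end_ms")],
       lty = 2, col = "red")
abline(h = c(-3, 3) * baselineSd(rec), lty = 3, col = "grey40")
```

## Known limitations

* The GEVI model is phenomenological: two relaxations with
  drive-direction-dependent time constants reproduce step responses but
  not every nuance of probe photophysics (no photobleaching–voltage
  interaction, no dual-component activation curves).
* The 3σ bounds and initiation rules are threshold detectors; their
  sustained-run and event-anchoring guards are tuned to the 5–50 Hz
  band and 1 kHz sampling, and should be revisited for other bands.
* The frequency track's 10 ms default segment is a convention carried
  by the analysis it mirrors; treat its absolute values with care and
  prefer `dominantFrequency()` for whole-event frequencies.
* Hopkins statistics are descriptive here; no permutation null or
  significance test is attached (a documented extension point).
```
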