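# Shared fixtures and independent oracles for the test suite. Expensive
# end-to-end fixtures are built once per session and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# --- independent oracles --------------------------------------------------

# Boltzmann steady-state fluorescence change, written out directly.
sigmoidOracle <- function(v, df_max, v_half, slope) {
  df_max / (1 + exp(-(v - v_half) / slope))
}

# Zero-crossing cycle counter: sign changes / 2, floored.
zeroCrossCyclesOracle <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  as.integer(sum(diff(s) != 0) %/% 2)
}

# Squared magnitude of the zero-phase cascaded Butterworth bandpass,
# from the bilinear-transform closed form (|H_hp| * |H_lp|)^2.
butterZeroPhaseGainOracle <- function(f, low, high, order, rate) {
  wf <- tan(pi * f / rate)
  hp2 <- 1 / (1 + (tan(pi * low / rate) / wf)^(2 * order))
  lp2 <- 1 / (1 + (wf / tan(pi * high / rate))^(2 * order))
  hp2 * lp2   # amplitude-squared of one pass = zero-phase amplitude gain
}

# Dominant in-band frequency of a short segment by direct DFT evaluation
# on a fine frequency grid (independent of the package's FFT path).
periodogramPeakOracle <- function(x, rate, band = c(5, 50), df = 0.1) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))
  xw <- x * w
  t <- (seq_len(n) - 1) / rate
  fs <- seq(band[1], band[2], by = df)
  p <- vapply(fs, function(f) {
    Mod(sum(xw * exp(-2i * pi * f * t)))^2
  }, numeric(1))
  fs[which.max(p)]
}

# --- fixture builders -----------------------------------------------------

# WaveformSet built directly from a values matrix (no movie round trip).
makeWaveformSet <- function(values, h, w, rate = 1000, mask = NULL,
                            baseline_sd = NULL) {
  if (is.null(mask)) mask <- matrix(FALSE, h, w)
  if (is.null(baseline_sd))
    baseline_sd <- apply(values, 2, stats::mad)
  new("WaveformSet", values = values, dims = c(as.integer(h), as.integer(w)),
      frameRate = rate, mask = mask, baselineSd = baseline_sd)
}

# OscillationRecord wrapped around a given representative trace.
makeRecord <- function(x, rate = 1000, baseline_sd = 1, detected = FALSE,
                       start_ms = NA_real_, end_ms = NA_real_) {
  new("OscillationRecord", representative = x,
      memberPixels = cbind(row = 1L, col = 1L),
      referencePixel = c(1L, 1L), frameRate = rate,
      baselineSd = baseline_sd, snr = NA_real_, detected = detected,
      startMs = start_ms, endMs = end_ms,
      durationMs = end_ms - start_ms,
      peakTimeMs = NA_real_, nCycles = NA_real_)
}

# Damped oscillation trace (the slice stereotype), zero outside its span.
dampedOsc <- function(n, rate = 1000, onset_ms = 1000, amp = 1, f = 15,
                      n_fluct = 5, tau = 400) {
  t <- (seq_len(n) - 1) * 1000 / rate
  u <- t - onset_ms
  u_end <- 1000 * (n_fluct + 0.5) / f
  x <- amp * exp(-u / tau) * sin(2 * pi * f * u / 1000)
  x[u < 0 | u > u_end] <- 0
  x
}

# Small end-to-end study-condition fixture: 20 x 20 px, 3 s, ArcLight,
# per-pixel SNR 20 with the lamp-noise ceiling near 25.
smallStudyMovie <- function(seed = 3, mode = "in_place_punctate") {
  im0 <- imagingParams(n_frames = 3000, height = 20, width = 20,
                       n_masked_pixels = 30, bleach_tau = 20000)
  sp <- oscillationSpec(onset_time = 1000, amplitude = 40,
                        n_fluctuations = 10, base_frequency = 12,
                        decay_tau = 600, active_fraction = 0.6,
                        spatial_mode = mode)
  sim <- generateVoltageField(sp, im0, seed = seed)
  tr <- perPixelOnset(sim$truth)
  act <- which(!is.na(tr), arr.ind = TRUE)[1, ]
  gp <- geviPresets()$ArcLight
  pk <- max(abs(bandpass(geviTransfer(sim$field@values[, act[1], act[2]],
                                      gp, 1), frame_rate = 1000)))
  im <- imagingParams(n_frames = 3000, height = 20, width = 20,
                      n_masked_pixels = 30, bleach_tau = 20000,
                      noise_sd = noiseSdForSnr(pk, im0, 20),
                      common_noise_cv = commonCvForSnr(pk, 25))
  mv <- renderMovie(sim$field, gp, im, seed = seed, truth = sim$truth)
  list(sim = sim, movie = mv$movie, truth = mv$truth, imaging = im,
       peak = pk)
}

sharedStudyFixture <- function() {
  cached("study20", {
    fx <- smallStudyMovie()
    fx$wf <- preprocessMovie(fx$movie)
    fx$record <- detectBounds(buildRepresentativeWaveform(fx$wf))
    fx
  })
}
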