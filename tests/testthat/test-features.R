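test_that("the reference pixel is the unmasked maximal-response pixel", {
  set.seed(10)
  n <- 1500
  vals <- matrix(rnorm(n * 36, sd = 0.1), n, 36)
  vals[, 14] <- vals[, 14] + dampedOsc(n, onset_ms = 600, amp = 2)
  wf <- makeWaveformSet(vals, 6, 6)
  expect_equal(selectReferencePixel(wf), c(2L, 3L))   # column-major 14
  # all-identical waveforms: row-major tie-break gives the first pixel
  wf0 <- makeWaveformSet(matrix(rep(dampedOsc(n, onset_ms = 600), 36), n, 36),
                         6, 6)
  expect_equal(selectReferencePixel(wf0), c(1L, 1L))
  # a masked pixel never wins even if it holds the global maximum
  mask <- matrix(FALSE, 6, 6); mask[2, 3] <- TRUE
  wfm <- makeWaveformSet(vals, 6, 6, mask = mask)
  expect_false(all(selectReferencePixel(wfm) == c(2L, 3L)))
})

test_that("greedy averaging recovers the participating pixels at SNR 20", {
  set.seed(77)
  n <- 2000
  sig <- dampedOsc(n, onset_ms = 800, amp = 1, f = 15, n_fluct = 6,
                   tau = 400)
  noise_sd <- max(abs(sig)) / 20
  vals <- matrix(rnorm(n * 1000, sd = noise_sd), n, 1000)
  participants <- sample(1000, 500)
  vals[, participants] <- vals[, participants] + sig
  wf <- makeWaveformSet(vals, 40, 25)
  rec <- buildRepresentativeWaveform(wf)
  members <- gevipipe:::pixelIndex(memberPixels(rec), 40)
  hits <- intersect(members, participants)
  expect_gte(length(hits) / length(participants), 0.9)   # recall
  expect_lt(length(setdiff(members, participants)) /
              max(length(members), 1), 0.1)              # contamination
  expect_gt(rec@snr, 20)
})

test_that("degenerate member sets behave per contract", {
  n <- 1200
  x <- dampedOsc(n, onset_ms = 500)
  # single unmasked pixel: representative equals that pixel's waveform
  mask <- matrix(TRUE, 4, 4); mask[3, 2] <- FALSE
  vals <- matrix(rnorm(n * 16, sd = 0.05), n, 16)
  vals[, 7] <- x   # column-major (3, 2)
  wf1 <- makeWaveformSet(vals, 4, 4, mask = mask)
  rec1 <- buildRepresentativeWaveform(wf1)
  expect_equal(representative(rec1), x)
  expect_equal(nrow(memberPixels(rec1)), 1)
  # noise-free identical pixels: everyone joins, average is the waveform
  wf2 <- makeWaveformSet(matrix(rep(x, 16), n, 16), 4, 4)
  rec2 <- buildRepresentativeWaveform(wf2)
  expect_equal(nrow(memberPixels(rec2)), 16)
  expect_equal(representative(rec2), x)
  # zero-variance reference errors
  wf3 <- makeWaveformSet(matrix(0, n, 16), 4, 4,
                         baseline_sd = rep(1, 16))
  expect_error(buildRepresentativeWaveform(wf3, reference = c(1, 1)),
               "zero variance")
})

test_that("3-sigma bounds match the damped-envelope crossings", {
  rate <- 1000
  n <- 4000
  amp <- 2; f <- 15; tau <- 400; sigma <- 0.05
  x <- dampedOsc(n, onset_ms = 1000, amp = amp, f = f, n_fluct = 19,
                 tau = tau)
  rec <- detectBounds(makeRecord(x, rate, baseline_sd = sigma))
  expect_true(isDetected(rec))
  # envelope falls through 3 sigma at t* = tau ln(A / 3 sigma); the last
  # suprathreshold sample lies within half a period before t*
  t_star <- tau * log(amp / (3 * sigma))
  expect_lte(rec@endMs, 1000 + t_star + 1)
  expect_gte(rec@endMs, 1000 + t_star - 1000 / (2 * f) - 1)
  # the first crossing is within the first quarter cycle after onset
  expect_gte(rec@startMs, 1000 - 1)
  expect_lte(rec@startMs, 1000 + 1000 / (4 * f) + 1)
  # peak of a decaying envelope falls in the first cycle
  expect_lte(peakTime(rec), 1000 / f)
})

test_that("bounds detection is robust and sign-invariant", {
  # pure noise: no oscillation detected (an outcome, not an error)
  set.seed(5)
  noise <- bandpass(rnorm(3000, sd = 0.3), frame_rate = 1000)
  recn <- detectBounds(makeRecord(noise, baseline_sd = stats::mad(noise)))
  expect_false(isDetected(recn))
  expect_true(is.na(recn@durationMs))
  # sign flip leaves the bounds unchanged
  x <- dampedOsc(3000, onset_ms = 800, amp = 1.5)
  r1 <- detectBounds(makeRecord(x, baseline_sd = 0.05))
  r2 <- detectBounds(makeRecord(-x, baseline_sd = 0.05))
  expect_equal(oscillationBounds(r1), oscillationBounds(r2))
  # scaling the amplitude up never shortens the duration
  r10 <- detectBounds(makeRecord(10 * x, baseline_sd = 0.05))
  expect_gte(r10@durationMs, r1@durationMs)
})

test_that("cycle counting agrees with the zero-crossing oracle", {
  rate <- 1000
  mk <- function(x, start_ms, end_ms)
    makeRecord(x, rate, baseline_sd = 1e-3, detected = TRUE,
               start_ms = start_ms, end_ms = end_ms)
  t <- (0:3000) / rate
  # stationary 15 Hz tone, 200 ms window
  x <- sin(2 * pi * 15 * t)
  rec <- mk(x, 500, 2500)
  win <- x[501:701]
  expect_equal(countCycles(rec, 200), zeroCrossCyclesOracle(win))
  # doubling the window doubles the count (+/- 1)
  expect_lte(abs(countCycles(rec, 400) - 2 * countCycles(rec, 200)), 1)
  # a single monophasic deflection has no complete cycle
  pulse <- exp(-((t * 1000 - 1000) / 30)^2)
  expect_equal(countCycles(mk(pulse, 900, 1100), 200), 0)
})

test_that("the frequency track matches an independent periodogram peak", {
  rate <- 1000
  t <- (0:2999) / rate
  x <- sin(2 * pi * 20 * t)
  rec <- makeRecord(x, rate, baseline_sd = 1e-3, detected = TRUE,
                    start_ms = 500, end_ms = 2500)
  trk <- frequencyTrack(rec, segment_ms = 50)
  expect_gt(nrow(trk), 30)
  expect_true(all(trk$dominant_freq_hz >= 5 & trk$dominant_freq_hz <= 50))
  # spot-check segments against the direct-DFT oracle
  for (k in c(1, 11, 25)) {
    seg0 <- round(trk$segment_time_ms[k] * rate / 1000) + 1
    seg <- x[seg0:(seg0 + 49)]
    expect_equal(trk$dominant_freq_hz[k],
                 periodogramPeakOracle(seg, rate), tolerance = 1.5)
  }
  # 50 ms segments resolve a 20 Hz tone
  expect_equal(median(trk$dominant_freq_hz), 20, tolerance = 1)
  # a chirp yields a non-decreasing track
  ch <- sin(2 * pi * (10 * t + (20 / 2 / 3) * t^2))  # 10 -> 30 Hz over 3 s
  recc <- makeRecord(ch, rate, baseline_sd = 1e-3, detected = TRUE,
                     start_ms = 200, end_ms = 2800)
  trc <- frequencyTrack(recc, segment_ms = 100)
  expect_true(all(diff(trc$dominant_freq_hz) > -2.5))
  expect_gt(tail(trc$dominant_freq_hz, 1), head(trc$dominant_freq_hz, 1) + 10)
  # undetected record -> empty track
  expect_equal(nrow(frequencyTrack(makeRecord(rnorm(1000)))), 0)
})

test_that("PSD peaks at the tone frequency and satisfies Parseval", {
  rate <- 1000
  t <- (0:2047) / rate
  x <- sin(2 * pi * 15 * t)
  rec <- makeRecord(x, rate)
  psd <- psdCurve(rec)
  half <- psd[psd$freq_hz <= rate / 2, ]
  expect_equal(half$freq_hz[which.max(half$power)], 15,
               tolerance = rate / length(x) + 1e-9)
  expect_equal(sum(psd$power) / nrow(psd), sum(x^2),
               tolerance = 1e-6 * sum(x^2))
  expect_equal(dominantFrequency(rec), 15, tolerance = rate / length(x))
  zero <- psdCurve(makeRecord(rep(0, 500)))
  expect_true(all(zero$power == 0))
})

test_that("peak timing distinguishes decaying and crescendo events", {
  rate <- 1000
  n <- 3000
  dec <- dampedOsc(n, onset_ms = 500, amp = 2, f = 10, n_fluct = 8,
                   tau = 300)
  rdec <- detectBounds(makeRecord(dec, rate, baseline_sd = 0.02))
  expect_lte(peakTime(rdec), 1000 / 10)            # first cycle
  t <- (seq_len(n) - 1)
  cres <- dampedOsc(n, onset_ms = 500, amp = 0.2, f = 10, n_fluct = 8,
                    tau = -400)                    # growing envelope
  rcres <- detectBounds(makeRecord(cres, rate, baseline_sd = 0.02))
  expect_gte(peakTime(rcres), rcres@durationMs - 1000 / 10)  # last cycle
  # symmetric pulse peaks exactly at its centre
  pulse <- exp(-((t - 1200) / 40)^2)
  rp <- detectBounds(makeRecord(pulse, rate, baseline_sd = 0.001))
  expect_equal(rp@startMs + peakTime(rp), 1200)
})

test_that("the feature table summarises a detected oscillation", {
  fx <- sharedStudyFixture()
  ft <- oscillationFeatures(fx$record)
  expect_named(ft, c("duration_ms", "n_cycles", "peak_time_ms",
                     "mean_freq_first200_ms", "n_member_pixels", "snr"))
  expect_true(ft$duration_ms > 0)
  expect_true(ft$n_member_pixels >= 1)
})
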