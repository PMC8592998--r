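test_that("bandpass rejects DC and matches the analytic gain in and out of band", {
  rate <- 1000
  t <- (0:9999) / rate
  # constant trace -> (numerically) zero
  flat <- bandpass(rep(3.7, 2000), frame_rate = rate)
  expect_lt(max(abs(flat)), 1e-8)
  mid <- 2001:8000
  for (f in c(1, 20, 45)) {
    x <- sin(2 * pi * f * t)
    y <- bandpass(x, frame_rate = rate)
    g_meas <- sqrt(mean(y[mid]^2)) / sqrt(mean(x[mid]^2))
    g_ana <- butterZeroPhaseGainOracle(f, 5, 50, 5, rate)
    expect_equal(g_meas, g_ana, tolerance = 0.02)
  }
  # 1 Hz sits deep in the stop band
  x1 <- sin(2 * pi * 1 * t)
  expect_lt(max(abs(bandpass(x1, frame_rate = rate)[mid])),
            2 * butterZeroPhaseGainOracle(1, 5, 50, 5, rate))
  expect_length(bandpass(x1, frame_rate = rate), length(x1))
  expect_error(bandpass(rnorm(10), frame_rate = rate), "warm-up")
})

test_that("dark-pixel masking follows the percentile-referenced rule", {
  mkmovie <- function(mat, nt = 60) {
    cnt <- array(rep(t(rep(1, nt) %o% as.vector(mat))),
                 c(nt, nrow(mat), ncol(mat)))
    for (i in seq_len(nt)) cnt[i, , ] <- mat
    new("Movie", counts = cnt, frameRate = 1000, origin = list())
  }
  uniform <- mkmovie(matrix(800, 10, 10))
  expect_equal(nMasked(maskDarkPixels(uniform)), 0)
  one_dark <- matrix(1000, 10, 10); one_dark[4, 7] <- 0
  mk <- maskDarkPixels(mkmovie(one_dark))
  expect_equal(nMasked(mk), 1)
  expect_true(maskedPixels(mk)[4, 7])
  # masking threshold referenced to the 99th percentile is scale-invariant
  mk2 <- maskDarkPixels(mkmovie(one_dark * 37.5))
  expect_identical(maskedPixels(mk), maskedPixels(mk2))
})

test_that("the generator's dark border is recovered exactly at the default threshold", {
  # native 80 x 80 geometry with the median masked-pixel count (389)
  im <- imagingParams(n_frames = 60, height = 80, width = 80,
                      noise_sd = 3, n_masked_pixels = 389)
  sp <- oscillationSpec(amplitude = 0, n_fluctuations = 0, onset_time = 0)
  sim <- generateVoltageField(sp, im, seed = 4)
  mv <- renderMovie(sim$field, geviPresets()$ArcLight, im, seed = 4)
  mk <- maskDarkPixels(mv$movie)
  expect_equal(nMasked(mk), 389)
  expect_identical(maskedPixels(mk), maskedPixels(mv$truth))
})

test_that("masking is invariant to frame order", {
  im <- imagingParams(n_frames = 50, height = 12, width = 12,
                      noise_sd = 5, n_masked_pixels = 14)
  sp <- oscillationSpec(amplitude = 0, n_fluctuations = 0, onset_time = 0)
  sim <- generateVoltageField(sp, im, seed = 6)
  mv <- renderMovie(sim$field, geviPresets()$ArcLight, im, seed = 6)
  perm <- withr::with_seed(1, sample(50))
  shuffled <- new("Movie", counts = movieCounts(mv$movie)[perm, , ],
                  frameRate = 1000, origin = list())
  expect_identical(maskedPixels(maskDarkPixels(mv$movie)),
                   maskedPixels(maskDarkPixels(shuffled)))
})

test_that("exponential baseline parameters are recovered within 1%", {
  t <- 0:4999
  raw <- 1800 * exp(-t / 7000) + 150
  ft <- gevipipe:::fitExpBaseline(raw, t)
  expect_equal(ft$a, 1800, tolerance = 0.01 * 1800)
  expect_equal(ft$tau, 7000, tolerance = 0.01 * 7000)
  expect_equal(ft$c, 150, tolerance = 0.01 * 150)
})

test_that("the variable-projection fit agrees with a Levenberg-Marquardt fit", {
  set.seed(12)
  t <- 0:2999
  raw <- 1500 * exp(-t / 6000) + 300 + rnorm(3000, sd = 4)
  ours <- gevipipe:::fitExpBaseline(raw, t)
  ref <- minpack.lm::nlsLM(raw ~ a * exp(-t / tau) + c0,
                           start = list(a = 1000, tau = 4000, c0 = 100))
  cf <- coef(ref)
  expect_equal(ours$a, unname(cf["a"]), tolerance = 0.02 * cf["a"])
  expect_equal(ours$tau, unname(cf["tau"]), tolerance = 0.02 * cf["tau"])
  expect_equal(ours$c, unname(cf["c0"]), tolerance = 0.05 * cf["c0"])
})

test_that("an injected transient is recovered at the filter's gain", {
  rate <- 1000
  t <- 0:4999
  f0 <- 2000 * exp(-t / 20000)
  burst <- dampedOsc(5000, onset_ms = 2500, amp = 10, f = 20,
                     n_fluct = 4, tau = 1e6)
  raw <- f0 * (1 - burst / 100)            # -10% fractional transient
  filt <- bandpass(raw - f0, frame_rate = rate)
  pw <- fitBaselineAndNormalize(raw, filt, rate)
  gain <- butterZeroPhaseGainOracle(20, 5, 50, 5, rate)
  expect_equal(max(abs(pw$values)), 10 * gain, tolerance = 0.05 * 10 * gain)
  # an oscillation-free stretch stays within the noise floor
  expect_lt(max(abs(pw$values[500:2000])), 3 * max(pw$baseline_sd, 1e-3))
})

test_that("normalisation is invariant to overall exposure scaling", {
  fx <- sharedStudyFixture()
  scaled <- new("Movie", counts = movieCounts(fx$movie) * 2.5,
                frameRate = frameRate(fx$movie), origin = list())
  wf2 <- preprocessMovie(scaled)
  expect_identical(maskedPixels(fx$wf), maskedPixels(wf2))
  expect_equal(waveformMatrix(wf2), waveformMatrix(fx$wf),
               tolerance = 1e-6)
})

test_that("baseline noise SD scales linearly with injected noise", {
  build <- function(noise_sd, seed = 31) {
    im <- imagingParams(n_frames = 1500, height = 8, width = 8,
                        n_masked_pixels = 0, noise_sd = noise_sd,
                        bleach_tau = 20000)
    sp <- oscillationSpec(amplitude = 0, n_fluctuations = 0, onset_time = 0)
    sim <- generateVoltageField(sp, im, seed = seed)
    mv <- renderMovie(sim$field, geviPresets()$ArcLight, im, seed = seed)
    median(baselineSd(preprocessMovie(mv$movie)))
  }
  s1 <- build(4); s2 <- build(8)
  expect_equal(s2 / s1, 2, tolerance = 0.15)
})

test_that("quick look returns a flat trace for a constant movie", {
  cnt <- array(1200, c(400, 6, 6))
  mv <- new("Movie", counts = cnt, frameRate = 1000, origin = list())
  ql <- quickLook(mv, reference_frames = 1:50)
  expect_equal(nrow(ql), 400)
  expect_lt(max(abs(ql$dff)), 1e-8)
  expect_error(quickLook(mv, reference_frames = 1:50,
                         roi = matrix(FALSE, 6, 6)), "ROI")
})
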