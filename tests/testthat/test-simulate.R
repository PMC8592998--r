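test_that("a null oscillation leaves the field at rest with no onsets", {
  im <- imagingParams(n_frames = 500, height = 10, width = 10,
                      n_masked_pixels = 5)
  sp <- oscillationSpec(onset_time = 100, amplitude = 0,
                        n_fluctuations = 0, base_frequency = 15)
  sim <- generateVoltageField(sp, im, seed = 1)
  expect_true(all(voltageValues(sim$field) == -70))
  expect_true(all(is.na(perPixelOnset(sim$truth))))
  expect_equal(trueDuration(sim$truth), 0)
})

test_that("participating pixels carry the analytic waveform cycle count", {
  im <- imagingParams(n_frames = 2000, height = 12, width = 12,
                      n_masked_pixels = 10)
  sp <- oscillationSpec(onset_time = 500, amplitude = 30,
                        n_fluctuations = 5, base_frequency = 15,
                        decay_tau = 200, active_fraction = 0.5)
  sim <- generateVoltageField(sp, im, seed = 2)
  tr <- perPixelOnset(sim$truth)
  act <- which(!is.na(tr), arr.ind = TRUE)
  # brute-force zero-crossing count on the analytic closed-form trace
  u <- (0:1999) - 500
  analytic <- 30 * exp(-u / 200) * sin(2 * pi * 15 * u / 1000)
  analytic[u < 0 | u > 1000 * 5.5 / 15] <- 0
  expected <- zeroCrossCyclesOracle(analytic)
  for (k in seq_len(min(3, nrow(act)))) {
    trace <- voltageValues(sim$field)[, act[k, 1], act[k, 2]] + 70
    expect_equal(zeroCrossCyclesOracle(trace), expected)
  }
  expect_equal(trueDuration(sim$truth), 1000 * 5.5 / 15, tolerance = 1e-9)
})

test_that("waving onsets are a perfect linear gradient at the set speed", {
  im <- imagingParams(n_frames = 2500, height = 30, width = 30,
                      n_masked_pixels = 0)
  sp <- oscillationSpec(onset_time = 200, amplitude = 30,
                        n_fluctuations = 4, base_frequency = 15,
                        spatial_mode = "waving", propagation_speed = 0.5,
                        active_fraction = 1)
  sim <- generateVoltageField(sp, im, seed = 5)
  tr <- perPixelOnset(sim$truth)
  df <- data.frame(onset = as.vector(tr),
                   row = as.vector(row(tr)), col = as.vector(col(tr)))
  fit <- lm(onset ~ row + col, data = df)
  expect_lt(max(abs(residuals(fit))), 1e-8)          # exactly affine
  grad <- sqrt(sum(coef(fit)[2:3]^2))                # ms per pixel
  expect_equal(grad, 1 / 0.5, tolerance = 1e-6)      # distance / speed
})

test_that("oscillations that outrun the recording are rejected", {
  im <- imagingParams(n_frames = 300, height = 8, width = 8,
                      n_masked_pixels = 0)
  sp <- oscillationSpec(onset_time = 200, amplitude = 30,
                        n_fluctuations = 10, base_frequency = 10)
  expect_error(generateVoltageField(sp, im, seed = 1), "exceeds")
})

test_that("noise-free rendering reproduces the closed-form bleach curve", {
  im <- imagingParams(n_frames = 400, height = 6, width = 6,
                      n_masked_pixels = 4, noise_sd = 0, bleach_tau = 5000,
                      baseline_counts = 1500)
  sp <- oscillationSpec(amplitude = 0, n_fluctuations = 0, onset_time = 10)
  sim <- generateVoltageField(sp, im, seed = 1)
  mv <- renderMovie(sim$field, geviPresets()$ArcLight, im, seed = 1)
  expected <- 1500 * exp(-(0:399) / 5000)
  unmasked <- which(!maskedPixels(mv$truth), arr.ind = TRUE)
  for (k in 1:3)
    expect_equal(movieCounts(mv$movie)[, unmasked[k, 1], unmasked[k, 2]],
                 expected, tolerance = 1e-12)
  # no bleaching: flat at baseline
  im2 <- imagingParams(n_frames = 400, height = 6, width = 6,
                       n_masked_pixels = 4, noise_sd = 0, bleach_tau = Inf,
                       baseline_counts = 1500)
  mv2 <- renderMovie(sim$field, geviPresets()$ArcLight, im2, seed = 1)
  expect_equal(movieCounts(mv2$movie)[, unmasked[1, 1], unmasked[1, 2]],
               rep(1500, 400), tolerance = 1e-12)
})

test_that("rendering is bit-identical per seed and truth is seed-stable", {
  im <- imagingParams(n_frames = 300, height = 8, width = 8,
                      n_masked_pixels = 6, noise_sd = 4,
                      common_noise_cv = 0.002, shot_noise = TRUE)
  sp <- oscillationSpec(onset_time = 80, amplitude = 30, n_fluctuations = 2,
                        base_frequency = 20)
  sim <- generateVoltageField(sp, im, seed = 9)
  a <- renderMovie(sim$field, geviPresets()$ArcLight, im, seed = 42)
  b <- renderMovie(sim$field, geviPresets()$ArcLight, im, seed = 42)
  c <- renderMovie(sim$field, geviPresets()$ArcLight, im, seed = 43)
  expect_identical(movieCounts(a$movie), movieCounts(b$movie))
  expect_false(identical(movieCounts(a$movie), movieCounts(c$movie)))
  # distinct seeds change only the noise realisation, not the truth
  s2 <- generateVoltageField(sp, im, seed = 9)
  expect_identical(perPixelOnset(sim$truth), perPixelOnset(s2$truth))
})

test_that("geometry mismatches are rejected", {
  im <- imagingParams(n_frames = 200, height = 8, width = 8,
                      n_masked_pixels = 0)
  sp <- oscillationSpec(onset_time = 20, amplitude = 10, n_fluctuations = 2,
                        base_frequency = 30)
  sim <- generateVoltageField(sp, im, seed = 1)
  im_bad <- imagingParams(n_frames = 200, height = 10, width = 8,
                          n_masked_pixels = 0, noise_sd = 0)
  expect_error(renderMovie(sim$field, geviPresets()$ArcLight, im_bad,
                           seed = 1), "geometries")
})

test_that("synthetic LFP has the expected sign, locality and noise floor", {
  im <- imagingParams(n_frames = 1000, height = 15, width = 15,
                      n_masked_pixels = 0)
  # single-pixel oscillation at the electrode
  sp <- oscillationSpec(onset_time = 200, amplitude = 30, n_fluctuations = 4,
                        base_frequency = 20, active_fraction = 1e-9)
  sim <- generateVoltageField(sp, im, seed = 1,
                              active_pixels = list(8L + 7L * 15L)) # px (8, 8)
  lfp <- synthLFP(sim$field, electrode = c(8, 8), noise_sd = 0)
  vdev <- voltageValues(sim$field)[, 8, 8] + 70
  lfp_1k <- lfp$value[seq(1, nrow(lfp), by = 2)]   # 2 kHz -> 1 kHz samples
  expect_equal(cor(lfp_1k, vdev), -1, tolerance = 1e-9)
  # far-away electrode with compact weighting sees almost nothing
  far <- synthLFP(sim$field, electrode = c(1, 15), noise_sd = 0,
                  sigma_px = 1.5)
  expect_lt(max(abs(far$value)), max(abs(lfp$value)) * 1e-4)
  # zero field -> pure noise at the requested SD
  null_field <- generateVoltageField(
    oscillationSpec(amplitude = 0, n_fluctuations = 0, onset_time = 0),
    im, seed = 1)
  noise <- synthLFP(null_field$field, electrode = c(8, 8), noise_sd = 0.5,
                    seed = 11)
  expect_equal(sd(noise$value), 0.5, tolerance = 0.05)
  expect_error(synthLFP(sim$field, electrode = c(99, 1)), "inside")
})

test_that("noise calibration hits the requested SNR after the bandpass", {
  fx <- sharedStudyFixture()
  # per-pixel SNR was calibrated to 20; measure it on an active pixel
  tr <- perPixelOnset(fx$sim$truth)
  act <- which(!is.na(tr) & !maskedPixels(fx$wf))
  v <- waveformMatrix(fx$wf)
  snrs <- vapply(act[1:25], function(p) {
    max(abs(v[300:2800, p])) / baselineSd(fx$wf)[p]
  }, numeric(1))
  expect_equal(median(snrs), 20, tolerance = 0.25 * 20)
})
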