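## Synthetic recordings: ground-truth voltage fields -> GEVI kinetics ->
## camera model. Everything downstream of the pipeline can be exercised
## against the GroundTruth these functions return.

#' Closed-form oscillation waveform
#'
#' The stereotyped event: a large initial deflection (first half-cycle)
#' followed by \code{n_fluctuations} full cycles whose envelope decays
#' exponentially. \code{s(u) = A exp(-u/decay_tau) sin(2 pi f u / 1000)}
#' for \code{u} in \code{[0, U]} with \code{U = 1000 (n_fluctuations +
#' 0.5) / f} ms, zero outside.
#'
#' @param u time since onset, ms (vector).
#' @param amplitude A, mV.
#' @param base_frequency f, Hz.
#' @param n_fluctuations full cycles after the initial half-cycle
#'   deflection.
#' @param decay_tau envelope time constant, ms.
#' @param polarity \code{"depolarizing"} (positive initial lobe) or
#'   \code{"hyperpolarizing"}.
#' @return Deviation from rest, mV, same length as \code{u}.
#' @export
oscillationWaveform <- function(u, amplitude, base_frequency, n_fluctuations,
                                decay_tau, polarity = "depolarizing") {
  stopifnot(base_frequency > 0, decay_tau > 0)
  u_end <- 1000 * (n_fluctuations + 0.5) / base_frequency
  pol <- if (polarity == "hyperpolarizing") -1 else 1
  v <- pol * amplitude * exp(-u / decay_tau) *
    sin(2 * pi * base_frequency * u / 1000)
  v[u < 0 | u > u_end] <- 0
  v
}

#' Total span of one oscillation spec, ms
#' @param spec an [OscillationSpec-class].
#' @return Duration from onset to the end of the last cycle, ms.
#' @export
oscillationSpan <- function(spec) {
  1000 * (spec@nFluctuations + 0.5) / spec@baseFrequency
}

## Deterministic out-of-slice mask: the n pixels nearest the (1, 1)
## corner -- a contiguous region emulating the tissue edge.
borderMask <- function(height, width, n_masked) {
  m <- matrix(FALSE, height, width)
  if (n_masked <= 0) return(m)
  d <- outer(seq_len(height) - 1L, seq_len(width) - 1L,
             function(r, c) sqrt(r^2 + c^2))
  ord <- order(d, seq_along(d))  # index tie-break keeps this deterministic
  m[ord[seq_len(n_masked)]] <- TRUE
  m
}

#' Generate a ground-truth membrane-voltage field
#'
#' Builds a T x H x W voltage field at \code{rest_potential} everywhere,
#' then adds each oscillation in \code{specs}. Participating pixels are
#' drawn (seeded) from the in-slice pixels. In \code{waving} mode the
#' per-pixel onset increases linearly along a randomly oriented
#' propagation axis at \code{propagation_speed}; in
#' \code{in_place_punctate} mode scattered pixels start synchronously;
#' in \code{in_place_decrementing} mode a disc of pixels starts
#' synchronously with amplitude falling off from its centre.
#'
#' @param specs one [OscillationSpec-class] or a list of them (their
#'   voltage deviations add).
#' @param imaging an [ImagingParams-class] (geometry, rate, mask size).
#' @param seed integer; drives participant sampling and wave
#'   orientation.
#' @param rest_potential resting membrane potential, mV.
#' @param active_pixels optional list (one element per spec) of in-slice
#'   pixel indices (column-major) forced to participate, overriding the
#'   seeded draw — convenient for ground-truth-controlled fixtures.
#' @return \code{list(field = VoltageField, truth = GroundTruth)}. The
#'   truth records each pixel's earliest true onset (ms) and the overall
#'   true duration (first onset to last cycle end).
#' @examples
#' im <- imagingParams(n_frames = 1500, height = 16, width = 16,
#'                     n_masked_pixels = 20)
#' sim <- generateVoltageField(oscillationSpec(onset_time = 600), im, seed = 1)
#' sim$truth
#' @export
generateVoltageField <- function(specs, imaging, seed = 1,
                                 rest_potential = -70,
                                 active_pixels = NULL) {
  if (is(specs, "OscillationSpec")) specs <- list(specs)
  stopifnot(all(vapply(specs, is, TRUE, "OscillationSpec")))
  validObject(imaging)
  h <- as.integer(imaging@height); w <- as.integer(imaging@width)
  nt <- as.integer(imaging@nFrames)
  dt <- 1000 / imaging@frameRate
  tms <- (seq_len(nt) - 1) * dt
  mask <- borderMask(h, w, imaging@nMaskedPixels)
  inslice <- which(!mask)
  rows <- ((seq_len(h * w) - 1L) %% h) + 1L
  cols <- ((seq_len(h * w) - 1L) %/% h) + 1L

  vals <- matrix(rest_potential, nt, h * w)
  onset_map <- matrix(NA_real_, h, w)
  t_first <- Inf; t_last <- -Inf

  withr::with_seed(seed, {
    for (si in seq_along(specs)) {
      sp <- specs[[si]]
      validObject(sp)
      if (sp@amplitude == 0 || sp@nFluctuations == 0) next
      span <- oscillationSpan(sp)
      n_act <- max(1L, round(sp@activeFraction * length(inslice)))
      if (!is.null(active_pixels) && !is.null(active_pixels[[si]])) {
        act <- active_pixels[[si]]
        if (any(mask[act])) stop("active_pixels must be in-slice")
      } else if (sp@spatialMode == "in_place_decrementing") {
        ctr <- inslice[sample.int(length(inslice), 1L)]
        d <- sqrt((rows[inslice] - rows[ctr])^2 + (cols[inslice] - cols[ctr])^2)
        act <- inslice[order(d, seq_along(d))[seq_len(n_act)]]
      } else {
        act <- inslice[sample.int(length(inslice), n_act)]
      }

      scale <- rep(1, length(act))
      if (sp@spatialMode == "in_place_decrementing") {
        ctr_r <- mean(rows[act]); ctr_c <- mean(cols[act])
        d <- sqrt((rows[act] - ctr_r)^2 + (cols[act] - ctr_c)^2)
        radius <- max(d, 1)
        scale <- exp(-(d / radius)^2)  # gentle falloff toward the rim
      }

      if (sp@spatialMode == "waving") {
        theta <- runif(1, 0, 2 * pi)
        proj <- cos(theta) * cols[act] + sin(theta) * rows[act]
        onsets <- sp@onsetTime + (proj - min(proj)) / sp@propagationSpeed
      } else {
        onsets <- rep(sp@onsetTime, length(act))
      }

      if (max(onsets) + span > (nt - 1) * dt)
        stop("oscillation (onset + duration) exceeds the recording length")

      i0 <- max(1L, floor(min(onsets) / dt) + 1L)
      i1 <- min(nt, ceiling((max(onsets) + span) / dt) + 1L)
      tw <- tms[i0:i1]
      u <- outer(tw, onsets, "-")
      dim(u) <- NULL
      dev <- oscillationWaveform(u, sp@amplitude, sp@baseFrequency,
                                 sp@nFluctuations, sp@decayTau, sp@polarity)
      dim(dev) <- c(length(tw), length(act))
      dev <- sweep(dev, 2L, scale, "*")
      vals[i0:i1, act] <- vals[i0:i1, act] + dev

      prev <- onset_map[act]
      onset_map[act] <- ifelse(is.na(prev), onsets, pmin(prev, onsets))
      t_first <- min(t_first, min(onsets))
      t_last <- max(t_last, max(onsets) + span)
    }
  })

  dim(vals) <- c(nt, h, w)
  field <- new("VoltageField", values = vals, dt = dt,
               restPotential = rest_potential)
  truth <- new("GroundTruth", specs = specs, perPixelOnset = onset_map,
               trueDuration = if (is.finite(t_first)) t_last - t_first else 0,
               mask = mask)
  list(field = field, truth = truth)
}

## Boltzmann steady-state fluorescence change (percent) at voltage V.
steadyStateDf <- function(v, gevi) {
  gevi@dfMax / (1 + exp(-(v - gevi@vHalf) / gevi@slope))
}

#' GEVI kinetic transfer function
#'
#' Maps a membrane-voltage time series to the probe's fractional
#' fluorescence response. The steady-state response follows the
#' Boltzmann curve \code{F_ss(V) = dfMax / (1 + exp(-(V -
#' vHalf)/slope))}, baselined so the resting potential maps to 0. The
#' temporal response is the weighted sum of two parallel first-order
#' relaxations toward \code{F_ss(V(t))}: on-kinetics
#' (\code{tauOnFast/tauOnSlow}, fast fraction \code{fracOnFast}) while
#' the target deviation exceeds the current response deviation, and
#' off-kinetics otherwise — the simplest dynamical model whose step
#' responses reproduce the probes' published bi-exponential fits.
#' Because \code{dfMax < 0} for the ArcLight family, depolarisation
#' yields a negative dF/F.
#'
#' @param voltage numeric vector or T x P matrix of membrane potential,
#'   mV (finite).
#' @param gevi a [GeviParams-class].
#' @param dt sampling interval, ms.
#' @param rest_potential baseline voltage; defaults to the first sample.
#' @return Fractional fluorescence change, percent, same shape as
#'   \code{voltage}; identically 0 for a constant trace at rest.
#' @examples
#' gp <- geviPresets()$ArcLight
#' v <- c(rep(-70, 100), rep(0, 400))   # 1 ms steps
#' df <- geviTransfer(v, gp, dt = 1)
#' range(df)
#' @export
geviTransfer <- function(voltage, gevi, dt, rest_potential = NULL) {
  validObject(gevi)
  stopifnot(dt > 0)
  vrng <- suppressWarnings(range(voltage))
  if (anyNA(vrng) || any(!is.finite(vrng))) stop("voltage must be finite")
  vec <- is.null(dim(voltage))
  vmat <- if (vec) matrix(voltage, ncol = 1) else voltage
  if (is.null(rest_potential)) rest_potential <- vmat[1, 1]
  target <- steadyStateDf(vmat, gevi)
  base <- steadyStateDf(rest_potential, gevi)
  out <- cpp_gevi_dynamics(target, base, dt,
                           gevi@tauOnFast, gevi@tauOnSlow, gevi@fracOnFast,
                           gevi@tauOffFast, gevi@tauOffSlow, gevi@fracOffFast)
  if (vec) drop(out) else out
}

## Factor by which the zero-phase analysis bandpass shrinks white-noise
## SD: sqrt of the mean squared (two-pass) gain over 0..Nyquist.
filterNoiseFactor <- function(rate, low = 5, high = 50, order = 5,
                              ngrid = 4096) {
  f <- seq(0, rate / 2, length.out = ngrid + 1)[-1]
  g <- butterCascadeGain(f, low, high, order, rate)^2  # zero-phase
  sqrt(mean(g^2))
}

#' Read-noise SD that puts a response at a target SNR
#'
#' Works backwards from a desired post-filter SNR: given the peak
#' fractional-fluorescence response (percent) a probe produces on a
#' fixture, returns the Gaussian read-noise SD (camera counts) such
#' that, after the analysis bandpass, the per-pixel baseline noise SD is
#' \code{peak / target_snr}.
#'
#' @param peak_dff peak |dF/F| of the rendered response, percent
#'   (after bandpass).
#' @param imaging an [ImagingParams-class] (baseline counts, rate).
#' @param target_snr desired peak / baseline-SD ratio.
#' @param low,high,order the analysis bandpass the SNR is defined under.
#' @return Read-noise SD in camera counts.
#' @export
noiseSdForSnr <- function(peak_dff, imaging, target_snr,
                          low = 5, high = 50, order = 5) {
  stopifnot(target_snr > 0, peak_dff > 0)
  nf <- filterNoiseFactor(imaging@frameRate, low, high, order)
  sd_pct_raw <- (peak_dff / target_snr) / nf
  sd_pct_raw / 100 * imaging@baselineCounts
}

#' Illumination-noise CV that caps averaged-waveform SNR
#'
#' The counterpart of [noiseSdForSnr()] for the shared multiplicative
#' illumination noise: returns the coefficient of variation such that,
#' after the analysis bandpass, the noise floor common to all pixels
#' sits at \code{peak / target_snr}. Because this component survives
#' pixel averaging, it sets the SNR ceiling of the representative
#' (pixel-averaged) oscillation waveform.
#'
#' @param peak_dff peak |dF/F| of the rendered response, percent (after
#'   bandpass).
#' @param target_snr desired ceiling for peak / baseline-SD of averaged
#'   waveforms.
#' @param rate frame rate, Hz.
#' @param low,high,order the analysis bandpass.
#' @return Coefficient of variation (unitless fraction).
#' @export
commonCvForSnr <- function(peak_dff, target_snr, rate = 1000,
                           low = 5, high = 50, order = 5) {
  stopifnot(target_snr > 0, peak_dff > 0)
  nf <- filterNoiseFactor(rate, low, high, order)
  (peak_dff / target_snr) / nf / 100
}

#' Render a fluorescence movie from a voltage field
#'
#' Passes every pixel's voltage through the GEVI transfer function and
#' applies the camera model: \code{counts = baseline exp(-t/bleachTau)
#' (1 + dFF/100)} plus Gaussian read noise and optional Poisson shot
#' noise. Out-of-slice pixels are rendered dark (2 percent of baseline).
#' Rendering is reproducible: the same seed gives a bit-identical movie.
#'
#' @param field a [VoltageField-class].
#' @param gevi a [GeviParams-class].
#' @param imaging an [ImagingParams-class]; geometry must match the
#'   field. When \code{noiseSd} is \code{NA} the read noise is
#'   calibrated so the field's largest response sits at the probe's
#'   reference SNR (\code{snrRef}) after the analysis bandpass.
#' @param seed integer; drives the noise realisation only.
#' @param truth optional [GroundTruth-class] from
#'   [generateVoltageField()], passed through (its mask must agree with
#'   \code{imaging}).
#' @return \code{list(movie = Movie, truth = GroundTruth)}.
#' @examples
#' im <- imagingParams(n_frames = 1200, height = 12, width = 12,
#'                     n_masked_pixels = 10, noise_sd = 2)
#' sim <- generateVoltageField(oscillationSpec(onset_time = 500,
#'                                             n_fluctuations = 3), im, seed = 2)
#' mv <- renderMovie(sim$field, geviPresets()$ArcLight, im, seed = 2,
#'                   truth = sim$truth)
#' mv$movie
#' @export
renderMovie <- function(field, gevi, imaging, seed = 1, truth = NULL) {
  validObject(field); validObject(gevi); validObject(imaging)
  d <- dim(field@values)
  if (d[1] != imaging@nFrames || d[2] != imaging@height ||
      d[3] != imaging@width)
    stop("field and imaging geometries disagree")
  if (imaging@baselineCounts < 0) stop("negative baseline_counts")
  nt <- d[1]; np <- d[2] * d[3]
  dt <- field@dt
  vmat <- field@values
  dim(vmat) <- c(nt, np)
  # in-place: vmat becomes the percent-dF/F matrix, then the counts
  cpp_gevi_transfer_ip(vmat, gevi@vHalf, gevi@slope, gevi@dfMax,
                       field@restPotential, dt,
                       gevi@tauOnFast, gevi@tauOnSlow, gevi@fracOnFast,
                       gevi@tauOffFast, gevi@tauOffSlow, gevi@fracOffFast)

  noise_sd <- imaging@noiseSd
  if (is.na(noise_sd)) {
    ref_px <- which.max(cpp_col_absmax(vmat))
    ref_trace <- bandpass(vmat[, ref_px], frame_rate = imaging@frameRate)
    peak <- max(abs(ref_trace))
    if (peak <= 0) stop("cannot calibrate noise: the field has no response")
    noise_sd <- noiseSdForSnr(peak, imaging, gevi@snrRef)
  }

  mask <- borderMask(d[2], d[3], imaging@nMaskedPixels)
  if (!is.null(truth) && !identical(truth@mask, mask))
    stop("truth mask does not match the imaging mask")

  bleach <- if (is.finite(imaging@bleachTau))
    exp(-(seq_len(nt) - 1) * dt / imaging@bleachTau) else rep(1, nt)
  withr::with_seed(seed, {
    common <- if (imaging@commonNoiseCv > 0)
      rnorm(nt, sd = imaging@commonNoiseCv) else numeric(0)
    cpp_camera_ip(vmat, bleach, imaging@baselineCounts, as.vector(mask),
                  0.02, common, noise_sd, imaging@shotNoise)
  })
  dim(vmat) <- d

  movie <- new("Movie", counts = vmat, frameRate = imaging@frameRate,
               origin = list(gevi = gevi@name, seed = seed,
                             noise_sd = noise_sd))
  if (is.null(truth))
    truth <- new("GroundTruth", specs = list(),
                 perPixelOnset = matrix(NA_real_, d[2], d[3]),
                 trueDuration = 0, mask = mask)
  list(movie = movie, truth = truth)
}

#' Synthesise a local field potential from a voltage field
#'
#' The LFP is modelled as the negative, spatially weighted (Gaussian
#' kernel around the electrode) average of the voltage deviations from
#' rest, linearly resampled to the electrophysiology rate, plus Gaussian
#' noise. The sign convention makes population depolarisation deflect
#' the LFP downward.
#'
#' @param field a [VoltageField-class].
#' @param electrode integer (row, col) electrode position, 1-based,
#'   inside the frame.
#' @param noise_sd additive Gaussian noise SD, arbitrary units.
#' @param seed integer, noise realisation.
#' @param sigma_px Gaussian weighting radius, pixels.
#' @param rate_out output sampling rate, Hz (default 2000).
#' @return \code{data.frame(time_ms, value)}.
#' @export
synthLFP <- function(field, electrode, noise_sd = 0, seed = 1,
                     sigma_px = 3, rate_out = 2000) {
  validObject(field)
  d <- dim(field@values)
  if (length(electrode) != 2 || electrode[1] < 1 || electrode[1] > d[2] ||
      electrode[2] < 1 || electrode[2] > d[3])
    stop("electrode must be a (row, col) position inside the frame")
  np <- d[2] * d[3]
  rows <- ((seq_len(np) - 1L) %% d[2]) + 1L
  cols <- ((seq_len(np) - 1L) %/% d[2]) + 1L
  wgt <- exp(-((rows - electrode[1])^2 + (cols - electrode[2])^2) /
               (2 * sigma_px^2))
  wgt <- wgt / sum(wgt)
  vmat <- field@values
  dim(vmat) <- c(d[1], np)
  lfp <- -as.vector((vmat - field@restPotential) %*% wgt)
  t_in <- (seq_len(d[1]) - 1) * field@dt
  t_out <- seq(0, max(t_in), by = 1000 / rate_out)
  v_out <- approx(t_in, lfp, xout = t_out)$y
  if (noise_sd > 0)
    v_out <- v_out + withr::with_seed(seed, rnorm(length(v_out), sd = noise_sd))
  data.frame(time_ms = t_out, value = v_out)
}
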