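#' Construct GEVI transfer parameters
#'
#' @param name probe label.
#' @param v_half half-activation membrane potential, mV.
#' @param tau_on_fast,tau_on_slow on time constants, ms.
#' @param frac_on_fast fast fraction of the on response, in \[0, 1\].
#' @param tau_off_fast,tau_off_slow off time constants, ms.
#' @param frac_off_fast fast fraction of the off response, in \[0, 1\].
#' @param df_max maximal fractional fluorescence change, percent
#'   (negative for ArcLight-family probes).
#' @param snr_ref reference SNR of a full-scale response.
#' @param slope sigmoid steepness, mV. The steepness of the
#'   fluorescence-voltage curve is a simulator convention (it is not a
#'   published probe constant); 20 mV is the default.
#'
#' @return A [GeviParams-class] object.
#' @examples
#' gp <- geviParams("toy", v_half = -30, tau_on_fast = 10, frac_on_fast = 1,
#'                  tau_on_slow = 50, tau_off_fast = 20, frac_off_fast = 1,
#'                  tau_off_slow = 60, df_max = -15, snr_ref = 10)
#' gp
#' @export
geviParams <- function(name, v_half, tau_on_fast, frac_on_fast, tau_on_slow,
                       tau_off_fast, frac_off_fast, tau_off_slow,
                       df_max, snr_ref, slope = 20) {
  new("GeviParams", name = name, vHalf = v_half,
      tauOnFast = tau_on_fast, fracOnFast = frac_on_fast,
      tauOnSlow = tau_on_slow, tauOffFast = tau_off_fast,
      fracOffFast = frac_off_fast, tauOffSlow = tau_off_slow,
      dfMax = df_max, snrRef = snr_ref, slope = slope)
}

#' Built-in GEVI parameter presets
#'
#' Step-response and steady-state parameters of the three probes the
#' pipeline was designed around: ArcLight-A242 and its two
#' faster-kinetics derivatives Bongwoori-Pos6 and Bongwoori-R3.
#' ArcLight responds slowly (bi-exponential off response of 22 ms (70\%)
#' / 74 ms) but with the largest fluorescence change and SNR;
#' Bongwoori-Pos6 has near-single-exponential fast kinetics and a V1/2
#' close to rest; Bongwoori-R3 is fast but right-shifted (V1/2 -3 mV),
#' so it responds mainly to strong depolarisations. Bongwoori-Pos6's on
#' response is single-exponential (fast fraction 100\%); its slow on
#' constant is a placeholder that never contributes.
#'
#' @param slope sigmoid steepness, mV, applied to every preset (a
#'   simulator convention, see [geviParams()]).
#' @return Named list of [GeviParams-class]: \code{ArcLight},
#'   \code{Bongwoori-Pos6}, \code{Bongwoori-R3}.
#' @examples
#' geviPresets()$ArcLight
#' @export
geviPresets <- function(slope = 20) {
  list(
    "ArcLight" = geviParams("ArcLight", v_half = -26,
      tau_on_fast = 10, frac_on_fast = 0.65, tau_on_slow = 53,
      tau_off_fast = 22, frac_off_fast = 0.70, tau_off_slow = 74,
      df_max = -19.7, snr_ref = 22.2, slope = slope),
    "Bongwoori-Pos6" = geviParams("Bongwoori-Pos6", v_half = -28,
      tau_on_fast = 6, frac_on_fast = 1.00, tau_on_slow = 6,
      tau_off_fast = 8, frac_off_fast = 0.97, tau_off_slow = 80,
      df_max = -10.7, snr_ref = 6.7, slope = slope),
    "Bongwoori-R3" = geviParams("Bongwoori-R3", v_half = -3,
      tau_on_fast = 7, frac_on_fast = 0.90, tau_on_slow = 45,
      tau_off_fast = 6, frac_off_fast = 0.91, tau_off_slow = 46,
      df_max = -15.4, snr_ref = 9.6, slope = slope)
  )
}

#' Construct an oscillation specification
#'
#' @param onset_time onset, ms.
#' @param amplitude initial deflection amplitude, mV.
#' @param n_fluctuations number of full cycles following the initial
#'   deflection (stereotypically 2-19).
#' @param base_frequency Hz (5-50 Hz for detectability under the
#'   analysis bandpass).
#' @param decay_tau envelope decay time constant, ms.
#' @param spatial_mode \code{"waving"}, \code{"in_place_punctate"} or
#'   \code{"in_place_decrementing"}.
#' @param propagation_speed px/ms (waving mode).
#' @param active_fraction fraction of in-slice pixels participating.
#' @param polarity \code{"depolarizing"} or \code{"hyperpolarizing"}.
#' @return An [OscillationSpec-class] object.
#' @examples
#' oscillationSpec(onset_time = 1000, amplitude = 30, n_fluctuations = 5,
#'                 base_frequency = 15)
#' @export
oscillationSpec <- function(onset_time = 1000, amplitude = 30,
                            n_fluctuations = 5, base_frequency = 15,
                            decay_tau = 200,
                            spatial_mode = c("in_place_punctate", "waving",
                                             "in_place_decrementing"),
                            propagation_speed = 0.5, active_fraction = 0.5,
                            polarity = c("depolarizing", "hyperpolarizing")) {
  new("OscillationSpec", onsetTime = onset_time, amplitude = amplitude,
      nFluctuations = n_fluctuations, baseFrequency = base_frequency,
      decayTau = decay_tau, spatialMode = match.arg(spatial_mode),
      propagationSpeed = propagation_speed, activeFraction = active_fraction,
      polarity = match.arg(polarity))
}

#' Construct imaging/camera parameters
#'
#' Defaults give the native acquisition: a 10 s, 10,000-frame movie of
#' 80 x 80 pixels at 1 kHz with 389 dark border pixels.
#'
#' @param n_frames frame count.
#' @param height,width pixels.
#' @param frame_rate Hz.
#' @param baseline_counts mean fluorescence, camera counts.
#' @param bleach_tau photobleaching time constant, ms (\code{Inf} for no
#'   bleaching).
#' @param noise_sd Gaussian read-noise SD in counts; \code{NA} asks
#'   [renderMovie()] to calibrate it so a full-scale response of the
#'   rendered probe reaches the probe's reference SNR after the analysis
#'   bandpass.
#' @param shot_noise add Poisson shot noise on top of read noise.
#' @param common_noise_cv coefficient of variation of the shared
#'   multiplicative illumination (lamp) noise; 0 disables it. Because
#'   every pixel sees the same illumination fluctuation, this component
#'   survives pixel averaging and caps the SNR of averaged waveforms
#'   the way real widefield recordings are capped.
#' @param n_masked_pixels dark out-of-slice border pixels.
#' @return An [ImagingParams-class] object.
#' @examples
#' imagingParams(n_frames = 2000, height = 20, width = 20)
#' @export
imagingParams <- function(n_frames = 10000, height = 80, width = 80,
                          frame_rate = 1000, baseline_counts = 2000,
                          bleach_tau = 20000, noise_sd = NA_real_,
                          shot_noise = FALSE, common_noise_cv = 0,
                          n_masked_pixels = 389) {
  new("ImagingParams", nFrames = n_frames, height = height, width = width,
      frameRate = frame_rate, baselineCounts = baseline_counts,
      bleachTau = bleach_tau, noiseSd = as.numeric(noise_sd),
      shotNoise = shot_noise, commonNoiseCv = common_noise_cv,
      nMaskedPixels = n_masked_pixels)
}
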