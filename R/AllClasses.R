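#' @import methods
#' @importFrom stats approx coef cor fft lm optimize quantile rnorm rpois runif sd var
#' @importFrom utils head tail write.csv
#' @useDynLib gevipipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' GEVI kinetic and steady-state transfer parameters
#'
#' Parameters of one genetically encoded voltage indicator (GEVI): the
#' Boltzmann steady-state fluorescence-voltage curve (half-activation
#' voltage \code{vHalf}, steepness \code{slope}, maximal fractional
#' fluorescence change \code{dfMax}) and the bi-exponential on/off step
#' response (fast/slow time constants with the fast-component fraction).
#' \code{dfMax} is negative for the ArcLight family: depolarisation dims
#' the probe.
#'
#' @slot name character label.
#' @slot vHalf membrane potential (mV) of half-maximal fluorescence change.
#' @slot tauOnFast,tauOnSlow on (depolarising-step) time constants, ms.
#' @slot fracOnFast fraction of the on response carried by the fast
#'   component, in \[0, 1\].
#' @slot tauOffFast,tauOffSlow off (repolarising-step) time constants, ms.
#' @slot fracOffFast fraction of the off response carried by the fast
#'   component, in \[0, 1\].
#' @slot dfMax maximal fractional fluorescence change, percent (non-zero;
#'   negative for ArcLight-family probes).
#' @slot snrRef reference signal-to-noise ratio of a full-scale response.
#' @slot slope sigmoid steepness, mV (simulator convention; the
#'   steady-state curve is \code{dfMax / (1 + exp(-(V - vHalf)/slope))}).
#'
#' @seealso [geviParams()], [geviPresets()], [geviTransfer()]
#' @export
setClass("GeviParams", representation(
  name = "character",
  vHalf = "numeric",
  tauOnFast = "numeric", fracOnFast = "numeric", tauOnSlow = "numeric",
  tauOffFast = "numeric", fracOffFast = "numeric", tauOffSlow = "numeric",
  dfMax = "numeric", snrRef = "numeric", slope = "numeric"
))

setValidity("GeviParams", function(object) {
  msg <- character()
  taus <- c(object@tauOnFast, object@tauOnSlow, object@tauOffFast,
            object@tauOffSlow)
  if (any(!is.finite(taus)) || any(taus <= 0))
    msg <- c(msg, "all time constants must be finite and > 0")
  fr <- c(object@fracOnFast, object@fracOffFast)
  if (any(fr < 0) || any(fr > 1))
    msg <- c(msg, "fast fractions must lie in [0, 1]")
  if (!is.finite(object@dfMax) || object@dfMax == 0)
    msg <- c(msg, "dfMax must be finite and non-zero")
  if (!is.finite(object@slope) || object@slope <= 0)
    msg <- c(msg, "slope must be > 0")
  if (!is.finite(object@vHalf))
    msg <- c(msg, "vHalf must be finite")
  if (length(msg)) msg else TRUE
})

#' Specification of one synthetic oscillation
#'
#' Describes a stereotyped slice oscillation: a large initial deflection
#' (the first half-cycle) followed immediately by \code{nFluctuations}
#' full cycles at \code{baseFrequency} whose amplitude decays with time
#' constant \code{decayTau}. The spatial mode is either a propagating
#' ("waving") wave whose per-pixel onsets advance linearly along a random
#' axis, or an in-place mode without directionality (punctate scattered
#' participants, or a decrementing disc whose amplitude falls off with
#' distance from a centre).
#'
#' @slot onsetTime oscillation onset, ms from the start of the recording.
#' @slot amplitude initial deflection amplitude, mV.
#' @slot nFluctuations integer count of full cycles after the initial
#'   deflection (the slice stereotype spans 2-19).
#' @slot baseFrequency oscillation frequency, Hz (5-50 Hz for
#'   detectability under the analysis bandpass).
#' @slot decayTau envelope decay time constant, ms.
#' @slot spatialMode one of \code{"waving"}, \code{"in_place_punctate"},
#'   \code{"in_place_decrementing"}.
#' @slot propagationSpeed pixels/ms (waving mode only).
#' @slot activeFraction fraction of in-slice pixels participating.
#' @slot polarity \code{"depolarizing"} or \code{"hyperpolarizing"}.
#'
#' @seealso [oscillationSpec()], [generateVoltageField()]
#' @export
setClass("OscillationSpec", representation(
  onsetTime = "numeric", amplitude = "numeric", nFluctuations = "numeric",
  baseFrequency = "numeric", decayTau = "numeric", spatialMode = "character",
  propagationSpeed = "numeric", activeFraction = "numeric",
  polarity = "character"
))

setValidity("OscillationSpec", function(object) {
  msg <- character()
  modes <- c("waving", "in_place_punctate", "in_place_decrementing")
  if (!object@spatialMode %in% modes)
    msg <- c(msg, paste("spatialMode must be one of:",
                        paste(modes, collapse = ", ")))
  if (!object@polarity %in% c("depolarizing", "hyperpolarizing"))
    msg <- c(msg, "polarity must be 'depolarizing' or 'hyperpolarizing'")
  if (object@nFluctuations < 0 || object@nFluctuations != round(object@nFluctuations))
    msg <- c(msg, "nFluctuations must be a non-negative integer")
  if (object@baseFrequency <= 0) msg <- c(msg, "baseFrequency must be > 0")
  if (object@decayTau <= 0) msg <- c(msg, "decayTau must be > 0")
  if (object@spatialMode == "waving" && object@propagationSpeed <= 0)
    msg <- c(msg, "propagationSpeed must be > 0 in waving mode")
  if (object@activeFraction <= 0 || object@activeFraction > 1)
    msg <- c(msg, "activeFraction must lie in (0, 1]")
  if (object@onsetTime < 0) msg <- c(msg, "onsetTime must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Camera and acquisition parameters for the movie renderer
#'
#' Defaults reproduce the native acquisition geometry of the widefield
#' recordings the pipeline targets: 10,000 frames of 80 x 80 pixels at
#' 1 kHz (a 10 s movie), with an exponential photobleaching baseline,
#' Gaussian read noise (plus optional Poisson shot noise) and a
#' contiguous region of dark out-of-slice pixels along one border
#' (default count 389, the median masked-pixel count in the recordings
#' being emulated).
#'
#' @slot nFrames frame count.
#' @slot height,width frame geometry in pixels.
#' @slot frameRate acquisition rate, Hz.
#' @slot baselineCounts mean fluorescence level, camera counts.
#' @slot bleachTau photobleaching time constant, ms (\code{Inf} = none).
#' @slot noiseSd Gaussian read-noise SD, counts (\code{NA} = calibrate at
#'   render time so a full-scale GEVI response hits the probe's
#'   reference SNR).
#' @slot shotNoise logical; add Poisson shot noise.
#' @slot commonNoiseCv coefficient of variation of a multiplicative
#'   frame-wide illumination (lamp) noise shared by all pixels
#'   (default 0 = none). Unlike read noise, this component does not
#'   average away across pixels, so it sets the SNR ceiling of
#'   pixel-averaged waveforms.
#' @slot nMaskedPixels count of dark out-of-slice pixels.
#'
#' @seealso [imagingParams()], [renderMovie()]
#' @export
setClass("ImagingParams", representation(
  nFrames = "numeric", height = "numeric", width = "numeric",
  frameRate = "numeric", baselineCounts = "numeric", bleachTau = "numeric",
  noiseSd = "numeric", shotNoise = "logical", commonNoiseCv = "numeric",
  nMaskedPixels = "numeric"
))

setValidity("ImagingParams", function(object) {
  msg <- character()
  if (object@nFrames < 1 || object@height < 1 || object@width < 1)
    msg <- c(msg, "nFrames, height and width must be >= 1")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (object@baselineCounts <= 0) msg <- c(msg, "baselineCounts must be > 0")
  if (object@bleachTau <= 0) msg <- c(msg, "bleachTau must be > 0")
  if (object@commonNoiseCv < 0)
    msg <- c(msg, "commonNoiseCv must be >= 0")
  if (object@nMaskedPixels < 0 ||
      object@nMaskedPixels >= object@height * object@width)
    msg <- c(msg, "nMaskedPixels must lie in [0, height*width)")
  if (length(msg)) msg else TRUE
})

#' Ground-truth membrane-voltage field
#'
#' A T x H x W array of membrane potential (mV) at sampling interval
#' \code{dt} (ms). The field equals \code{restPotential} everywhere in
#' the absence of activity; oscillations are additive deviations.
#'
#' @slot values numeric array, time x height x width, mV.
#' @slot dt sampling interval, ms.
#' @slot restPotential resting membrane potential, mV.
#' @export
setClass("VoltageField", representation(
  values = "array", dt = "numeric", restPotential = "numeric"
))

setValidity("VoltageField", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3-d (time x height x width) array")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth attached to a synthetic recording
#'
#' @slot specs list of [OscillationSpec-class] objects that built the field.
#' @slot perPixelOnset H x W matrix of true initiation times (ms;
#'   \code{NA} where the pixel does not participate or is out of slice).
#' @slot trueDuration total true oscillation duration, ms (onset of the
#'   first to offset of the last active cycle).
#' @slot mask logical H x W matrix, \code{TRUE} = out-of-slice pixel.
#' @export
setClass("GroundTruth", representation(
  specs = "list", perPixelOnset = "matrix", trueDuration = "numeric",
  mask = "matrix"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!identical(dim(object@perPixelOnset), dim(object@mask)))
    msg <- c(msg, "perPixelOnset and mask must share dimensions")
  if (any(!is.na(object@perPixelOnset[object@mask])))
    msg <- c(msg, "onsets must be undefined on masked pixels")
  if (length(msg)) msg else TRUE
})

#' A widefield fluorescence movie
#'
#' Camera counts as a T x H x W array with the acquisition rate. Counts
#' are stored as doubles; quantisation to 16 bits happens only on
#' [writeMovie()].
#'
#' @slot counts numeric array, time x height x width, camera counts.
#' @slot frameRate acquisition rate, Hz.
#' @slot origin free-form provenance metadata list.
#' @seealso [readMovie()], [writeMovie()], [renderMovie()]
#' @export
setClass("Movie", representation(
  counts = "array", frameRate = "numeric", origin = "list"
))

setValidity("Movie", function(object) {
  msg <- character()
  if (length(dim(object@counts)) != 3L)
    msg <- c(msg, "counts must be a 3-d (time x height x width) array")
  rng <- suppressWarnings(range(object@counts))   # single pass, no copy
  if (anyNA(rng) || any(!is.finite(rng)))
    msg <- c(msg, "counts must be finite")
  if (isTRUE(rng[1] < 0))
    msg <- c(msg, "counts must be non-negative")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' Out-of-slice pixel mask
#'
#' @slot masked logical H x W matrix, \code{TRUE} = masked (dark,
#'   out-of-slice) pixel.
#' @slot nMasked number of masked pixels.
#' @seealso [maskDarkPixels()]
#' @export
setClass("PixelMask", representation(masked = "matrix", nMasked = "numeric"))

setValidity("PixelMask", function(object) {
  msg <- character()
  if (!is.logical(object@masked))
    msg <- c(msg, "masked must be a logical matrix")
  if (object@nMasked != sum(object@masked))
    msg <- c(msg, "nMasked must equal the number of TRUE entries")
  if (object@nMasked >= length(object@masked))
    msg <- c(msg, "at least one pixel must remain unmasked")
  if (length(msg)) msg else TRUE
})

#' Per-pixel %dF/F0 oscillation waveforms of one recording
#'
#' The product of preprocessing: every pixel's bandpassed, baseline
#' normalised fractional fluorescence change time series, stored as a
#' T x (H*W) matrix in column-major pixel order (pixel (r, c) maps to
#' column \code{r + (c-1)*H}; 1-based), together with the out-of-slice
#' mask and the per-pixel baseline noise SD.
#'
#' @slot values numeric T x (H*W) matrix, percent dF/F0.
#' @slot dims integer (height, width).
#' @slot frameRate Hz.
#' @slot mask logical H x W matrix (TRUE = masked).
#' @slot baselineSd numeric vector (length H*W): per-pixel Gaussian
#'   baseline noise SD, percent, estimated over the baseline window.
#' @seealso [preprocessMovie()]
#' @export
setClass("WaveformSet", representation(
  values = "matrix", dims = "integer", frameRate = "numeric",
  mask = "matrix", baselineSd = "numeric"
))

setValidity("WaveformSet", function(object) {
  msg <- character()
  np <- prod(object@dims)
  if (ncol(object@values) != np)
    msg <- c(msg, "values must have one column per pixel")
  if (length(object@baselineSd) != np)
    msg <- c(msg, "baselineSd must have one entry per pixel")
  if (!identical(dim(object@mask), as.integer(object@dims)))
    msg <- c(msg, "mask dimensions must match dims")
  if (length(msg)) msg else TRUE
})

#' A detected oscillation and its features
#'
#' The representative oscillation waveform of a recording (mean of the
#' pixels most correlated with the maximal-response reference pixel,
#' chosen to maximise SNR) with its 3-sigma bounds and derived features.
#' Bounds are \code{NA} (and \code{detected} is \code{FALSE}) when no
#' sample exceeds 3 sigma — a "no oscillation detected" outcome, not an
#' error.
#'
#' @slot representative numeric time series, percent dF/F0.
#' @slot memberPixels integer n x 2 matrix of (row, col) member pixels.
#' @slot referencePixel integer (row, col).
#' @slot frameRate Hz.
#' @slot baselineSd sigma of the representative's Gaussian baseline
#'   noise, percent.
#' @slot snr |peak| / baselineSd of the representative.
#' @slot detected logical.
#' @slot startMs,endMs,durationMs,peakTimeMs oscillation bounds (ms; the
#'   start/end are the first/last 3-sigma exceedances, peak time is
#'   relative to start).
#' @slot nCycles complete-cycle count in the analysis window.
#' @seealso [buildRepresentativeWaveform()], [detectBounds()]
#' @export
setClass("OscillationRecord", representation(
  representative = "numeric", memberPixels = "matrix",
  referencePixel = "integer", frameRate = "numeric", baselineSd = "numeric",
  snr = "numeric", detected = "logical",
  startMs = "numeric", endMs = "numeric", durationMs = "numeric",
  peakTimeMs = "numeric", nCycles = "numeric"
))

setValidity("OscillationRecord", function(object) {
  msg <- character()
  if (isTRUE(object@detected)) {
    if (!is.na(object@startMs) && !is.na(object@endMs) &&
        object@startMs > object@endMs)
      msg <- c(msg, "startMs must be <= endMs")
    if (!is.na(object@peakTimeMs) && !is.na(object@durationMs) &&
        (object@peakTimeMs < 0 || object@peakTimeMs > object@durationMs))
      msg <- c(msg, "peakTimeMs must lie within [0, durationMs]")
  }
  if (length(msg)) msg else TRUE
})
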