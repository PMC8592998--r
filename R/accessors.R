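#' @name accessors
#' @title Accessors for gevipipe classes
#'
#' @description Small accessor generics so downstream code never reaches
#' into slots: frame rates, geometries, waveform matrices, masks and
#' oscillation features.
#'
#' @param object a gevipipe S4 object.
#' @return The corresponding slot value; see each method.
NULL

#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setMethod("frameRate", "Movie", function(object) object@frameRate)
#' @rdname accessors
#' @export
setMethod("frameRate", "WaveformSet", function(object) object@frameRate)
#' @rdname accessors
#' @export
setMethod("frameRate", "OscillationRecord", function(object) object@frameRate)

#' @rdname accessors
#' @export
setGeneric("movieCounts", function(object) standardGeneric("movieCounts"))
#' @rdname accessors
#' @export
setMethod("movieCounts", "Movie", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("frameDims", function(object) standardGeneric("frameDims"))
#' @rdname accessors
#' @export
setMethod("frameDims", "Movie", function(object) dim(object@counts)[2:3])
#' @rdname accessors
#' @export
setMethod("frameDims", "WaveformSet", function(object) as.integer(object@dims))
#' @rdname accessors
#' @export
setMethod("frameDims", "VoltageField", function(object) dim(object@values)[2:3])

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "Movie", function(object) dim(object@counts)[1])
#' @rdname accessors
#' @export
setMethod("nFrames", "WaveformSet", function(object) nrow(object@values))

#' @rdname accessors
#' @export
setGeneric("maskedPixels", function(object) standardGeneric("maskedPixels"))
#' @rdname accessors
#' @export
setMethod("maskedPixels", "PixelMask", function(object) object@masked)
#' @rdname accessors
#' @export
setMethod("maskedPixels", "WaveformSet", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("maskedPixels", "GroundTruth", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("nMasked", function(object) standardGeneric("nMasked"))
#' @rdname accessors
#' @export
setMethod("nMasked", "PixelMask", function(object) object@nMasked)

#' @rdname accessors
#' @export
setGeneric("waveformMatrix", function(object) standardGeneric("waveformMatrix"))
#' @rdname accessors
#' @export
setMethod("waveformMatrix", "WaveformSet", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("baselineSd", function(object) standardGeneric("baselineSd"))
#' @rdname accessors
#' @export
setMethod("baselineSd", "WaveformSet", function(object) object@baselineSd)
#' @rdname accessors
#' @export
setMethod("baselineSd", "OscillationRecord", function(object) object@baselineSd)

#' @rdname accessors
#' @export
setGeneric("representative", function(object) standardGeneric("representative"))
#' @rdname accessors
#' @export
setMethod("representative", "OscillationRecord",
          function(object) object@representative)

#' @rdname accessors
#' @export
setGeneric("memberPixels", function(object) standardGeneric("memberPixels"))
#' @rdname accessors
#' @export
setMethod("memberPixels", "OscillationRecord",
          function(object) object@memberPixels)

#' @rdname accessors
#' @export
setGeneric("referencePixel", function(object) standardGeneric("referencePixel"))
#' @rdname accessors
#' @export
setMethod("referencePixel", "OscillationRecord",
          function(object) object@referencePixel)

#' @rdname accessors
#' @export
setGeneric("isDetected", function(object) standardGeneric("isDetected"))
#' @rdname accessors
#' @export
setMethod("isDetected", "OscillationRecord", function(object) object@detected)

#' @rdname accessors
#' @export
setGeneric("oscillationBounds", function(object)
  standardGeneric("oscillationBounds"))
#' @rdname accessors
#' @export
setMethod("oscillationBounds", "OscillationRecord", function(object)
  c(start_ms = object@startMs, end_ms = object@endMs,
    duration_ms = object@durationMs))

#' @rdname accessors
#' @export
setGeneric("voltageValues", function(object) standardGeneric("voltageValues"))
#' @rdname accessors
#' @export
setMethod("voltageValues", "VoltageField", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("restPotential", function(object) standardGeneric("restPotential"))
#' @rdname accessors
#' @export
setMethod("restPotential", "VoltageField", function(object) object@restPotential)

#' @rdname accessors
#' @export
setGeneric("perPixelOnset", function(object) standardGeneric("perPixelOnset"))
#' @rdname accessors
#' @export
setMethod("perPixelOnset", "GroundTruth", function(object) object@perPixelOnset)

#' @rdname accessors
#' @export
setGeneric("trueDuration", function(object) standardGeneric("trueDuration"))
#' @rdname accessors
#' @export
setMethod("trueDuration", "GroundTruth", function(object) object@trueDuration)

setMethod("show", "GeviParams", function(object) {
  cat("GeviParams:", object@name, "\n")
  cat(sprintf("  V1/2 %+.1f mV, slope %.1f mV, dF/F max %+.1f %%, ref SNR %.1f\n",
              object@vHalf, object@slope, object@dfMax, object@snrRef))
  cat(sprintf("  tau_on  %.1f ms (%.0f%%) / %.1f ms\n",
              object@tauOnFast, 100 * object@fracOnFast, object@tauOnSlow))
  cat(sprintf("  tau_off %.1f ms (%.0f%%) / %.1f ms\n",
              object@tauOffFast, 100 * object@fracOffFast, object@tauOffSlow))
})

setMethod("show", "OscillationSpec", function(object) {
  cat("OscillationSpec:", object@spatialMode, object@polarity, "\n")
  cat(sprintf("  onset %.0f ms, amplitude %.1f mV, %d cycles @ %.1f Hz, decay tau %.0f ms\n",
              object@onsetTime, object@amplitude,
              as.integer(object@nFluctuations), object@baseFrequency,
              object@decayTau))
  if (object@spatialMode == "waving")
    cat(sprintf("  propagation %.2f px/ms\n", object@propagationSpeed))
  cat(sprintf("  active fraction %.2f\n", object@activeFraction))
})

setMethod("show", "ImagingParams", function(object) {
  cat(sprintf("ImagingParams: %d frames of %d x %d px @ %.0f Hz\n",
              as.integer(object@nFrames), as.integer(object@height),
              as.integer(object@width), object@frameRate))
  cat(sprintf("  baseline %.0f counts, bleach tau %s ms, noise SD %s, shot noise %s\n",
              object@baselineCounts, format(object@bleachTau),
              ifelse(is.na(object@noiseSd), "auto", format(object@noiseSd)),
              object@shotNoise))
  cat(sprintf("  %d masked border pixels\n", as.integer(object@nMaskedPixels)))
})

setMethod("show", "Movie", function(object) {
  d <- dim(object@counts)
  cat(sprintf("Movie: %d frames of %d x %d px @ %.0f Hz (%.1f s)\n",
              d[1], d[2], d[3], object@frameRate, d[1] / object@frameRate))
})

setMethod("show", "PixelMask", function(object) {
  cat(sprintf("PixelMask: %d / %d pixels masked\n",
              as.integer(object@nMasked), length(object@masked)))
})

setMethod("show", "WaveformSet", function(object) {
  cat(sprintf("WaveformSet: %d x %d px, %d frames @ %.0f Hz, %d masked\n",
              object@dims[1], object@dims[2], nrow(object@values),
              object@frameRate, sum(object@mask)))
})

setMethod("show", "VoltageField", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoltageField: %d samples of %d x %d px, dt %.2f ms, rest %.0f mV\n",
              d[1], d[2], d[3], object@dt, object@restPotential))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d oscillation spec(s), true duration %.0f ms, %d participating pixels\n",
              length(object@specs), object@trueDuration,
              sum(!is.na(object@perPixelOnset))))
})

setMethod("show", "OscillationRecord", function(object) {
  if (!object@detected) {
    cat("OscillationRecord: no oscillation detected\n")
    return(invisible(NULL))
  }
  cat(sprintf("OscillationRecord: ref pixel (%d, %d), %d member pixels, SNR %.1f\n",
              object@referencePixel[1], object@referencePixel[2],
              nrow(object@memberPixels), object@snr))
  cat(sprintf("  bounds %.0f-%.0f ms (duration %.0f ms), peak at +%.0f ms\n",
              object@startMs, object@endMs, object@durationMs,
              object@peakTimeMs))
})
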