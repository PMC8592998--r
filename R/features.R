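## Representative oscillation waveform and its features: 3-sigma bounds,
## cycle count, 10 ms-segment dominant-frequency track, PSD, peak time.

pixelIndex <- function(px, h) (px[, 2] - 1L) * h + px[, 1]

indexPixel <- function(idx, h)
  cbind(row = ((idx - 1L) %% h) + 1L, col = ((idx - 1L) %/% h) + 1L)

#' Select the reference pixel of a recording
#'
#' Returns the unmasked pixel whose waveform attains the largest
#' absolute percent dF/F0 anywhere in the recording (excluding an edge
#' guard at both ends, where zero-phase filter transients live). Ties
#' are broken in row-major order (scan rows left to right, top to
#' bottom).
#'
#' @param wf a [WaveformSet-class].
#' @param edge_guard_ms samples within this distance of the recording's
#'   edges are ignored (default 250 ms).
#' @return Integer \code{c(row, col)}, 1-based.
#' @export
selectReferencePixel <- function(wf, edge_guard_ms = 250) {
  validObject(wf)
  h <- wf@dims[1]
  un <- which(!as.vector(wf@mask))
  if (!length(un)) stop("no unmasked pixels")
  nt <- nrow(wf@values)
  guard <- min(round(edge_guard_ms * wf@frameRate / 1000), (nt - 1L) %/% 3L)
  mx <- cpp_col_absmax(wf@values, as.integer(un), guard, nt - guard)
  px <- indexPixel(un, h)
  rank_rm <- (px[, 1] - 1L) * wf@dims[2] + px[, 2]  # row-major tie-break
  best <- un[order(-mx, rank_rm)[1]]
  as.integer(indexPixel(best, h))
}

#' Build the representative oscillation waveform
#'
#' Orders the unmasked pixels by descending Pearson correlation with the
#' reference pixel's waveform and averages them greedily in that order.
#' The running SNR of the average (|peak| divided by its SD over the
#' baseline window) first improves as correlated pixels cancel noise,
#' then degrades once uncorrelated pixels join; averaging stops when the
#' running SNR drops below \code{stop_ratio} times the best SNR seen,
#' and the average at the best SNR is returned with its member set.
#'
#' @param wf a [WaveformSet-class].
#' @param reference optional \code{c(row, col)}; default
#'   [selectReferencePixel()].
#' @param stop_ratio stop once SNR < \code{stop_ratio} * best SNR;
#'   default 0.99.
#' @param baseline_ms baseline window used for the SNR denominator, ms.
#' @param smooth_ms the running peak is read off a short moving average
#'   of this length (default 10 ms) so single-sample noise does not
#'   jitter the stopping rule; the returned waveform is unsmoothed.
#' @param patience number of consecutive below-threshold additions
#'   required before stopping (default 5).
#' @return An [OscillationRecord-class] with the representative
#'   waveform, member pixels, reference pixel, SNR and baseline SD
#'   filled in; bounds are added by [detectBounds()].
#' @export
buildRepresentativeWaveform <- function(wf, reference = NULL,
                                        stop_ratio = 0.99,
                                        baseline_ms = 500,
                                        smooth_ms = 10, patience = 5) {
  validObject(wf)
  h <- wf@dims[1]
  if (is.null(reference)) reference <- selectReferencePixel(wf)
  ref_idx <- (reference[2] - 1L) * h + reference[1]
  if (wf@mask[reference[1], reference[2]]) stop("reference pixel is masked")
  ref_trace <- wf@values[, ref_idx]
  if (sd(ref_trace) == 0) stop("reference pixel has zero variance")

  un <- which(!as.vector(wf@mask))
  r_all <- suppressWarnings(as.vector(cor(wf@values, ref_trace)))
  r <- r_all[un]
  r[is.na(r)] <- -Inf            # zero-variance pixels sort last
  r[un == ref_idx] <- Inf        # reference always first
  ord <- un[order(-r)]

  nt <- nrow(wf@values)
  nbase <- max(2L, sum((seq_len(nt) - 1) * 1000 / wf@frameRate <
                         baseline_ms))
  guard <- min(round(250 * wf@frameRate / 1000), (nt - 1L) %/% 3L)
  res <- cpp_greedy_snr(wf@values, nbase, stop_ratio,
                        max(1L, round(smooth_ms * wf@frameRate / 1000)),
                        patience, as.integer(ord), guard, nt - guard)
  members <- indexPixel(ord[seq_len(res$n_members)], h)
  avg <- res$average
  # robust Gaussian-sigma over the whole trace (see preprocessMovie)
  bsd <- stats::mad(avg)
  new("OscillationRecord", representative = avg, memberPixels = members,
      referencePixel = as.integer(reference), frameRate = wf@frameRate,
      baselineSd = bsd, snr = res$snr, detected = FALSE,
      startMs = NA_real_, endMs = NA_real_, durationMs = NA_real_,
      peakTimeMs = NA_real_, nCycles = NA_real_)
}

#' Detect oscillation bounds at the 3-sigma level
#'
#' The oscillation starts at the first sample where the representative
#' waveform leaves the +/- \code{k_sigma} * sigma band of the Gaussian
#' baseline noise and ends at the last such sample; duration is end
#' minus start, and the peak time is the absolute maximum within the
#' bounds, relative to the start.
#'
#' On a long recording, chance excursions of the band-limited baseline
#' noise (probability about 0.0027 per sample at 3 sigma) would
#' otherwise set the bounds, so the first/last-crossing rule is applied
#' to sustained exceedances only — suprathreshold runs lasting at least
#' \code{sustain_ms}, the same sustain criterion the per-pixel
#' initiation times use. Qualifying runs separated by sub-threshold
#' gaps of at most \code{gap_ms} form one event, and the event
#' containing the largest excursion defines the bounds. No qualifying
#' run at all is a "no oscillation detected" outcome — the record comes
#' back with \code{isDetected(record) == FALSE}, not an error.
#'
#' @param record an [OscillationRecord-class].
#' @param baseline_sd sigma of the baseline noise, percent; defaults to
#'   the record's own estimate.
#' @param k_sigma detection threshold in sigmas (default 3).
#' @param sustain_ms minimum suprathreshold run length, ms (default 5).
#' @param gap_ms maximum sub-threshold gap inside one event, ms
#'   (default 100, half a cycle at the low edge of the analysis band).
#' @param edge_guard_ms samples within this distance of the recording's
#'   edges are ignored (default 250 ms; zero-phase filter transients).
#' @return The record with \code{startMs}, \code{endMs},
#'   \code{durationMs}, \code{peakTimeMs} and the \code{detected} flag
#'   filled in.
#' @export
detectBounds <- function(record, baseline_sd = NULL, k_sigma = 3,
                         sustain_ms = 5, gap_ms = 100,
                         edge_guard_ms = 250) {
  if (is.null(baseline_sd)) baseline_sd <- record@baselineSd
  stopifnot(baseline_sd > 0)
  x <- record@representative
  nt <- length(x)
  guard <- min(round(edge_guard_ms * record@frameRate / 1000),
               (nt - 1L) %/% 3L)
  if (guard > 0) x[c(seq_len(guard), (nt - guard + 1L):nt)] <- 0
  dtms <- 1000 / record@frameRate
  undetected <- function(record) {
    record@detected <- FALSE
    record@startMs <- record@endMs <- record@durationMs <-
      record@peakTimeMs <- NA_real_
    record
  }
  above <- abs(x) > k_sigma * baseline_sd
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  minrun <- max(1L, round(sustain_ms / dtms))
  qual <- which(r$values & r$lengths >= minrun)
  if (!length(qual)) return(undetected(record))
  rs <- starts[qual]; re <- ends[qual]
  gap <- max(1L, round(gap_ms / dtms))
  cluster <- cumsum(c(1L, (rs[-1] - re[-length(re)] - 1L) > gap))
  run_peak <- vapply(seq_along(qual),
                     function(i) max(abs(x[rs[i]:re[i]])), numeric(1))
  peak_cluster <- cluster[which.max(run_peak)]
  i0 <- min(rs[cluster == peak_cluster])
  i1 <- max(re[cluster == peak_cluster])
  record@detected <- TRUE
  record@startMs <- (i0 - 1) * dtms
  record@endMs <- (i1 - 1) * dtms
  record@durationMs <- record@endMs - record@startMs
  ipk <- i0 - 1L + which.max(abs(x[i0:i1]))
  record@peakTimeMs <- (ipk - i0) * dtms
  record@baselineSd <- baseline_sd
  validObject(record)
  record
}

#' Count complete oscillation cycles
#'
#' Number of complete cycles in the analysis window = (zero crossings of
#' the representative waveform within \code{[start, start + window_ms]}
#' intersected with the detected bounds) / 2, rounded down. Cycle
#' counting by zero-crossing pairs is robust to noise once detection is
#' 3-sigma bounded.
#'
#' @param record a detected [OscillationRecord-class].
#' @param window_ms analysis window from the start, ms (default 200, the
#'   conventional early-oscillation window); \code{NULL} = to the end.
#' @return Integer cycle count (0 for a single monophasic deflection).
#' @export
countCycles <- function(record, window_ms = 200) {
  if (!record@detected) stop("bounds not detected")
  dtms <- 1000 / record@frameRate
  i0 <- round(record@startMs / dtms) + 1L
  i_end <- round(record@endMs / dtms) + 1L
  if (!is.null(window_ms))
    i_end <- min(i_end, i0 + round(window_ms / dtms))
  x <- record@representative[i0:i_end]
  s <- sign(x)
  s <- s[s != 0]
  crossings <- sum(diff(s) != 0)
  as.integer(crossings %/% 2)
}

#' Time-resolved dominant frequency of the oscillation
#'
#' Splits the detected oscillation into consecutive non-overlapping
#' \code{segment_ms} segments, Hann-windows each, zero-pads to at least
#' 1024 samples and reports the periodogram's peak frequency within the
#' analysis band. A 10 ms rectangular window cannot natively resolve
#' 5-50 Hz; the zero-padded periodogram peak mimics the short-window
#' spectrogram estimate used for oscillation frequency tracking.
#' Segments shorter than \code{min_samples} are skipped, and an
#' undetected record yields an empty track.
#'
#' @param record an [OscillationRecord-class].
#' @param segment_ms segment length, ms (default 10).
#' @param band frequency search band, Hz (default c(5, 50)).
#' @param min_samples minimum samples per segment (default 5).
#' @param nfft_min minimum zero-padded FFT length (default 1024).
#' @param stride_ms spacing between segment starts, ms; the default
#'   (\code{segment_ms}) gives consecutive non-overlapping segments,
#'   smaller values give overlapping segments and a smoother track.
#' @return \code{data.frame(segment_time_ms, dominant_freq_hz)};
#'   segment times are the segment starts in recording time.
#' @export
frequencyTrack <- function(record, segment_ms = 10, band = c(5, 50),
                           min_samples = 5, nfft_min = 1024,
                           stride_ms = segment_ms) {
  empty <- data.frame(segment_time_ms = numeric(), dominant_freq_hz = numeric())
  if (!record@detected) return(empty)
  rate <- record@frameRate
  dtms <- 1000 / rate
  i0 <- round(record@startMs / dtms) + 1L
  i1 <- round(record@endMs / dtms) + 1L
  seg_n <- max(1L, round(segment_ms / dtms))
  starts <- seq(i0, i1, by = max(1L, round(stride_ms / dtms)))
  nfft <- max(nfft_min, seg_n)
  nfft <- 2^ceiling(log2(nfft))
  freqs <- (seq_len(nfft) - 1) * rate / nfft
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  out <- lapply(starts, function(s) {
    e <- min(s + seg_n - 1L, i1)
    x <- record@representative[s:e]
    if (length(x) < min_samples) return(NULL)
    win <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(x)))
    xp <- c(x * win, rep(0, nfft - length(x)))
    p <- Mod(fft(xp))^2
    data.frame(segment_time_ms = (s - 1) * dtms,
               dominant_freq_hz = freqs[in_band[which.max(p[in_band])]])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Power spectral density of the representative waveform
#'
#' The squared-magnitude FFT of the representative oscillation waveform
#' over its detected bounds (the whole trace when no bounds are set).
#' All \code{N} FFT bins are returned so that Parseval's identity,
#' \code{sum(power) / N == sum(values^2)}, holds exactly on the returned
#' table; bins above the Nyquist frequency mirror the lower half, so
#' plots conventionally show \code{freq_hz <= rate/2}.
#'
#' @param record an [OscillationRecord-class].
#' @return \code{data.frame(freq_hz, power)} with \code{power} in
#'   (percent dF/F0)^2.
#' @export
psdCurve <- function(record) {
  x <- record@representative
  if (record@detected) {
    dtms <- 1000 / record@frameRate
    i0 <- round(record@startMs / dtms) + 1L
    i1 <- round(record@endMs / dtms) + 1L
    x <- x[i0:i1]
  }
  n <- length(x)
  data.frame(freq_hz = (seq_len(n) - 1) * record@frameRate / n,
             power = Mod(fft(x))^2)
}

#' Dominant frequency of the whole oscillation
#'
#' The in-band argmax of the full-oscillation power spectral density
#' ([psdCurve()]). Unlike the 10 ms segment track — whose short window
#' cannot natively separate frequencies inside the 5-50 Hz band — the
#' whole-oscillation PSD resolves to about 1/duration Hz, so this is
#' the estimator of choice for an oscillation's overall frequency.
#'
#' @param record an [OscillationRecord-class].
#' @param band search band, Hz (default c(5, 50)).
#' @return Frequency, Hz.
#' @export
dominantFrequency <- function(record, band = c(5, 50)) {
  psd <- psdCurve(record)
  in_band <- psd$freq_hz >= band[1] & psd$freq_hz <= band[2]
  psd$freq_hz[in_band][which.max(psd$power[in_band])]
}

#' Peak time of the oscillation
#'
#' Time of the absolute maximum of the representative waveform within
#' the detected bounds, relative to the oscillation start.
#'
#' @param record a detected [OscillationRecord-class].
#' @return Peak time, ms.
#' @export
peakTime <- function(record) {
  if (!record@detected) stop("bounds not detected")
  record@peakTimeMs
}

#' One-row feature table of a detected oscillation
#'
#' @param record a detected [OscillationRecord-class].
#' @param early_ms early-oscillation window for the cycle count and mean
#'   frequency, ms (default 200).
#' @return \code{data.frame} with \code{duration_ms}, \code{n_cycles},
#'   \code{peak_time_ms}, \code{mean_freq_first200_ms} (Hz),
#'   \code{n_member_pixels}, \code{snr}.
#' @export
oscillationFeatures <- function(record, early_ms = 200) {
  if (!record@detected)
    return(data.frame(duration_ms = NA_real_, n_cycles = NA_integer_,
                      peak_time_ms = NA_real_,
                      mean_freq_first200_ms = NA_real_,
                      n_member_pixels = nrow(record@memberPixels),
                      snr = record@snr))
  trk <- frequencyTrack(record)
  early <- trk$segment_time_ms < record@startMs + early_ms
  data.frame(duration_ms = record@durationMs,
             n_cycles = countCycles(record, early_ms),
             peak_time_ms = record@peakTimeMs,
             mean_freq_first200_ms =
               if (any(early)) mean(trk$dominant_freq_hz[early]) else NA_real_,
             n_member_pixels = nrow(record@memberPixels),
             snr = record@snr)
}
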