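## Unsupervised k = 1 nearest-neighbour anomaly scoring: each 4x4 pixel
## group is represented by its mean waveform, trained on every 300 ms
## window of its own first 500 ms, and each later window is scored by
## the Euclidean distance to its nearest training window.

#' Tile a waveform set into pixel-group waveforms
#'
#' Segments the frame into \code{tile} x \code{tile} pixel groups (400
#' groups of 4 x 4 pixels for the native 80 x 80 frame) in row-major
#' order and represents each group by the arithmetic mean waveform of
#' its member pixels — all members, regardless of mask; group waveforms
#' receive no further filtering or averaging.
#'
#' @param wf a [WaveformSet-class].
#' @param tile group edge length, pixels (frame dimensions must be
#'   divisible by it).
#' @return List with \code{values} (T x nGroups matrix), \code{group_id}
#'   (0-based, row-major), \code{pixels} (list of member (row, col)
#'   matrices), \code{tile}.
#' @export
groupPixels <- function(wf, tile = 4) {
  validObject(wf)
  h <- wf@dims[1]; w <- wf@dims[2]
  if (h %% tile != 0 || w %% tile != 0)
    stop("frame dimensions must be divisible by the tile size")
  gh <- h %/% tile; gw <- w %/% tile
  ng <- gh * gw
  vals <- matrix(0, nrow(wf@values), ng)
  pixels <- vector("list", ng)
  for (gr in seq_len(gh)) {
    for (gc in seq_len(gw)) {
      gid <- (gr - 1L) * gw + (gc - 1L)          # row-major, 0-based
      rr <- ((gr - 1L) * tile + 1L):(gr * tile)
      cc <- ((gc - 1L) * tile + 1L):(gc * tile)
      idx <- as.vector(outer(rr, (cc - 1L) * h, "+"))
      vals[, gid + 1L] <- rowMeans(wf@values[, idx, drop = FALSE])
      pixels[[gid + 1L]] <- indexPixel(idx, h)
    }
  }
  list(values = vals, group_id = 0:(ng - 1L), pixels = pixels, tile = tile)
}

#' Training windows from the recording's own baseline
#'
#' Saturation sampling: every stride-1 window of \code{window_ms} that
#' fits inside the first \code{baseline_ms} of the trace. At 1 kHz with
#' the 500/300 ms defaults this yields 201 windows.
#'
#' @param values one group's waveform (numeric vector).
#' @param frame_rate Hz.
#' @param baseline_ms training region length, ms (default 500).
#' @param window_ms window length, ms (default 300).
#' @return Matrix with one training window per column.
#' @export
trainBaselineWindows <- function(values, frame_rate, baseline_ms = 500,
                                 window_ms = 300) {
  nb <- round(baseline_ms * frame_rate / 1000)
  win <- round(window_ms * frame_rate / 1000)
  if (nb < win) stop("baseline_ms must be >= window_ms")
  if (length(values) < nb) stop("recording shorter than the baseline")
  starts <- 0:(nb - win)
  vapply(starts, function(s) values[(s + 1):(s + win)], numeric(win))
}

#' k = 1 nearest-neighbour anomaly scores for one group waveform
#'
#' Scores sliding windows of the trace by their Euclidean distance to
#' the nearest window of the training region (the first
#' \code{baseline_ms}); larger scores are more anomalous. By default
#' every stride-1 window starting at or after \code{baseline_ms} is
#' scored; \code{starts_ms} overrides the scored window starts (scoring
#' the training region itself returns all-zero scores, every window
#' being its own twin).
#'
#' @param values one group's waveform (numeric vector).
#' @param frame_rate Hz.
#' @param baseline_ms training region, ms (default 500).
#' @param window_ms window length, ms (default 300).
#' @param stride scoring stride, samples (default 1, the saturation
#'   convention; widen for a cheaper score map).
#' @param starts_ms optional explicit window start times, ms.
#' @return \code{data.frame(window_start_ms, score)}.
#' @export
knnScore <- function(values, frame_rate, baseline_ms = 500, window_ms = 300,
                     stride = 1, starts_ms = NULL) {
  nb <- round(baseline_ms * frame_rate / 1000)
  win <- round(window_ms * frame_rate / 1000)
  if (nb < win) stop("baseline_ms must be >= window_ms")
  n <- length(values)
  if (n < nb) stop("recording shorter than the baseline")
  if (is.null(starts_ms)) {
    starts <- seq.int(nb, n - win, by = stride)        # 0-based
  } else {
    starts <- round(starts_ms * frame_rate / 1000)
    if (any(starts < 0) || any(starts + win > n))
      stop("scoring window out of range")
  }
  sc <- cpp_knn_scores(values, win, nb, as.integer(starts))
  data.frame(window_start_ms = starts * 1000 / frame_rate, score = sc)
}

#' Anomaly score tracks for every pixel group of a recording
#'
#' [groupPixels()] then [knnScore()] per group: each 4 x 4 group is
#' trained on its own first \code{baseline_ms} and scored over the rest
#' of the recording (independent training per group, no pooling).
#'
#' @param wf a [WaveformSet-class].
#' @param tile group edge length (default 4).
#' @param baseline_ms,window_ms,stride see [knnScore()].
#' @return Long \code{data.frame(group_id, window_start_ms, score)}.
#' @export
knnAnomaly <- function(wf, tile = 4, baseline_ms = 500, window_ms = 300,
                       stride = 1) {
  grp <- groupPixels(wf, tile)
  out <- lapply(seq_along(grp$group_id), function(i) {
    sc <- knnScore(grp$values[, i], wf@frameRate, baseline_ms, window_ms,
                   stride)
    cbind(group_id = grp$group_id[i], sc)
  })
  do.call(rbind, out)
}
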