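## Amplitude symmetry: correlate pixels to the reference, form
## equal-size correlation-ordered groups, pair the most inversely
## correlated groups, and compute the symmetry coefficient S.

#' Pearson correlation of every unmasked pixel with the reference
#'
#' Correlations are computed over the detected oscillation window when a
#' detected record is supplied (the default convention), or over the
#' whole recording otherwise. Zero-variance pixels have no defined
#' correlation; they come back \code{NA} with a message and are excluded
#' from grouping.
#'
#' @param wf a [WaveformSet-class].
#' @param record a detected [OscillationRecord-class] supplying the
#'   reference pixel and the window, or \code{NULL} with
#'   \code{reference} given explicitly.
#' @param reference optional \code{c(row, col)} reference pixel.
#' @param window optional \code{c(start_ms, end_ms)} correlation window.
#' @return H x W numeric matrix of correlations (\code{NA} on masked or
#'   zero-variance pixels); the reference pixel maps to 1.
#' @export
correlateToReference <- function(wf, record = NULL, reference = NULL,
                                 window = NULL) {
  validObject(wf)
  h <- wf@dims[1]
  if (is.null(reference)) {
    if (is.null(record)) stop("supply a record or a reference pixel")
    reference <- record@referencePixel
  }
  if (wf@mask[reference[1], reference[2]]) stop("reference pixel is masked")
  if (is.null(window) && !is.null(record) && isTRUE(record@detected))
    window <- c(record@startMs, record@endMs)
  dtms <- 1000 / wf@frameRate
  rows <- if (is.null(window)) seq_len(nrow(wf@values)) else
    (round(window[1] / dtms) + 1L):(round(window[2] / dtms) + 1L)
  ref_idx <- (reference[2] - 1L) * h + reference[1]
  ref_trace <- wf@values[rows, ref_idx]
  if (sd(ref_trace) == 0) stop("reference waveform has zero variance")
  un <- which(!as.vector(wf@mask))
  r <- suppressWarnings(as.vector(cor(wf@values[rows, un, drop = FALSE],
                                      ref_trace)))
  if (anyNA(r))
    message(sum(is.na(r)), " zero-variance pixel(s) excluded")
  out <- matrix(NA_real_, h, wf@dims[2])
  out[un] <- r
  out
}

#' Form correlation-ordered groups and pair them
#'
#' Unmasked pixels are sorted by their correlation with the reference
#' and cut into \code{n_groups} contiguous equal-size rank groups of
#' \code{min(floor(max_group_fraction * N), floor(N / n_groups))}
#' pixels; each group is represented by the mean waveform of its
#' members over \code{window}. The most positively ranked group is
#' paired with the most negatively ranked, the second-most with the
#' second-most, and so on until no equal-size groups remain — with an
#' odd group count the middle group is left unpaired and dropped. When
#' the size cap binds, each rank block keeps the members nearest its own
#' extreme (the top block its most positive pixels, the bottom block its
#' most negative).
#'
#' @param corr correlation matrix from [correlateToReference()].
#' @param wf the [WaveformSet-class] the correlations came from.
#' @param n_groups number of rank groups, conventionally 5-7 (default 5).
#' @param max_group_fraction group-size cap as a fraction of the
#'   unmasked pixel count (default 0.18).
#' @param window optional \code{c(start_ms, end_ms)}; group mean
#'   waveforms (and downstream norms) are taken over this window.
#' @param pairing \code{"rank"} (default) pairs by rank symmetry;
#'   \code{"waveform"} pairs equal-size groups greedily by the most
#'   negative correlation between their mean waveforms.
#' @return List with \code{pairs} (list of \code{list(a, b)} group
#'   indices), \code{groups} (list of pixel index matrices, most to
#'   least correlated), \code{waveforms} (group mean waveforms, one
#'   column per group), \code{group_size}.
#' @export
groupAndPair <- function(corr, wf, n_groups = 5, max_group_fraction = 0.18,
                         window = NULL, pairing = c("rank", "waveform")) {
  pairing <- match.arg(pairing)
  stopifnot(n_groups >= 2)
  h <- wf@dims[1]
  ok <- which(!is.na(corr))
  if (length(ok) < 2 * n_groups) stop("fewer usable pixels than groups")
  g <- min(floor(max_group_fraction * length(ok)),
           floor(length(ok) / n_groups))
  if (g < 1) stop("group size would be zero")
  ord <- ok[order(corr[ok], decreasing = TRUE)]
  block <- floor(length(ok) / n_groups)
  dtms <- 1000 / wf@frameRate
  rows <- if (is.null(window)) seq_len(nrow(wf@values)) else
    (round(window[1] / dtms) + 1L):(round(window[2] / dtms) + 1L)

  groups <- vector("list", n_groups)
  waves <- matrix(0, length(rows), n_groups)
  for (k in seq_len(n_groups)) {
    blk <- ord[((k - 1L) * block + 1L):(k * block)]
    sel <- if (k <= n_groups / 2) head(blk, g)
           else if (k > n_groups / 2 + 1 || n_groups %% 2 == 0) tail(blk, g)
           else blk[seq_len(g) + (block - g) %/% 2]   # middle block: centre
    groups[[k]] <- sel
    waves[, k] <- rowMeans(wf@values[rows, sel, drop = FALSE])
  }

  if (pairing == "rank") {
    n_pairs <- n_groups %/% 2
    pairs <- lapply(seq_len(n_pairs),
                    function(i) list(a = i, b = n_groups - i + 1L))
  } else {
    remaining <- seq_len(n_groups)
    if (n_groups %% 2 == 1) {     # drop the least-pairable middle group
      remaining <- remaining[-((n_groups + 1L) %/% 2L)]
    }
    pairs <- list()
    while (length(remaining) >= 2) {
      cm <- cor(waves[, remaining, drop = FALSE])
      diag(cm) <- Inf
      ij <- which(cm == min(cm), arr.ind = TRUE)[1, ]
      pairs[[length(pairs) + 1L]] <- list(a = remaining[ij[1]],
                                          b = remaining[ij[2]])
      remaining <- remaining[-ij]
    }
  }
  list(pairs = pairs, groups = lapply(groups, indexPixel, h = h),
       group_index = groups, waveforms = waves, group_size = g)
}

#' Amplitude symmetry coefficient of two waveforms
#'
#' \code{S = ||(A - B)/2|| / (||(A - B)/2|| + ||(A + B)/2||)} with
#' Euclidean norms: 1 indicates perfect symmetry (B is the mirror image
#' of A), 0 indicates identical waveforms (no amplitude symmetry over
#' time).
#'
#' @param wave_a,wave_b equal-length numeric waveforms, not both
#'   identically zero.
#' @return S in \[0, 1\].
#' @examples
#' a <- sin(seq(0, 4 * pi, length.out = 1000))
#' symmetryCoefficient(a, -a)   # 1
#' symmetryCoefficient(a, a)    # 0
#' @export
symmetryCoefficient <- function(wave_a, wave_b) {
  stopifnot(length(wave_a) == length(wave_b))
  sym <- sqrt(sum(((wave_a - wave_b) / 2)^2))
  asym <- sqrt(sum(((wave_a + wave_b) / 2)^2))
  if (sym + asym == 0)
    stop("symmetry coefficient undefined for two identically zero waveforms")
  sym / (sym + asym)
}

#' Amplitude symmetry analysis of a recording
#'
#' Runs the full procedure: correlations to the reference over the
#' oscillation window, rank grouping and pairing, and the symmetry
#' coefficient of each pair's mean waveforms.
#'
#' @param wf a [WaveformSet-class].
#' @param record a detected [OscillationRecord-class].
#' @param n_groups,max_group_fraction,pairing see [groupAndPair()].
#' @return \code{data.frame(pair, group_a, group_b, group_size, S)} with
#'   the grouping attached as attribute \code{"grouping"}.
#' @export
amplitudeSymmetry <- function(wf, record, n_groups = 5,
                              max_group_fraction = 0.18,
                              pairing = c("rank", "waveform")) {
  if (!isTRUE(record@detected)) stop("record has no detected oscillation")
  window <- c(record@startMs, record@endMs)
  corr <- correlateToReference(wf, record)
  gp <- groupAndPair(corr, wf, n_groups, max_group_fraction, window,
                     pairing)
  res <- do.call(rbind, lapply(seq_along(gp$pairs), function(i) {
    pr <- gp$pairs[[i]]
    data.frame(pair = i, group_a = pr$a, group_b = pr$b,
               group_size = gp$group_size,
               S = symmetryCoefficient(gp$waveforms[, pr$a],
                                       gp$waveforms[, pr$b]))
  }))
  attr(res, "grouping") <- gp
  res
}
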