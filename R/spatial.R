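## Spatial origin analysis: per-pixel initiation times, the graded
## latency time-bin scheme, Hopkins cluster-tendency statistics per bin,
## and cross-oscillation substrate comparison.

#' Per-pixel oscillation initiation times
#'
#' A pixel initiates at the earliest time its waveform stays beyond
#' \code{k_sigma} times its own Gaussian baseline noise SD for at least
#' \code{sustain_ms} continuously; pixels that never satisfy the
#' criterion (and masked pixels) are absent (\code{NA}).
#'
#' In the default \code{"event"} mode the sustained-crossing rule is
#' anchored to each pixel's own oscillation: qualifying runs closer
#' than \code{gap_ms} are chained into events, and the pixel's
#' initiation is the start of the event that carries its largest
#' excursion. This keeps chance sustained excursions of the
#' band-limited baseline noise (which occur at a rate of order one per
#' second per pixel at 3 sigma) from masquerading as initiations
#' hundreds of milliseconds before the oscillation. \code{"first"} mode
#' applies the literal earliest-sustained-crossing rule, appropriate
#' for short, windowed searches.
#'
#' @param wf a [WaveformSet-class].
#' @param sustain_ms sustain criterion, ms, between 5 and 10 (default 5).
#' @param k_sigma threshold in baseline SDs (default 3).
#' @param mode \code{"event"} (default) or \code{"first"}, see Details.
#' @param gap_ms run-chaining gap for event mode, ms (default 60, about
#'   half a cycle at the low end of the oscillation band).
#' @param search_start_ms ignore samples before this time, ms.
#' @param edge_guard_ms samples within this distance of the recording's
#'   edges are never searched (default 250 ms): the zero-phase filter's
#'   warm-up transients on per-pixel noise can reach several sigma
#'   there and would masquerade as events.
#' @return H x W numeric matrix of initiation times (ms), with the
#'   sustain criterion attached as attribute \code{"sustain_ms"}.
#' @export
initiationTimes <- function(wf, sustain_ms = 5, k_sigma = 3,
                            mode = c("event", "first"), gap_ms = 60,
                            search_start_ms = 0, edge_guard_ms = 250) {
  validObject(wf)
  mode <- match.arg(mode)
  stopifnot(sustain_ms >= 5, sustain_ms <= 10)
  rate <- wf@frameRate
  nt <- nrow(wf@values)
  m <- max(1L, round(sustain_ms * rate / 1000))
  thr <- k_sigma * wf@baselineSd
  guard <- round(edge_guard_ms * rate / 1000)
  from <- max(round(search_start_ms * rate / 1000), guard)
  to <- max(from + 1L, nt - guard)
  first <- if (mode == "event") {
    cpp_event_init(wf@values, thr, m, max(1L, round(gap_ms * rate / 1000)),
                   from, to)
  } else {
    rows <- (from + 1L):to
    f <- cpp_first_sustained(wf@values[rows, , drop = FALSE], thr, m)
    ifelse(f > 0, f + from, 0L)
  }
  t_init <- ifelse(first > 0, (first - 1) * 1000 / rate, NA_real_)
  out <- matrix(t_init, wf@dims[1], wf@dims[2])
  out[wf@mask] <- NA_real_
  attr(out, "sustain_ms") <- sustain_ms
  out
}

## The time-bin scheme for initiation latencies (ms after oscillation
## start): 1 ms bins over 1-10, 5 ms over 11-40, 10 ms over 41-80,
## 20 ms over 81-200 -- 26 bins.
initiationBinEdges <- function() {
  lo <- c(0:9, seq(10, 35, 5), seq(40, 70, 10), seq(80, 180, 20))
  hi <- c(1:10, seq(15, 40, 5), seq(50, 80, 10), seq(100, 200, 20))
  data.frame(t_lo = lo, t_hi = hi)
}

#' Bin initiation latencies into the standard time-bin scheme
#'
#' Latencies \code{t_init - t0} fall into 1 ms bins for 1-10 ms, 5 ms
#' bins for 11-40 ms, 10 ms bins for 41-80 ms and 20 ms bins for
#' 81-200 ms (26 bins); a bin covers \code{(t_lo, t_hi]} (the first bin
#' includes 0). Pixels initiating later than 200 ms after \code{t0} are
#' excluded.
#'
#' @param map initiation-time matrix from [initiationTimes()].
#' @param t0 oscillation start, ms (typically the representative
#'   waveform's \code{startMs}).
#' @return List with \code{edges} (\code{data.frame(t_lo, t_hi, n)}) and
#'   \code{pixels} (per-bin integer matrices of (row, col)).
#' @export
binInitiations <- function(map, t0) {
  h <- nrow(map)
  idx <- which(!is.na(map))
  if (!length(idx)) stop("initiation map is empty")
  delta <- map[idx] - t0
  edges <- initiationBinEdges()
  pixels <- vector("list", nrow(edges))
  n <- integer(nrow(edges))
  for (b in seq_len(nrow(edges))) {
    inb <- if (b == 1L) delta >= 0 & delta <= edges$t_hi[b]
           else delta > edges$t_lo[b] & delta <= edges$t_hi[b]
    pixels[[b]] <- indexPixel(idx[inb], h)
    n[b] <- sum(inb)
  }
  list(edges = cbind(edges, n = n), pixels = pixels)
}

#' Hopkins cluster-tendency statistic on pixel sets
#'
#' For a set of \code{n} points (initiating pixels), draws \code{n}
#' comparison pixels without replacement from the remaining pool,
#' computes \code{u} = the summed distances from each comparison pixel
#' to its nearest point, \code{w} = the summed within-set
#' nearest-neighbour distances of the points, and \code{H = u / (u +
#' w)}, averaged over \code{repeats} seeded draws. Oriented in the
#' standard cluster-tendency sense: H near 0.5 means the points are
#' indistinguishable from a random draw of the pool (no clustering), H
#' toward 1 means clustered points, and H toward 0 means
#' regularly/uniformly spaced points.
#'
#' @param points integer n x 2 matrix of (row, col) pixel coordinates,
#'   n >= 2.
#' @param pool integer m x 2 matrix of the remaining candidate pixels
#'   (excluding \code{points}), m >= n.
#' @param repeats number of seeded comparison draws averaged (default
#'   20).
#' @param seed integer.
#' @return Mean H over the repeats.
#' @examples
#' pts <- cbind(row = sample(1:20, 30, TRUE), col = sample(1:20, 30, TRUE))
#' pool <- as.matrix(expand.grid(row = 1:20, col = 1:20))
#' hopkinsStat(pts, pool, repeats = 5, seed = 1)
#' @export
hopkinsStat <- function(points, pool, repeats = 20, seed = 1) {
  points <- as.matrix(points); pool <- as.matrix(pool)
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points")
  if (nrow(pool) < n) stop("pool smaller than the points set")
  # within-set nearest-neighbour distances of the points (constant
  # across repeats)
  d2w <- outer(points[, 1], points[, 1], "-")^2 +
         outer(points[, 2], points[, 2], "-")^2
  diag(d2w) <- Inf
  w <- sum(sqrt(apply(d2w, 1, min)))
  hs <- withr::with_seed(seed, vapply(seq_len(repeats), function(i) {
    cmp <- pool[sample.int(nrow(pool), n), , drop = FALSE]
    d2u <- outer(cmp[, 1], points[, 1], "-")^2 +
           outer(cmp[, 2], points[, 2], "-")^2
    u <- sum(sqrt(apply(d2u, 1, min)))
    u / (u + w)
  }, numeric(1)))
  mean(hs)
}

#' Hopkins profile of oscillation initiation over time bins
#'
#' [binInitiations()] then [hopkinsStat()] per bin: each time bin's
#' initiating pixels are tested for spatial clustering against
#' comparison pixels drawn from the remaining unmasked pixels. Bins with
#' fewer than 2 pixels are recorded with \code{h_mean = NA}.
#'
#' @param map initiation-time matrix from [initiationTimes()].
#' @param mask logical H x W out-of-slice mask.
#' @param t0 oscillation start, ms; default = the earliest initiation,
#'   taken robustly as the 1st percentile of the map so that a single
#'   spurious early pixel cannot shift every latency bin.
#' @param repeats Hopkins repeats per bin (default 20).
#' @param seed integer.
#' @return \code{data.frame(bin, t_lo, t_hi, n, h_mean)}.
#' @export
originProfile <- function(map, mask, t0 = NULL, repeats = 20, seed = 1) {
  if (is.null(t0)) t0 <- quantile(map, 0.01, na.rm = TRUE, names = FALSE)
  bins <- binInitiations(map, t0)
  h <- nrow(map)
  un <- which(!as.vector(mask))
  out <- bins$edges
  out$bin <- seq_len(nrow(out))
  out$h_mean <- NA_real_
  for (b in seq_len(nrow(out))) {
    pts <- bins$pixels[[b]]
    if (nrow(pts) < 2) next
    pool_idx <- setdiff(un, pixelIndex(pts, h))
    if (length(pool_idx) < nrow(pts)) next
    out$h_mean[b] <- hopkinsStat(pts, indexPixel(pool_idx, h),
                                 repeats = repeats, seed = seed + b)
  }
  out[, c("bin", "t_lo", "t_hi", "n", "h_mean")]
}

#' Compare the pixel substrates of oscillations within one recording
#'
#' For each oscillation window, unmasked pixels are ranked by their
#' correlation with that window's reference pixel and split into
#' \code{n_groups} equal-rank groups; for every pair of oscillations the
#' overlap is the Jaccard index of their top-group pixel sets, and the
#' pair is called shared when the overlap reaches
#' \code{share_threshold}. The grouping is also computed over all
#' oscillation windows jointly.
#'
#' @param wf a [WaveformSet-class].
#' @param windows list of >= 2 non-overlapping \code{c(start_ms,
#'   end_ms)} oscillation windows.
#' @param references optional list of \code{c(row, col)} reference
#'   pixels per window; default = each window's maximal-|dF/F| unmasked
#'   pixel.
#' @param n_groups correlation-rank groups per oscillation (default 4).
#' @param share_threshold Jaccard threshold for calling a pair shared
#'   (default 0.5).
#' @return List with \code{pairs}
#'   (\code{data.frame(osc_a, osc_b, overlap, shared)}),
#'   \code{top_groups} (per-oscillation (row, col) matrices),
#'   \code{all_top_group} (top group of the joint grouping).
#' @export
substrateComparison <- function(wf, windows, references = NULL,
                                n_groups = 4, share_threshold = 0.5) {
  validObject(wf)
  if (length(windows) < 2)
    return(list(pairs = data.frame(osc_a = integer(), osc_b = integer(),
                                   overlap = numeric(), shared = logical()),
                top_groups = list(), all_top_group = NULL))
  ws <- do.call(rbind, windows)
  ord <- order(ws[, 1])
  if (any(ws[ord, 1][-1] < ws[ord, 2][-length(windows)]))
    stop("oscillation windows overlap in time")
  h <- wf@dims[1]
  dtms <- 1000 / wf@frameRate
  un <- which(!as.vector(wf@mask))

  topGroup <- function(rows, reference) {
    if (is.null(reference)) {
      mx <- cpp_col_absmax(wf@values[rows, un, drop = FALSE])
      reference <- as.integer(indexPixel(un[which.max(mx)], h))
    }
    ref_trace <- wf@values[rows, (reference[2] - 1L) * h + reference[1]]
    r <- suppressWarnings(as.vector(cor(wf@values[rows, un, drop = FALSE],
                                        ref_trace)))
    ok <- un[!is.na(r)]
    ord_px <- ok[order(r[!is.na(r)], decreasing = TRUE)]
    g <- floor(length(ord_px) / n_groups)
    ord_px[seq_len(g)]
  }

  rows_of <- function(wnd)
    (round(wnd[1] / dtms) + 1L):(round(wnd[2] / dtms) + 1L)

  tops <- lapply(seq_along(windows), function(i)
    topGroup(rows_of(windows[[i]]),
             if (is.null(references)) NULL else references[[i]]))

  pairs <- do.call(rbind, apply(utils::combn(length(windows), 2), 2,
                                function(ij) {
    a <- tops[[ij[1]]]; b <- tops[[ij[2]]]
    ov <- length(intersect(a, b)) / length(union(a, b))
    data.frame(osc_a = ij[1], osc_b = ij[2], overlap = ov,
               shared = ov >= share_threshold)
  }, simplify = FALSE))

  all_rows <- sort(unique(unlist(lapply(windows, rows_of))))
  all_top <- topGroup(all_rows, NULL)

  list(pairs = pairs,
       top_groups = lapply(tops, indexPixel, h = h),
       all_top_group = indexPixel(all_top, h))
}
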