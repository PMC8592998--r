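## Raw movies -> per-pixel %dF/F0 oscillation waveforms: dark-pixel
## masking, zero-phase Butterworth bandpass, exponential photobleaching
## baseline normalisation.

#' Analytic magnitude response of the analysis bandpass
#'
#' Single-pass magnitude of the cascaded digital Butterworth high-pass
#' (at \code{low}) and low-pass (at \code{high}), both of order
#' \code{order}, designed by the bilinear transform (as
#' \code{signal::butter} does): with \code{W(f) = tan(pi f / rate)},
#' \code{|H(f)| = (1 + (W(low)/W(f))^(2 order))^(-1/2) * (1 +
#' (W(f)/W(high))^(2 order))^(-1/2)}. The pipeline applies the cascade
#' forward and backward (zero phase), so the effective amplitude gain is
#' this value squared.
#'
#' @param f frequency, Hz (vector).
#' @param low,high band edges, Hz.
#' @param order filter order.
#' @param rate sampling rate, Hz.
#' @return Single-pass |H(f)|; square it for the zero-phase gain.
#' @seealso [bandpass()]
#' @export
butterCascadeGain <- function(f, low = 5, high = 50, order = 5,
                              rate = 1000) {
  wf <- tan(pi * f / rate)
  wl <- tan(pi * low / rate)
  wh <- tan(pi * high / rate)
  hp <- ifelse(f <= 0, 0, 1 / sqrt(1 + (wl / wf)^(2 * order)))
  lp <- 1 / sqrt(1 + (wf / wh)^(2 * order))
  hp * lp
}

#' Zero-phase Butterworth bandpass
#'
#' Applies a 5th-order Butterworth high-pass at \code{low} Hz and
#' low-pass at \code{high} Hz (designed with [signal::butter()]) forward
#' and backward, so the output is zero-phase and the effective magnitude
#' response is the squared single-pass response. The input is
#' reflect-padded (odd reflection about the end points) by one warm-up
#' length before filtering, and the output has the same length as the
#' input with DC removed.
#'
#' @param trace numeric vector, or a matrix filtered column-wise.
#' @param low_hz,high_hz band edges, Hz.
#' @param order filter order (per filter in the cascade).
#' @param frame_rate sampling rate, Hz.
#' @return Filtered trace, same shape as the input.
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' x <- sin(2 * pi * 20 * t) + sin(2 * pi * 1 * t)
#' y <- bandpass(x, frame_rate = 1000)   # keeps 20 Hz, rejects 1 Hz
#' @export
bandpass <- function(trace, low_hz = 5, high_hz = 50, order = 5,
                     frame_rate = 1000) {
  stopifnot(low_hz > 0, low_hz < high_hz, high_hz < frame_rate / 2)
  vec <- is.null(dim(trace))
  x <- if (vec) matrix(trace, ncol = 1) else trace
  warmup <- 3 * (2 * order + 1)
  if (nrow(x) <= warmup)
    stop("trace shorter than the filter warm-up length (",
         warmup + 1, " samples)")
  hp <- signal::butter(order, low_hz / (frame_rate / 2), type = "high")
  lp <- signal::butter(order, high_hz / (frame_rate / 2), type = "low")
  npad <- min(nrow(x) - 1L, 3L * ceiling(frame_rate / low_hz))
  # demean first: the high-pass removes DC analytically, but its poles
  # sit close to z = 1 and amplify the numerical residue of a large
  # offset
  x <- sweep(x, 2L, colMeans(x))
  y <- cpp_filtfilt_mat(hp$b, hp$a, x, npad)
  y <- cpp_filtfilt_mat(lp$b, lp$a, y, npad)
  if (vec) drop(y) else y
}

#' Mask dark out-of-slice pixels
#'
#' A pixel is masked iff its temporal-mean count falls below
#' \code{dark_fraction} times the 99th percentile of all pixels'
#' temporal means. Referencing the threshold to a high percentile makes
#' the rule invariant to exposure scaling.
#'
#' @param movie a [Movie-class].
#' @param dark_fraction threshold fraction in (0, 1); default 0.10.
#' @return A [PixelMask-class].
#' @export
maskDarkPixels <- function(movie, dark_fraction = 0.10) {
  stopifnot(dark_fraction > 0, dark_fraction < 1)
  d <- dim(movie@counts)
  cnt <- movie@counts
  dim(cnt) <- c(d[1], d[2] * d[3])
  mu <- colMeans(cnt)
  thr <- dark_fraction * quantile(mu, 0.99, names = FALSE)
  masked <- matrix(mu < thr, d[2], d[3])
  if (all(masked)) stop("all pixels masked; dark_fraction too high")
  new("PixelMask", masked = masked, nMasked = sum(masked))
}

## Variable-projection fit of F0(t) = a exp(-t/tau) + c: for a given tau
## the (a, c) are linear; tau is found by 1-d minimisation of the
## profiled RSS over log(tau). Returns the fit evaluated on t_eval.
fitExpBaseline <- function(raw, t_ms, fit_idx = NULL, max_points = 400) {
  if (is.null(fit_idx)) fit_idx <- seq_along(raw)
  if (length(fit_idx) > max_points)
    fit_idx <- fit_idx[seq(1L, length(fit_idx),
                           length.out = max_points)]
  y <- raw[fit_idx]; tt <- t_ms[fit_idx]
  n <- length(y)
  if (n < 3) stop("too few samples to fit a baseline")
  my <- mean(y)
  if (sd(y) <= 1e-12 * max(abs(my), 1))
    return(list(a = 0, tau = Inf, c = my, rss = 0, constant = TRUE))

  rss_at <- function(log_tau) {
    e <- exp(-tt / exp(log_tau))
    me <- mean(e)
    vxy <- sum((e - me) * (y - my))
    vxx <- sum((e - me)^2)
    if (vxx <= 0) return(sum((y - my)^2))
    a <- vxy / vxx
    sum((y - my - a * (e - me))^2)
  }
  span <- max(tt) - min(tt)
  opt <- optimize(rss_at, interval = log(c(span / 200, span * 200)),
                  tol = 1e-4)
  tau <- exp(opt$minimum)
  e <- exp(-tt / tau)
  fit <- lm(y ~ e)
  a <- unname(coef(fit)[2]); c0 <- unname(coef(fit)[1])
  if (!is.finite(a) || !is.finite(c0))
    stop("baseline fit failed (degenerate pixel)")
  list(a = a, tau = tau, c = c0, rss = opt$objective, constant = FALSE)
}

evalExpBaseline <- function(fit, t_ms) {
  if (fit$constant || !is.finite(fit$tau)) rep(fit$c + fit$a, length(t_ms))
  else fit$a * exp(-t_ms / fit$tau) + fit$c
}

#' Fit the photobleaching baseline and normalise one pixel
#'
#' Fits an exponential decay \code{F0(t) = a exp(-t/tau) + c} to the raw
#' count trace (restricted to oscillation-free windows when provided,
#' otherwise the whole trace — safe because the oscillation is zero-mean
#' after the bandpass) and converts the filtered trace to fractional
#' fluorescence change, \code{values = filtered / F0 * 100}. The
#' Gaussian baseline noise SD is estimated robustly (scaled median
#' absolute deviation) from \code{values} over the first
#' \code{baseline_ms} (or over the quiet windows).
#'
#' @param raw_trace raw counts, one pixel.
#' @param filtered_trace the same pixel after [bandpass()].
#' @param frame_rate Hz.
#' @param quiet_windows optional list of \code{c(start_ms, end_ms)}
#'   oscillation-free ranges used for the fit and the SD estimate.
#' @param baseline_ms baseline window for the SD estimate, ms.
#' @param pixel optional (row, col) carried through.
#' @return List with \code{values} (percent dF/F0), \code{pixel},
#'   \code{baseline_sd} (percent), \code{f0} (the fitted curve) and
#'   \code{fit} (list \code{a}, \code{tau}, \code{c}).
#' @examples
#' t <- 0:1999
#' raw <- 1000 * exp(-t / 5000) + rnorm(2000, sd = 1)
#' filt <- bandpass(raw, frame_rate = 1000)
#' pw <- fitBaselineAndNormalize(raw, filt, 1000)
#' pw$baseline_sd
#' @export
fitBaselineAndNormalize <- function(raw_trace, filtered_trace, frame_rate,
                                    quiet_windows = NULL, baseline_ms = 500,
                                    pixel = c(NA_integer_, NA_integer_)) {
  stopifnot(length(raw_trace) == length(filtered_trace))
  n <- length(raw_trace)
  t_ms <- (seq_len(n) - 1) * 1000 / frame_rate
  fit_idx <- NULL
  if (!is.null(quiet_windows)) {
    keep <- rep(FALSE, n)
    for (wnd in quiet_windows) keep <- keep | (t_ms >= wnd[1] & t_ms <= wnd[2])
    if (!any(keep)) stop("quiet_windows select no samples")
    fit_idx <- which(keep)
  }
  fit <- fitExpBaseline(raw_trace, t_ms, fit_idx)
  f0 <- evalExpBaseline(fit, t_ms)
  if (any(f0 <= 0)) stop("fitted baseline is non-positive")
  values <- filtered_trace / f0 * 100
  sd_idx <- if (is.null(fit_idx)) which(t_ms < baseline_ms) else fit_idx
  list(values = values, pixel = pixel,
       baseline_sd = stats::mad(values[sd_idx]), f0 = f0, fit = fit)
}

#' Preprocess a movie into per-pixel oscillation waveforms
#'
#' The full preprocessing stage: masks dark out-of-slice pixels, applies
#' the zero-phase 5-50 Hz Butterworth bandpass to every pixel, fits each
#' pixel's exponential photobleaching baseline and normalises to percent
#' dF/F0. All pixels (masked included) get a waveform — the k-NN stage
#' averages raw 4x4 groups regardless of mask — but masked pixels are
#' excluded from every downstream pixel selection. Pixels whose
#' exponential fit degenerates (or whose fitted baseline is not strictly
#' positive, typical for dark pixels near zero counts) fall back to a
#' constant baseline at their mean count.
#'
#' @details The exponential baseline is removed before the filter is
#' applied (the filtered signal is then divided by the fitted curve):
#' filtering is linear, so this equals the filter-then-divide order in
#' the passband, but it avoids the filter's start-up transient on the
#' bleaching trend — a deterministic edge residual that every pixel
#' would otherwise share and that no amount of pixel averaging could
#' remove.
#'
#' @param movie a [Movie-class].
#' @param low_hz,high_hz,order bandpass parameters (default 5-50 Hz,
#'   order 5).
#' @param dark_fraction masking threshold, see [maskDarkPixels()].
#' @param baseline_ms baseline window for noise-SD estimates, ms.
#' @param quiet_windows optional oscillation-free ranges for the
#'   baseline fits, list of \code{c(start_ms, end_ms)}.
#' @return A [WaveformSet-class].
#' @export
preprocessMovie <- function(movie, low_hz = 5, high_hz = 50, order = 5,
                            dark_fraction = 0.10, baseline_ms = 500,
                            quiet_windows = NULL) {
  validObject(movie)
  stopifnot(dark_fraction > 0, dark_fraction < 1)
  d <- dim(movie@counts)
  np <- d[2] * d[3]
  cnt <- movie@counts
  dim(cnt) <- c(d[1], np)
  # masking rule as in maskDarkPixels, on the same temporal means
  mu <- colMeans(cnt)
  masked <- matrix(mu < dark_fraction * quantile(mu, 0.99, names = FALSE),
                   d[2], d[3])
  if (all(masked)) stop("all pixels masked; dark_fraction too high")

  t_ms <- (seq_len(d[1]) - 1) * 1000 / movie@frameRate
  fit_idx <- NULL
  if (!is.null(quiet_windows)) {
    keep <- rep(FALSE, d[1])
    for (wnd in quiet_windows) keep <- keep | (t_ms >= wnd[1] & t_ms <= wnd[2])
    fit_idx <- which(keep)
  }
  base_idx <- if (is.null(fit_idx)) which(t_ms < baseline_ms) else fit_idx

  av <- numeric(np); tauv <- numeric(np); cv <- numeric(np)
  t_end <- t_ms[d[1]]
  for (p in seq_len(np)) {
    ft <- tryCatch(fitExpBaseline(cnt[, p], t_ms, fit_idx),
                   error = function(e) NULL)
    if (!is.null(ft)) {
      # f0 is monotone in t, so endpoint positivity implies positivity
      ends <- evalExpBaseline(ft, c(0, t_end))
      if (any(!is.finite(ends)) || any(ends <= 0)) ft <- NULL
    }
    if (is.null(ft)) ft <- list(a = 0, tau = Inf,
                                c = max(mean(cnt[, p]), 1e-6),
                                constant = TRUE)
    av[p] <- ft$a; tauv[p] <- ft$tau; cv[p] <- ft$c
  }
  dtms <- 1000 / movie@frameRate
  cpp_apply_baseline_ip(cnt, av, tauv, cv, dtms, TRUE)     # remove F0
  hp <- signal::butter(order, low_hz / (movie@frameRate / 2), type = "high")
  lp <- signal::butter(order, high_hz / (movie@frameRate / 2), type = "low")
  npad <- min(d[1] - 1L, 3L * ceiling(movie@frameRate / low_hz))
  cpp_filtfilt_ip(hp$b, hp$a, cnt, npad)
  cpp_filtfilt_ip(lp$b, lp$a, cnt, npad)
  cpp_apply_baseline_ip(cnt, av, tauv, cv, dtms, FALSE)    # divide, percent
  # Robust Gaussian-sigma estimate (MAD) over the whole recording: the
  # oscillation occupies a minority of samples and barely moves the
  # median absolute deviation, while the long window supplies enough
  # independent draws of the band-limited noise for a stable per-pixel
  # sigma (a 500 ms window holds only ~25 of them), and the filter's
  # edge transients cannot bias it.
  bsd <- apply(cnt, 2, stats::mad)
  new("WaveformSet", values = cnt, dims = c(d[2], d[3]),
      frameRate = movie@frameRate, mask = masked, baselineSd = bsd)
}

#' Quick on-the-spot look at a recording
#'
#' The during-session convenience view: spatially averages the counts
#' over a region of interest, bandpasses the average, and converts to
#' fractional change against user-chosen reference frames,
#' \code{dF/F_ref = filtered / mean(F[reference_frames]) * 100}. The
#' reference frame index is a required argument (choose frames before
#' the activity of interest).
#'
#' @param movie a [Movie-class].
#' @param reference_frames integer frame indices whose mean ROI count is
#'   the reference F.
#' @param roi optional logical H x W matrix (default: whole frame).
#' @param low_hz,high_hz,order bandpass parameters.
#' @return \code{data.frame(time_ms, dff)} (percent dF/F_ref).
#' @export
quickLook <- function(movie, reference_frames, roi = NULL,
                      low_hz = 5, high_hz = 50, order = 5) {
  validObject(movie)
  d <- dim(movie@counts)
  cnt <- movie@counts
  dim(cnt) <- c(d[1], d[2] * d[3])
  sel <- if (is.null(roi)) seq_len(ncol(cnt)) else which(as.vector(roi))
  if (!length(sel)) stop("empty ROI")
  avg <- rowMeans(cnt[, sel, drop = FALSE])
  f_ref <- mean(avg[reference_frames])
  if (!is.finite(f_ref) || f_ref <= 0) stop("invalid reference frames")
  filt <- bandpass(avg, low_hz, high_hz, order, movie@frameRate)
  data.frame(time_ms = (seq_len(d[1]) - 1) * 1000 / movie@frameRate,
             dff = filt / f_ref * 100)
}
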