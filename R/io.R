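## Readers/writers: 16-bit multi-frame grayscale TIFF movies, mask
## images, pseudocolor renderings of oscillation segments.

#' Write a movie as multi-frame 16-bit grayscale TIFF
#'
#' Counts are rounded and clipped to the 16-bit range; the frame rate is
#' stored in a plain-text sidecar (\code{<path>.meta.txt}) so
#' [readMovie()] round-trips it.
#'
#' @param movie a [Movie-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMovie <- function(movie, path) {
  validObject(movie)
  d <- dim(movie@counts)
  if (max(movie@counts) > 65535)
    warning("counts exceed 16-bit range; clipping")
  frames <- lapply(seq_len(d[1]), function(i) {
    pmin(pmax(round(movie@counts[i, , ]), 0), 65535) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L,
                  compression = "none")
  writeLines(sprintf("frame_rate_hz=%g", movie@frameRate),
             paste0(path, ".meta.txt"))
  invisible(path)
}

#' Read a multi-frame 16-bit grayscale TIFF movie
#'
#' @param path TIFF file.
#' @param frame_rate acquisition rate, Hz; when \code{NULL} it is taken
#'   from the sidecar written by [writeMovie()] (an error if absent).
#' @return A [Movie-class] with integer counts.
#' @export
readMovie <- function(path, frame_rate = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE,
                                    as.is = TRUE),
                     error = function(e)
                       stop("failed to read TIFF (corrupt or truncated): ",
                            conditionMessage(e)))
  if (!length(frames)) stop("empty TIFF")
  if (is.null(frame_rate)) {
    sidecar <- paste0(path, ".meta.txt")
    if (file.exists(sidecar)) {
      ln <- grep("^frame_rate_hz=", readLines(sidecar), value = TRUE)
      if (length(ln))
        frame_rate <- as.numeric(sub("^frame_rate_hz=", "", ln[1]))
    }
    if (is.null(frame_rate) || !isTRUE(is.finite(frame_rate)))
      stop("frame rate not stored alongside the file; pass frame_rate=")
  }
  d1 <- dim(frames[[1]])
  counts <- array(0, c(length(frames), d1[1], d1[2]))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (length(dim(f)) != 2L)
      stop("frame ", i, " is not grayscale (RGB or multi-channel)")
    if (!identical(dim(f), d1))
      stop("frame ", i, " has inconsistent shape")
    counts[i, , ] <- f
  }
  new("Movie", counts = counts, frameRate = frame_rate,
      origin = list(path = path))
}

## 3x3 mean filter with edge replication.
meanFilter3 <- function(frame) {
  h <- nrow(frame); w <- ncol(frame)
  p <- frame[c(1, 1:h, h), c(1, 1:w, w)]
  acc <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + p[dr + 1:h, dc + 1:w]
  acc / 9
}

#' Render an oscillation segment as a pseudocolor image sequence
#'
#' Each frame of the segment (oscillation bounds plus \code{pad_frames}
#' on both sides) is spatially low-pass filtered with a 3 x 3 mean
#' kernel; the global minimum and maximum over the whole segment are
#' mapped to the ends of the colormap, maximising dynamic range without
#' saturating any pixel. Frames are written as a numbered PNG sequence
#' together with a playback note: 1 kHz acquisitions played at the
#' default 30 fps run 33-fold slowed down. (Encoding to a video
#' container is left to the user's encoder of choice.)
#'
#' @param movie a [Movie-class].
#' @param out_dir output directory (created if needed).
#' @param start_ms,end_ms segment bounds, ms (e.g. oscillation bounds).
#' @param pad_frames frames prepended and appended (default 75).
#' @param colormap a colour vector (default 256-step viridis).
#' @param fps_out playback rate for the note, frames/s (default 30).
#' @return Invisible list: \code{files}, \code{n_frames},
#'   \code{slowdown}, \code{range} (the global min/max used).
#' @export
renderPseudocolorMovie <- function(movie, out_dir, start_ms, end_ms,
                                   pad_frames = 75,
                                   colormap = grDevices::hcl.colors(256, "viridis"),
                                   fps_out = 30) {
  validObject(movie)
  d <- dim(movie@counts)
  dtms <- 1000 / movie@frameRate
  i0 <- max(1L, round(start_ms / dtms) + 1L - pad_frames)
  i1 <- min(d[1], round(end_ms / dtms) + 1L + pad_frames)
  if (i1 < i0) stop("empty segment")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  filtered <- lapply(i0:i1, function(i) meanFilter3(movie@counts[i, , ]))
  rng <- range(unlist(lapply(filtered, range)))
  ncol_map <- length(colormap)
  rgb_map <- t(grDevices::col2rgb(colormap)) / 255
  files <- character(length(filtered))
  for (k in seq_along(filtered)) {
    z <- filtered[[k]]
    scaled <- if (rng[2] > rng[1]) (z - rng[1]) / (rng[2] - rng[1])
              else matrix(0.5, nrow(z), ncol(z))
    ci <- pmin(ncol_map, 1L + floor(scaled * (ncol_map - 1) + 0.5))
    img <- array(rgb_map[ci, ], c(nrow(z), ncol(z), 3))
    files[k] <- file.path(out_dir, sprintf("frame_%05d.png", k))
    png::writePNG(img, files[k])
  }
  slowdown <- movie@frameRate / fps_out
  writeLines(sprintf(
    "acquired at %g Hz; play the sequence at %g fps (%.0f-fold slowed down)",
    movie@frameRate, fps_out, slowdown),
    file.path(out_dir, "playback.txt"))
  invisible(list(files = files, n_frames = length(files),
                 slowdown = slowdown, range = rng))
}

#' Write a pixel mask as PNG and CSV
#'
#' @param mask a [PixelMask-class].
#' @param png_path,csv_path output files (either may be \code{NULL}).
#' @return Invisible \code{NULL}.
#' @export
writeMask <- function(mask, png_path = NULL, csv_path = NULL) {
  if (!is.null(png_path))
    png::writePNG(ifelse(mask@masked, 0, 1), png_path)
  if (!is.null(csv_path)) {
    idx <- which(mask@masked)
    px <- indexPixel(idx, nrow(mask@masked))
    write.csv(data.frame(row = px[, 1], col = px[, 2]), csv_path,
              row.names = FALSE)
  }
  invisible(NULL)
}
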