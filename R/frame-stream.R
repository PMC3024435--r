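#' Raw interleaved frame stream
#'
#' Container for a wavelength-interleaved grayscale movie as produced by a
#' sequentially illuminated imaging system: the camera runs at `n` times the
#' effective per-wavelength rate (e.g. 120 Hz camera rate for 30 Hz imaging
#' with four wavelengths), and consecutive frames cycle through the
#' illumination wavelengths.
#'
#' @param frames numeric array, time x rows x cols, non-negative intensities
#'   in arbitrary units.
#' @param wavelength_tags vector of wavelength identifiers, either one per
#'   frame or one cycle (recycled across the movie).
#' @param frame_rate_hz camera frame rate in Hz.
#' @param pixel_pitch_um physical pixel size in micrometers.
#' @return an object of class `frame_stream`.
#' @export
frame_stream <- function(frames, wavelength_tags, frame_rate_hz,
                         pixel_pitch_um = 80) {
  if (length(dim(frames)) != 3L)
    stop_fcois("`frames` must be a time x rows x cols array",
               class = "fcois_input_error")
  if (dim(frames)[1] == 0L)
    stop_fcois("empty frame stream", class = "fcois_input_error")
  if (any(frames < 0))
    stop_fcois("intensities must be non-negative", class = "fcois_input_error")
  nt <- dim(frames)[1]
  tags <- as.character(wavelength_tags)
  if (length(tags) < nt) {
    if (nt %% length(tags) != 0 && length(tags) > 1) {
      # partial trailing cycle is allowed; recycle then truncate
      tags <- rep(tags, length.out = nt)
    } else {
      tags <- rep(tags, length.out = nt)
    }
  } else {
    tags <- tags[seq_len(nt)]
  }
  structure(list(frames = frames, wavelength_tags = tags,
                 frame_rate_hz = frame_rate_hz,
                 pixel_pitch_um = pixel_pitch_um),
            class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stream> %d frames of %dx%d @ %g Hz, tags {%s}\n",
              d[1], d[2], d[3], x$frame_rate_hz,
              paste(unique(x$wavelength_tags), collapse = ", ")))
  invisible(x)
}

# Infer the tag cycle and check periodicity. Returns the first cycle.
tag_cycle <- function(tags) {
  first <- tags[1]
  nxt <- which(tags[-1] == first)
  period <- if (length(nxt) == 0) length(tags) else nxt[1]
  cycle <- tags[seq_len(period)]
  if (anyDuplicated(cycle))
    stop_fcois("wavelength tags repeat within one cycle",
               class = "fcois_tagging_error")
  full <- rep(cycle, length.out = length(tags))
  if (!identical(full, tags))
    stop_fcois("wavelength tag sequence is not periodic",
               class = "fcois_tagging_error")
  cycle
}

#' Demultiplex a wavelength-interleaved stream
#'
#' Splits an interleaved movie into one movie per wavelength. The
#' per-channel rate is the stream rate divided by the cycle length; a
#' trailing incomplete wavelength cycle is dropped with a warning.
#'
#' @param stream a [frame_stream()].
#' @return an object of class `channel_set`: a named list of per-wavelength
#'   movies plus `channel_rate_hz`, `wavelengths` and `pixel_pitch_um`.
#' @export
demux_wavelengths <- function(stream) {
  stopifnot(inherits(stream, "frame_stream"))
  nt <- dim(stream$frames)[1]
  cycle <- tag_cycle(stream$wavelength_tags)
  p <- length(cycle)
  if (nt < p)
    stop_fcois("fewer frames than one wavelength cycle",
               class = "fcois_input_error")
  ncyc <- nt %/% p
  if (nt %% p != 0)
    warning(sprintf("dropping %d trailing frame(s) not filling a full cycle",
                    nt %% p))
  channels <- lapply(seq_len(p), function(k) {
    stream$frames[seq(k, by = p, length.out = ncyc), , , drop = FALSE]
  })
  names(channels) <- cycle
  structure(list(channels = channels,
                 wavelengths = cycle,
                 channel_rate_hz = stream$frame_rate_hz / p,
                 pixel_pitch_um = stream$pixel_pitch_um),
            class = "channel_set")
}

#' Re-interleave a channel set into a frame stream
#'
#' Inverse of [demux_wavelengths()] for streams with complete cycles.
#'
#' @param channels a `channel_set`.
#' @return a [frame_stream()].
#' @export
interleave_channels <- function(channels) {
  stopifnot(inherits(channels, "channel_set"))
  p <- length(channels$channels)
  d <- dim(channels$channels[[1]])
  out <- array(0, c(d[1] * p, d[2], d[3]))
  for (k in seq_len(p)) {
    out[seq(k, by = p, length.out = d[1]), , ] <- channels$channels[[k]]
  }
  frame_stream(out, rep(channels$wavelengths, d[1]),
               channels$channel_rate_hz * p, channels$pixel_pitch_um)
}

#' Spatially bin a frame by block averaging
#'
#' Each output pixel is the mean of its `factor` x `factor` input block, so
#' a 512x512 frame binned by 4 becomes 128x128 and the global mean
#' intensity is preserved exactly. Block mean (not sum) keeps intensity
#' units stable; ratiometric analyses are scale-invariant either way.
#'
#' @param frame 2-D numeric matrix.
#' @param factor positive integer; both dimensions must be divisible by it.
#' @return binned matrix of dimension `dim(frame) / factor`.
#' @export
bin_frames <- function(frame, factor) {
  if (!is_count(factor))
    stop_fcois("`factor` must be a positive integer", class = "fcois_input_error")
  if (factor == 1L) return(frame)
  d <- dim(frame)
  if (any(d %% factor != 0))
    stop_fcois(sprintf("frame of %dx%d is not divisible by factor %d",
                       d[1], d[2], factor), class = "fcois_shape_error")
  nr <- d[1] %/% factor
  nc <- d[2] %/% factor
  # sum over blocks via two reshapes, then divide by block size
  x <- array(frame, c(factor, nr, factor, nc))
  out <- apply(x, c(2, 4), sum) / factor^2
  out
}

#' Bin every frame of a movie array
#'
#' @param movie time x rows x cols array.
#' @inheritParams bin_frames
#' @return binned movie array.
#' @export
bin_movie <- function(movie, factor) {
  if (factor == 1L) return(movie)
  d <- dim(movie)
  out <- array(0, c(d[1], d[2] %/% factor, d[3] %/% factor))
  for (t in seq_len(d[1])) out[t, , ] <- bin_frames(movie[t, , ], factor)
  out
}

#' White-light composite image
#'
#' Builds a false-color anatomical image from the first frame of the red,
#' yellow and blue illumination channels, each normalized to a maximum of
#' one and stored in the red, green and blue planes of an RGB image.
#'
#' @param channels a `channel_set` containing the requested wavelengths.
#' @param red,yellow,blue wavelength names used for the R, G and B planes.
#' @return rows x cols x 3 array with values in `[0, 1]`.
#' @export
white_light_composite <- function(channels, red = "625", yellow = "588",
                                  blue = "478") {
  stopifnot(inherits(channels, "channel_set"))
  pick <- function(wl) {
    if (!wl %in% names(channels$channels))
      stop_fcois(sprintf("channel %s nm not present", wl),
                 class = "fcois_input_error")
    frame <- channels$channels[[wl]][1, , ]
    m <- max(frame)
    if (m == 0) {
      warning(sprintf("channel %s nm is all zero; left unnormalized", wl))
      frame
    } else frame / m
  }
  r <- pick(red); g <- pick(yellow); b <- pick(blue)
  out <- array(0, c(dim(r), 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

#' Brain mask from a painted image
#'
#' Follows the manual segmentation convention in which all non-brain pixels
#' of the white-light image are painted pure white: a pixel is excluded when
#' every color channel is at or above `white_threshold`, and every other
#' pixel (including anti-aliased near-white) is brain.
#'
#' @param painted rows x cols x 3 RGB array in `[0, 1]`, or a grayscale
#'   matrix.
#' @param white_threshold exclusion threshold; the default `1` excludes only
#'   pure white.
#' @param pixel_pitch_um physical pixel size, stored on the mask.
#' @return a `brain_mask`: logical matrix with attribute `pixel_pitch_um`.
#' @export
mask_from_painted_image <- function(painted, white_threshold = 1,
                                    pixel_pitch_um = 80) {
  if (length(dim(painted)) == 3L) {
    white <- apply(painted >= white_threshold, c(1, 2), all)
  } else {
    white <- painted >= white_threshold
  }
  mask <- !white
  if (!any(mask))
    stop_fcois("mask is empty: every pixel is painted white",
               class = "fcois_input_error")
  brain_mask(mask, pixel_pitch_um)
}

#' Construct a brain mask
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @param pixel_pitch_um physical pixel size in micrometers.
#' @return object of class `brain_mask`.
#' @export
brain_mask <- function(mask, pixel_pitch_um = 80) {
  mask <- mask == TRUE
  if (!any(mask))
    stop_fcois("mask must contain at least one pixel",
               class = "fcois_input_error")
  structure(mask, pixel_pitch_um = pixel_pitch_um,
            class = c("brain_mask", "matrix", "array"))
}

#' Read a multi-page TIFF movie as a frame stream
#'
#' @param path TIFF file with one page per frame.
#' @param wavelength_tags tag cycle (or full tag sequence).
#' @param frame_rate_hz camera frame rate.
#' @param pixel_pitch_um pixel size in micrometers.
#' @return a [frame_stream()].
#' @export
read_frame_stream_tiff <- function(path, wavelength_tags, frame_rate_hz,
                                   pixel_pitch_um = 80) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  frames <- array(0, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]
  frame_stream(frames, wavelength_tags, frame_rate_hz, pixel_pitch_um)
}

#' Write a frame stream to a multi-page TIFF
#'
#' Intensities are rescaled to `[0, 1]` by the stream maximum (TIFF stores
#' normalized floats); the scale factor is returned invisibly.
#'
#' @param stream a [frame_stream()].
#' @param path output file.
#' @export
write_frame_stream_tiff <- function(stream, path) {
  m <- max(stream$frames)
  scl <- if (m > 0) m else 1
  pages <- lapply(seq_len(dim(stream$frames)[1]),
                  function(i) stream$frames[i, , ] / scl)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(scl)
}
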