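#' Masked-pixel trace matrix
#'
#' Holds one time trace per brain pixel (pixels x time), the sampling rate,
#' and the pixel index map. After [global_signal_regression()] the fitted
#' global signal and per-pixel regression weights are carried along.
#'
#' @param traces pixels x time numeric matrix.
#' @param rate_hz sampling rate.
#' @param pixels data frame with columns `row`, `col` (1-based), one row
#'   per trace; see [mask_pixels()].
#' @param pixel_pitch_um pixel size in micrometers.
#' @param mask_dim dimensions of the originating image grid.
#' @return object of class `trace_matrix`.
#' @export
trace_matrix <- function(traces, rate_hz, pixels, pixel_pitch_um = 80,
                         mask_dim = NULL) {
  traces <- as.matrix(traces)
  if (nrow(traces) != nrow(pixels))
    stop_fcois("one pixel map row per trace required",
               class = "fcois_input_error")
  structure(list(traces = traces, rate_hz = rate_hz, pixels = pixels,
                 pixel_pitch_um = pixel_pitch_um,
                 mask_dim = mask_dim %||% c(max(pixels$row), max(pixels$col)),
                 global = NULL, beta = NULL),
            class = "trace_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d pixels x %d samples @ %g Hz%s\n",
              nrow(x$traces), ncol(x$traces), x$rate_hz,
              if (!is.null(x$global)) " (global signal regressed)" else ""))
  invisible(x)
}

#' Extract masked-pixel traces from a hemoglobin movie
#'
#' @param hemo a `hemo_movie`.
#' @param mask a `brain_mask` matching the movie grid.
#' @param species `"hbo"` or `"hbr"`.
#' @return a [trace_matrix()].
#' @export
as_trace_matrix <- function(hemo, mask, species = c("hbo", "hbr")) {
  species <- match.arg(species)
  movie <- hemo[[species]]
  if (is.null(movie))
    stop_fcois("movie does not carry species ", species,
               class = "fcois_input_error")
  d <- dim(movie)
  if (!all(d[2:3] == dim(mask)))
    stop_fcois("mask and movie grids differ", class = "fcois_shape_error")
  flat <- matrix(movie, nrow = d[1])
  traces <- t(flat[, as.vector(mask), drop = FALSE])
  trace_matrix(traces, hemo$rate_hz, mask_pixels(mask),
               attr(mask, "pixel_pitch_um") %||% hemo$pixel_pitch_um,
               mask_dim = dim(mask))
}

# Squared magnitude of the order-`order` Butterworth band-pass applied
# forward and backward (i.e. |H_lp|^2 * |H_hp|^2), evaluated at frequencies
# `f`. This is the exact zero-phase response of a forward-backward pass.
butterworth_gain2 <- function(f, low, high, order = 4) {
  af <- abs(f)
  g <- 1 / (1 + (af / high)^(2 * order))
  pos <- af > 0
  g[pos] <- g[pos] / (1 + (low / af[pos])^(2 * order))
  g[!pos] <- 0
  g
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters each trace to the functional-connectivity band (default
#' 0.009-0.08 Hz) with the squared-magnitude response of an order-4
#' Butterworth band-pass, equivalent to a forward-backward (zero-phase)
#' pass. The response is applied spectrally on the demeaned trace, which
#' avoids the long warm-up transients a recursive implementation exhibits
#' at these band edges (the 0.009 Hz corner has a ~47 s time constant).
#' The trace is treated as one period; see the methods vignette for the
#' implications for non-stationary recordings.
#'
#' @param x numeric vector, pixels x time matrix, or [trace_matrix()].
#' @param low,high band edges in Hz.
#' @param fs sampling rate in Hz (taken from a `trace_matrix` input).
#' @param order Butterworth order per pass.
#' @return filtered object of the same type.
#' @export
bandpass <- function(x, low = 0.009, high = 0.08, fs = NULL, order = 4) {
  if (inherits(x, "trace_matrix")) {
    x$traces <- bandpass(x$traces, low, high, fs %||% x$rate_hz, order)
    return(x)
  }
  if (is.null(fs)) stop_fcois("`fs` required", class = "fcois_config_error")
  if (fs <= 2 * high)
    stop_fcois("sampling rate must exceed twice the upper band edge",
               class = "fcois_config_error")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (n < fs / low)
    stop_fcois("trace shorter than one period of the low cutoff",
               class = "fcois_length_error")
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * fs / n
  g <- butterworth_gain2(f, low, high, order)
  out <- matrix(0, nrow(x), n)
  # chunk over pixels to bound the complex-valued FFT intermediates
  chunk <- max(1L, 5e6 %/% n)
  for (s in seq(1L, nrow(x), by = chunk)) {
    e <- min(nrow(x), s + chunk - 1L)
    xt <- t(x[s:e, , drop = FALSE])
    xt <- xt - rep(colMeans(xt), each = n)    # time x pixels, demeaned
    y <- Re(stats::mvfft(stats::mvfft(xt) * g, inverse = TRUE)) / n
    out[s:e, ] <- t(y)
  }
  if (vec) out[1, ] else out
}

#' Resample band-limited traces to 1 Hz
#'
#' Plain decimation (every `fs`-th sample, starting at the first): after
#' band-pass filtering below 0.08 Hz there is no energy near the 0.5 Hz
#' Nyquist limit of the target rate, so decimation is alias-free. Output
#' length is the whole number of seconds in the recording.
#'
#' @param x vector, pixels x time matrix, or [trace_matrix()].
#' @param fs input sampling rate (Hz); must be a whole number.
#' @return decimated object of the same type at 1 Hz.
#' @export
resample_to_1hz <- function(x, fs = NULL) {
  if (inherits(x, "trace_matrix")) {
    x$traces <- resample_to_1hz(x$traces, fs %||% x$rate_hz)
    x$rate_hz <- 1
    return(x)
  }
  if (is.null(fs)) stop_fcois("`fs` required", class = "fcois_config_error")
  if (fs != round(fs))
    stop_fcois("only whole-number input rates are supported",
               class = "fcois_resampling_error")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n_out <- ncol(x) %/% fs
  idx <- (seq_len(n_out) - 1L) * fs + 1L
  out <- x[, idx, drop = FALSE]
  if (vec) out[1, ] else out
}

#' Global signal regression
#'
#' The brain-average time course `g(t)` (unweighted mean over all pixels)
#' is regressed out of every pixel trace: `beta_p = <y_p, g> / <g, g>` and
#' the residual is `y_p - beta_p g`. Because the average of the `beta_p`
#' over pixels is exactly 1, the brain-average residual trace is zero to
#' machine precision.
#'
#' @param x pixels x time matrix or [trace_matrix()].
#' @return for a matrix, a list with `traces`, `global`, `beta`; for a
#'   `trace_matrix`, the object with residual traces and `global`/`beta`
#'   fields filled in.
#' @export
global_signal_regression <- function(x) {
  if (inherits(x, "trace_matrix")) {
    res <- global_signal_regression(x$traces)
    x$traces <- res$traces
    x$global <- res$global
    x$beta <- res$beta
    return(x)
  }
  if (nrow(x) < 2)
    stop_fcois("need at least two pixels", class = "fcois_input_error")
  g <- colMeans(x)
  gg <- sum(g^2)
  if (gg == 0)
    stop_fcois("global signal is identically zero",
               class = "fcois_degenerate_global_error")
  beta <- as.vector(x %*% g) / gg
  list(traces = x - outer(beta, g), global = g, beta = beta)
}

#' One-sided power spectrum
#'
#' Periodogram normalized so that the summed power across positive
#' frequencies equals the (population) variance of the trace, and the
#' zero-frequency term equals the squared mean.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @return data frame with columns `frequency` (Hz) and `power`.
#' @export
power_spectrum <- function(x, fs) {
  n <- length(x)
  if (n < 2) stop_fcois("trace too short", class = "fcois_input_error")
  X <- stats::fft(x) / n
  nf <- n %/% 2 + 1L
  p <- Mod(X[seq_len(nf)])^2
  # double the shared bins (all but DC and, for even n, Nyquist)
  dbl <- seq(2L, nf - as.integer(n %% 2 == 0))
  p[dbl] <- 2 * p[dbl]
  data.frame(frequency = (seq_len(nf) - 1L) * fs / n, power = p)
}

#' Standard functional-connectivity preprocessing
#'
#' Band-pass filter to the functional-connectivity band, resample to 1 Hz,
#' then regress out the global brain signal — in that order.
#'
#' @param tm a [trace_matrix()].
#' @param low,high band edges in Hz.
#' @param resample logical; decimate to 1 Hz after filtering.
#' @param gsr logical; apply global signal regression.
#' @return preprocessed [trace_matrix()].
#' @export
preprocess_traces <- function(tm, low = 0.009, high = 0.08,
                              resample = TRUE, gsr = TRUE) {
  stopifnot(inherits(tm, "trace_matrix"))
  if (resample) {
    # fused filter + decimate, chunked over pixels: for long recordings the
    # full-rate filtered matrix never needs to exist in memory
    fs <- tm$rate_hz
    n_out <- ncol(tm$traces) %/% fs
    out <- matrix(0, nrow(tm$traces), n_out)
    chunk <- max(1L, 5e6 %/% ncol(tm$traces))
    for (s in seq(1L, nrow(tm$traces), by = chunk)) {
      e <- min(nrow(tm$traces), s + chunk - 1L)
      filt <- bandpass(tm$traces[s:e, , drop = FALSE], low, high, fs)
      out[s:e, ] <- resample_to_1hz(filt, fs)
    }
    tm$traces <- out
    tm$rate_hz <- 1
  } else {
    tm <- bandpass(tm, low, high)
  }
  if (gsr) tm <- global_signal_regression(tm)
  tm
}
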