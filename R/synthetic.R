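#' Phantom configuration
#'
#' Study conditions for the synthetic resting-state phantom: a 128 x 128
#' grid at 80 um pitch imaged for 900 s at 30 Hz, with six bilateral
#' networks (twelve regions) tiling an elliptical "cortex". Each region
#' carries a band-limited (0.009-0.08 Hz) latent signal; homotopic region
#' pairs correlate at 0.8, the frontal/somatosensory and
#' retrosplenial/motor network pairs are anticorrelated at -0.5, and
#' visual couples weakly (+0.3) to the colliculus. On top of the network
#' signals each pixel receives a shared band-limited global component,
#' shared-phase physiological oscillations near the respiration (~2.5 Hz)
#' and heart (~10 Hz) rates, and white sensor noise.
#'
#' @param grid image side in pixels.
#' @param pixel_pitch_um pixel size.
#' @param duration_s recording length in seconds.
#' @param rate_hz hemodynamic sampling rate.
#' @param networks network names, anterior to posterior.
#' @param homotopic_r target correlation of left/right region pairs.
#' @param anticorrelated named list of network pairs and target r.
#' @param latent_sd latent signal standard deviation (uM HbO2).
#' @param global_weight weight of the shared global component.
#' @param noise_sd white pixel noise standard deviation (uM, per frame).
#' @param physio data frame of shared oscillations: `freq_hz`, `amp`.
#' @param hbr_ratio inverse coupling gamma: `dHbR = -gamma * dHbO2`.
#' @param band band edges (Hz) of the latent signals.
#' @param min_size smallest admissible region, in pixels.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(grid = 128, pixel_pitch_um = 80,
                           duration_s = 900, rate_hz = 30,
                           networks = c("frontal", "motor", "somatosensory",
                                        "retrosplenial", "visual",
                                        "colliculus"),
                           homotopic_r = 0.8,
                           anticorrelated = list(
                             c("frontal", "somatosensory", -0.5),
                             c("retrosplenial", "motor", -0.5),
                             c("visual", "colliculus", 0.3)),
                           latent_sd = 1, global_weight = 0.3,
                           noise_sd = 1,
                           physio = data.frame(freq_hz = c(2.5, 10),
                                               amp = c(0.5, 0.25)),
                           hbr_ratio = 0.3,
                           band = c(0.009, 0.08),
                           min_size = 10) {
  if (length(networks) == 0)
    stop_fcois("at least one network required", class = "fcois_config_error")
  structure(list(grid = grid, pixel_pitch_um = pixel_pitch_um,
                 duration_s = duration_s, rate_hz = rate_hz,
                 networks = networks, homotopic_r = homotopic_r,
                 anticorrelated = anticorrelated, latent_sd = latent_sd,
                 global_weight = global_weight, noise_sd = noise_sd,
                 physio = physio, hbr_ratio = hbr_ratio, band = band,
                 min_size = min_size),
            class = "phantom_config")
}

#' Target region-to-region correlation matrix of a phantom
#'
#' One latent per region (each network has a left and a right region).
#' Must be symmetric with unit diagonal and positive semidefinite; the
#' smallest eigenvalue is reported otherwise.
#'
#' @param config a [phantom_config()].
#' @return correlation matrix with region dimnames (`<network>_L/R`).
#' @export
phantom_target_correlation <- function(config) {
  nets <- config$networks
  regions <- as.vector(t(outer(nets, c("L", "R"), paste, sep = "_")))
  k <- length(regions)
  r <- diag(k)
  dimnames(r) <- list(regions, regions)
  for (n in nets) {
    i <- match(paste0(n, "_L"), regions); j <- match(paste0(n, "_R"), regions)
    r[i, j] <- r[j, i] <- config$homotopic_r
  }
  for (p in config$anticorrelated) {
    v <- as.numeric(p[3])
    for (s1 in c("_L", "_R")) for (s2 in c("_L", "_R")) {
      i <- match(paste0(p[1], s1), regions)
      j <- match(paste0(p[2], s2), regions)
      if (!is.na(i) && !is.na(j)) r[i, j] <- r[j, i] <- v
    }
  }
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop_fcois("target correlation matrix is not positive semidefinite ",
               "(smallest eigenvalue ", format(min(ev)), ")",
               class = "fcois_config_error")
  r
}

#' Phantom geometry: mask and ground-truth regions
#'
#' An elliptical brain mask, bilaterally symmetric, partitioned into the
#' configured networks as anterior-posterior bands split at the midline —
#' every in-mask pixel belongs to exactly one region and every region
#' exceeds the minimum parcel size.
#'
#' @param config a [phantom_config()].
#' @return list with `mask` (a `brain_mask`) and `truth` (a
#'   [label_map()] of regions named `<network>_L/R`).
#' @export
make_phantom_geometry <- function(config) {
  n <- config$grid
  ctr <- (n + 1) / 2
  a <- 0.455 * n                 # semi-axis along rows (anterior-posterior)
  b <- 0.355 * n                 # semi-axis along cols (medial-lateral)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  inside <- ((rows - ctr) / a)^2 + ((cols - ctr) / b)^2 <= 1
  mask <- brain_mask(inside, config$pixel_pitch_um)
  nets <- config$networks
  band <- pmin(length(nets),
               pmax(1L, 1L + floor((rows - (ctr - a)) / (2 * a / length(nets)))))
  region <- 2L * (band - 1L) + ifelse(cols <= ctr, 1L, 2L)
  img <- matrix(NA_integer_, n, n)
  img[inside] <- region[inside]
  regions <- as.vector(t(outer(nets, c("L", "R"), paste, sep = "_")))
  counts <- tabulate(img[inside], nbins = length(regions))
  if (any(counts < config$min_size))
    stop_fcois("region(s) smaller than min_size: ",
               paste(regions[counts < config$min_size], collapse = ", "),
               class = "fcois_config_error")
  truth <- label_map(img, n_slots = length(regions), names = regions,
                     pixel_pitch_um = config$pixel_pitch_um)
  list(mask = mask, truth = truth)
}

# Band-limited unit-variance noise traces (k x t), filtered with the same
# Butterworth band as preprocessing.
band_limited_noise <- function(k, t, fs, band) {
  x <- matrix(stats::rnorm(k * t), k, t)
  y <- bandpass(x, band[1], band[2], fs)
  y / sqrt(rowMeans(y^2))
}

#' Latent network traces with an exact target correlation
#'
#' Band-limited latent signals, one per region: white noise is filtered
#' to the functional-connectivity band, empirically whitened (so the
#' sample correlation of the basis is exactly the identity) and mixed by
#' the Cholesky factor of the target correlation matrix. The sample
#' correlation over the full duration therefore equals the target to
#' machine precision, and the whitening guarantees any positive
#' semidefinite target is realizable.
#'
#' @param config a [phantom_config()].
#' @param seed RNG seed (integer) for reproducibility; `NULL` leaves the
#'   RNG state alone.
#' @return matrix regions x time (uM), rownames `<network>_L/R`, with the
#'   target matrix in attribute `target`.
#' @export
simulate_network_traces <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  target <- phantom_target_correlation(config)
  k <- nrow(target)
  t <- round(config$duration_s * config$rate_hz)
  z <- band_limited_noise(k, t, config$rate_hz, config$band)
  z <- z - rowMeans(z)
  # empirical whitening: rows exactly orthonormal after this
  s <- svd(z, nu = k, nv = 0)
  w <- t(s$u) %*% z
  w <- w / sqrt(rowSums(w^2))
  lat <- chol_psd(target) %*% w
  lat <- lat * config$latent_sd / sqrt(rowMeans(lat^2))
  rownames(lat) <- rownames(target)
  attr(lat, "target") <- target
  lat
}

# Cholesky-like factor L with L %*% t(L) = x, tolerating semidefiniteness.
chol_psd <- function(x) {
  e <- eigen(x, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(v), nrow = length(v))
}

#' Render phantom hemodynamics
#'
#' Every pixel of a region receives its region latent plus the shared
#' global component, the shared-phase physiological oscillations, and
#' independent white noise; deoxy-hemoglobin is inversely coupled as
#' `dHbR = -gamma * dHbO2`. With `masked = TRUE` (the default for large
#' phantoms) traces are returned only for in-mask pixels, pixels outside
#' the brain carrying no signal by construction.
#'
#' @param geometry from [make_phantom_geometry()].
#' @param latents from [simulate_network_traces()].
#' @param config a [phantom_config()].
#' @param seed RNG seed for noise and physiological phases.
#' @param masked return a masked [trace_matrix()]-backed movie rather
#'   than full grid arrays.
#' @param species which contrasts to materialize.
#' @return a `hemo_movie`; in masked mode the elements `hbo`/`hbr` are
#'   pixels x time matrices with a `pixels` map attached.
#' @export
render_hemodynamics <- function(geometry, latents, config, seed = NULL,
                                masked = TRUE, species = c("hbo", "hbr")) {
  if (!is.null(seed)) set.seed(seed)
  lab <- labels_for_pixels(geometry$truth, mask_pixels(geometry$mask))
  t_len <- ncol(latents)
  tt <- (seq_len(t_len) - 1) / config$rate_hz
  g <- band_limited_noise(1, t_len, config$rate_hz, config$band)[1, ]
  phases <- stats::runif(nrow(config$physio), 0, 2 * pi)
  physio <- rep(0, t_len)
  for (i in seq_len(nrow(config$physio)))
    physio <- physio + config$physio$amp[i] *
      sin(2 * pi * config$physio$freq_hz[i] * tt + phases[i])
  shared <- config$global_weight * g + physio
  n_px <- length(lab)
  # fill pixel chunks in place to bound peak memory on large phantoms
  hbo <- matrix(0, n_px, t_len)
  chunk <- max(1L, 2e7 %/% t_len)
  for (s in seq(1L, n_px, by = chunk)) {
    e <- min(n_px, s + chunk - 1L)
    blk <- latents[lab[s:e], , drop = FALSE]
    blk <- blk + rep(shared, each = e - s + 1L)
    if (config$noise_sd > 0)
      blk <- blk + stats::rnorm((e - s + 1L) * t_len, sd = config$noise_sd)
    hbo[s:e, ] <- blk
  }
  px <- mask_pixels(geometry$mask)
  make_movie <- function(mat) {
    if (masked) {
      mat                      # pixel map stored on the movie object
    } else {
      arr <- array(NA_real_, c(t_len, dim(geometry$mask)))
      flat <- matrix(arr, nrow = t_len)
      flat[, which(as.vector(unclass(geometry$mask)))] <- t(mat)
      array(flat, c(t_len, dim(geometry$mask)))
    }
  }
  out <- list(hbo = NULL, hbr = NULL,
              rate_hz = config$rate_hz,
              pixel_pitch_um = config$pixel_pitch_um,
              masked = masked, global_truth = g,
              pixels = if (masked) px,
              grid_dim = dim(geometry$mask))
  if ("hbo" %in% species) out$hbo <- make_movie(hbo)
  if ("hbr" %in% species) out$hbr <- make_movie(-config$hbr_ratio * hbo)
  class(out) <- "hemo_movie"
  out
}

#' Traces of a masked phantom movie
#'
#' @param hemo a masked `hemo_movie` from [render_hemodynamics()].
#' @param species contrast to extract.
#' @return a [trace_matrix()].
#' @export
phantom_traces <- function(hemo, species = c("hbo", "hbr")) {
  species <- match.arg(species)
  mat <- hemo[[species]]
  if (is.null(mat) || !isTRUE(hemo$masked))
    stop_fcois("not a masked phantom movie; use as_trace_matrix()",
               class = "fcois_input_error")
  px <- hemo$pixels
  trace_matrix(mat, hemo$rate_hz, px, hemo$pixel_pitch_um,
               mask_dim = hemo$grid_dim)
}

#' Render a raw interleaved frame stream from hemodynamics
#'
#' Forward Modified Beer-Lambert rendering: for each model wavelength,
#' `Phi(t) = Phi0 * exp(-(eps_HbO2 dHbO2 + eps_HbR dHbR) * L)`, the
#' per-wavelength frames interleaved cyclically at `n_wavelengths` times
#' the hemodynamic rate (120 Hz for four wavelengths at 30 Hz). Each
#' wavelength samples the hemodynamic state of its frame's cycle.
#'
#' @param hemo an unmasked `hemo_movie` (grid arrays).
#' @param model an [optical_model()].
#' @param phi0 baseline intensity (scalar or per wavelength).
#' @return a [frame_stream()] at `rate_hz * n_wavelengths`.
#' @export
render_raw_frames <- function(hemo, model, phi0 = 100) {
  if (isTRUE(hemo$masked))
    stop_fcois("raw rendering needs an unmasked movie (masked = FALSE)",
               class = "fcois_input_error")
  if (any(phi0 <= 0))
    stop_fcois("baseline intensity must be positive", class = "fcois_input_error")
  d <- dim(hemo$hbo)
  nw <- length(model$wavelengths_nm)
  phi0 <- rep(phi0, length.out = nw)
  hbo <- ifelse(is.na(hemo$hbo), 0, hemo$hbo)
  hbr <- ifelse(is.na(hemo$hbr), 0, hemo$hbr)
  frames <- array(0, c(d[1] * nw, d[2], d[3]))
  for (k in seq_len(nw)) {
    expo <- -(model$extinction[k, "hbo"] * hbo +
                model$extinction[k, "hbr"] * hbr) * model$pathlength_mm[k]
    if (!all(is.finite(expo)))
      stop_fcois("non-finite optical exponent", class = "fcois_amplitude_error")
    frames[seq(k, by = nw, length.out = d[1]), , ] <- phi0[k] * exp(expo)
  }
  frame_stream(frames, as.character(model$wavelengths_nm),
               hemo$rate_hz * nw, hemo$pixel_pitch_um)
}

#' Generate a complete phantom
#'
#' Convenience wrapper: geometry, latents and hemodynamics under one seed.
#' With a fixed seed the phantom is bit-reproducible.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed.
#' @param masked,species passed to [render_hemodynamics()].
#' @return list with `config`, `mask`, `truth`, `latents`, `hemo`.
#' @export
simulate_phantom <- function(config = phantom_config(), seed = 1,
                             masked = TRUE, species = "hbo") {
  set.seed(seed)
  geometry <- make_phantom_geometry(config)
  latents <- simulate_network_traces(config)
  hemo <- render_hemodynamics(geometry, latents, config, masked = masked,
                              species = species)
  list(config = config, mask = geometry$mask, truth = geometry$truth,
       latents = latents, hemo = hemo)
}
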