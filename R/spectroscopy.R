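#' Optical model for hemoglobin spectroscopy
#'
#' Bundles the per-wavelength extinction coefficients of oxy- and
#' deoxy-hemoglobin with the effective photon pathlengths used by the
#' Modified Beer-Lambert Law. Extinction coefficients are stored in the
#' natural-log convention with units mm^-1 uM^-1, so that differential
#' absorption stays in mm^-1 when concentrations are in uM. Tabulated
#' compilations usually give base-10 molar extinction in cm^-1 M^-1;
#' multiply by `log(10) * 1e-7` to convert.
#'
#' @param wavelengths_nm numeric vector of wavelengths.
#' @param extinction matrix with one row per wavelength and columns
#'   `hbo`, `hbr` (mm^-1 uM^-1, natural log).
#' @param pathlength_mm effective pathlength per wavelength (mm), or `NULL`
#'   when pathlengths are to be computed from optical properties.
#' @param mu_a_mm,mu_s_prime_mm optional baseline absorption and reduced
#'   scattering coefficients (mm^-1) per wavelength for analytic
#'   pathlength mode.
#' @return object of class `optical_model`.
#' @export
optical_model <- function(wavelengths_nm, extinction, pathlength_mm = NULL,
                          mu_a_mm = NULL, mu_s_prime_mm = NULL) {
  extinction <- as.matrix(extinction)
  if (nrow(extinction) != length(wavelengths_nm))
    stop_fcois("one extinction row per wavelength required",
               class = "fcois_config_error")
  if (ncol(extinction) != 2L)
    stop_fcois("extinction must have columns for HbO2 and HbR",
               class = "fcois_config_error")
  if (nrow(extinction) < ncol(extinction))
    stop_fcois("need at least as many wavelengths as hemoglobin species",
               class = "fcois_config_error")
  cond <- kappa(extinction)
  if (!is.finite(cond) || cond > 1e12)
    stop_fcois("extinction matrix is rank deficient (condition number ",
               format(cond), ")", class = "fcois_conditioning_error")
  if (is.null(pathlength_mm)) {
    if (is.null(mu_a_mm) || is.null(mu_s_prime_mm))
      stop_fcois("supply either pathlength_mm or baseline optical properties",
                 class = "fcois_config_error")
    pathlength_mm <- pathlength_factors(mu_a_mm = mu_a_mm,
                                        mu_s_prime_mm = mu_s_prime_mm)
  }
  if (any(pathlength_mm <= 0))
    stop_fcois("pathlengths must be positive", class = "fcois_config_error")
  colnames(extinction) <- c("hbo", "hbr")
  structure(list(wavelengths_nm = wavelengths_nm,
                 extinction = extinction,
                 pathlength_mm = pathlength_mm),
            class = "optical_model")
}

#' Read an optical model from JSON or YAML
#'
#' Expected keys: `wavelengths_nm`, `extinction` (rows per wavelength,
#' columns HbO2 then HbR), and either `pathlength_mm` or `mu_a_mm` +
#' `mu_s_prime_mm` for analytic pathlength mode.
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return an [optical_model()].
#' @export
read_optical_model <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path)
  ext <- if (is.matrix(cfg$extinction)) cfg$extinction
         else do.call(rbind, lapply(cfg$extinction, unlist))
  optical_model(unlist(cfg$wavelengths_nm), ext,
                pathlength_mm = cfg$pathlength_mm,
                mu_a_mm = cfg$mu_a_mm, mu_s_prime_mm = cfg$mu_s_prime_mm)
}

#' Diffuse reflectance of a semi-infinite medium
#'
#' Diffusion-approximation reflectance at source-detector separation
#' `rho_mm`, up to a geometry constant:
#' `R = exp(-mu_eff * rho) * (1 + mu_eff * rho) / rho^2` with
#' `mu_eff = sqrt(3 * mu_a * (mu_a + mu_s'))`. Used as the model whose
#' log-derivative with respect to absorption defines the mean photon
#' pathlength.
#'
#' @param mu_a_mm absorption coefficient (mm^-1).
#' @param mu_s_prime_mm reduced scattering coefficient (mm^-1).
#' @param rho_mm effective source-detector separation (mm).
#' @return reflectance (arbitrary units).
#' @export
diffusion_reflectance <- function(mu_a_mm, mu_s_prime_mm, rho_mm = 1) {
  mu_eff <- sqrt(3 * mu_a_mm * (mu_a_mm + mu_s_prime_mm))
  exp(-mu_eff * rho_mm) * (1 + mu_eff * rho_mm) / rho_mm^2
}

#' Effective photon pathlength factors
#'
#' In table mode (the default when `pathlength_mm` is given) the values are
#' returned unchanged. In analytic mode the mean pathlength is the
#' sensitivity of the diffusion-model reflectance to absorption,
#' `L = -d ln R / d mu_a`, evaluated in closed form:
#' `L = (3/2) * (2 mu_a + mu_s') * rho^2 / (1 + mu_eff * rho)`.
#' The effective separation `rho_mm` stands in for the illumination
#' geometry and is configurable.
#'
#' @param pathlength_mm direct pathlength table (mm); returned verbatim.
#' @param mu_a_mm,mu_s_prime_mm per-wavelength baseline optical properties
#'   (mm^-1) for analytic mode.
#' @param rho_mm effective source-detector separation (mm).
#' @return numeric vector of pathlengths (mm).
#' @export
pathlength_factors <- function(pathlength_mm = NULL, mu_a_mm = NULL,
                               mu_s_prime_mm = NULL, rho_mm = 1) {
  if (!is.null(pathlength_mm)) return(pathlength_mm)
  if (is.null(mu_a_mm) || is.null(mu_s_prime_mm))
    stop_fcois("supply a pathlength table or (mu_a, mu_s') pairs",
               class = "fcois_config_error")
  mu_eff <- sqrt(3 * mu_a_mm * (mu_a_mm + mu_s_prime_mm))
  1.5 * (2 * mu_a_mm + mu_s_prime_mm) * rho_mm^2 / (1 + mu_eff * rho_mm)
}

#' Intensity movie to differential absorption
#'
#' Applies the Modified Beer-Lambert Law with the temporal mean as the
#' baseline: `dmu_a(t) = -ln(Phi(t) / <Phi>_t) / L`. The result is a
#' differential measure; its temporal reference is the mean intensity, so
#' recovered concentration changes are defined up to a per-pixel constant.
#'
#' @param channel numeric array with time as the first dimension (or a
#'   pixels x time matrix with `time_first = FALSE`, or a vector).
#' @param pathlength_mm photon pathlength for this wavelength (mm).
#' @param mask optional logical matrix; intensities are validated only
#'   inside the mask, and pixels outside are set to `NA`.
#' @return array of differential absorption (mm^-1), same shape.
#' @export
intensity_to_dabs <- function(channel, pathlength_mm, mask = NULL) {
  if (pathlength_mm <= 0)
    stop_fcois("pathlength must be positive", class = "fcois_config_error")
  if (is.null(dim(channel))) channel <- matrix(channel, nrow = length(channel))
  d <- dim(channel)
  x <- matrix(channel, nrow = d[1])           # time x pixels
  check_cols <- if (!is.null(mask)) which(as.vector(mask)) else seq_len(ncol(x))
  bad <- which(x[, check_cols, drop = FALSE] <= 0, arr.ind = TRUE)
  if (length(bad) > 0) {
    stop_fcois(sprintf(
      "non-positive intensity at frame %d, pixel %d",
      bad[1, 1], check_cols[bad[1, 2]]), class = "fcois_data_error")
  }
  mu <- colMeans(x)
  y <- -log(sweep(x, 2, mu, "/")) / pathlength_mm
  if (!is.null(mask)) y[, !as.vector(mask)] <- NA_real_
  array(y, d)
}

#' Differential absorption to hemoglobin concentration changes
#'
#' Per pixel and frame, solves the spectroscopy system
#' `E %*% dHb = dmu_a` in the least-squares sense, where `E` holds the
#' extinction coefficients of HbO2 and HbR at each wavelength. The mean and
#' maximum residual norms are attached as a QC attribute.
#'
#' @param dabs list (one element per wavelength, in the model's order) of
#'   arrays of differential absorption, all the same shape with time first;
#'   or a matrix with one row per wavelength.
#' @param model an [optical_model()], or an extinction matrix.
#' @return list with elements `hbo` and `hbr` (same shape as one input
#'   element, uM) and attribute `residual` = c(mean, max).
#' @export
dabs_to_hemoglobin <- function(dabs, model) {
  E <- if (inherits(model, "optical_model")) model$extinction else as.matrix(model)
  cond <- kappa(E)
  if (!is.finite(cond) || cond > 1e12)
    stop_fcois("extinction matrix is rank deficient (condition number ",
               format(cond), ")", class = "fcois_conditioning_error")
  if (is.matrix(dabs) && !is.list(dabs)) {
    B <- dabs
    shape <- NULL
  } else {
    shape <- dim(dabs[[1]])
    if (is.null(shape)) shape <- length(dabs[[1]])
    B <- do.call(rbind, lapply(dabs, as.vector))
  }
  if (nrow(B) != nrow(E))
    stop_fcois("one absorption measurement per model wavelength required",
               class = "fcois_input_error")
  if (nrow(E) < 2L)
    stop_fcois("at least two wavelengths required", class = "fcois_input_error")
  fit <- qr.coef(qr(E), B)
  res <- B - E %*% fit
  rn <- sqrt(colSums(res^2))
  reshape <- function(v) if (is.null(shape)) as.vector(v) else array(v, shape)
  out <- list(hbo = reshape(fit[1, ]), hbr = reshape(fit[2, ]))
  attr(out, "residual") <- c(mean = mean(rn), max = max(rn))
  out
}

# Normalized truncated Gaussian kernel (1-D).
gaussian_kernel_1d <- function(size = 5, sigma = 1.3) {
  half <- (size - 1) / 2
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

# Band matrix applying 1-D Gaussian convolution with reflect padding.
conv_band_matrix <- function(n, kernel) {
  size <- length(kernel)
  half <- (size - 1L) %/% 2L
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - half):(i + half)
    # reflect indices at the borders (1-based mirror without repeating edge)
    idx <- ifelse(idx < 1, 2 - idx, idx)
    idx <- ifelse(idx > n, 2 * n - idx, idx)
    for (j in seq_along(idx)) A[i, idx[j]] <- A[i, idx[j]] + kernel[j]
  }
  A
}

#' Spatial Gaussian smoothing
#'
#' Per-frame 2-D convolution with a normalized truncated Gaussian (default
#' 5x5 support, sigma 1.3 pixels). The kernel is separable and applied as
#' two 1-D passes; borders use reflect padding, which keeps constant images
#' exactly unchanged.
#'
#' @param movie 2-D matrix or time x rows x cols array.
#' @param size odd kernel support in pixels.
#' @param sigma kernel standard deviation in pixels.
#' @return smoothed movie of the same shape.
#' @export
smooth_gaussian <- function(movie, size = 5, sigma = 1.3) {
  k <- gaussian_kernel_1d(size, sigma)
  single <- is.matrix(movie)
  if (single) movie <- array(movie, c(1, dim(movie)))
  d <- dim(movie)
  if (size > d[2] || size > d[3])
    stop_fcois("kernel does not fit the image grid", class = "fcois_shape_error")
  Ar <- conv_band_matrix(d[2], k)
  Ac <- conv_band_matrix(d[3], k)
  out <- array(0, d)
  for (t in seq_len(d[1])) out[t, , ] <- Ar %*% movie[t, , ] %*% t(Ac)
  if (single) out[1, , ] else out
}

#' Channel set to hemoglobin movie
#'
#' Full spectroscopy step: per-wavelength differential absorption via the
#' Modified Beer-Lambert Law, least-squares unmixing into HbO2/HbR, then
#' optional spatial Gaussian smoothing of each contrast.
#'
#' @param channels a `channel_set` whose names match the model wavelengths.
#' @param model an [optical_model()].
#' @param mask optional `brain_mask`; validation restricted to the mask.
#' @param smooth logical; apply [smooth_gaussian()] to each contrast.
#' @return object of class `hemo_movie` with elements `hbo`, `hbr`
#'   (time x rows x cols, uM), `rate_hz`, `pixel_pitch_um`.
#' @export
intensity_to_hemoglobin <- function(channels, model, mask = NULL,
                                    smooth = TRUE) {
  stopifnot(inherits(channels, "channel_set"))
  wl <- as.character(model$wavelengths_nm)
  if (!all(wl %in% names(channels$channels)))
    stop_fcois("channel set lacks wavelengths required by the model",
               class = "fcois_config_error")
  dabs <- lapply(seq_along(wl), function(i)
    intensity_to_dabs(channels$channels[[wl[i]]], model$pathlength_mm[i]))
  hb <- dabs_to_hemoglobin(dabs, model)
  hbo <- hb$hbo; hbr <- hb$hbr
  if (smooth) {
    hbo <- smooth_gaussian(hbo)
    hbr <- smooth_gaussian(hbr)
  }
  structure(list(hbo = hbo, hbr = hbr,
                 rate_hz = channels$channel_rate_hz,
                 pixel_pitch_um = channels$pixel_pitch_um,
                 qc = attr(hb, "residual")),
            class = "hemo_movie")
}

#' @export
print.hemo_movie <- function(x, ...) {
  d <- dim(x$hbo)
  cat(sprintf("<hemo_movie> %d frames of %dx%d @ %g Hz (HbO2 + HbR, uM)\n",
              d[1], d[2], d[3], x$rate_hz))
  invisible(x)
}
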