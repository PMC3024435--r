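#' Read a seed catalogue
#'
#' Seed catalogues are CSV/TSV tables with columns `name`, `row`, `col`
#' (1-based pixel coordinates) and `diameter_mm`.
#'
#' @param path file path; separator inferred from the extension.
#' @return data frame of seeds.
#' @export
read_seeds <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  seeds <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  need <- c("name", "row", "col", "diameter_mm")
  if (!all(need %in% names(seeds)))
    stop_fcois("seed catalogue must have columns ",
               paste(need, collapse = ", "), class = "fcois_input_error")
  seeds
}

#' Default seed catalogue
#'
#' The sixteen canonical bilateral seed locations (left and right visual,
#' somatosensory, motor, frontal, cingulate and retrosplenial cortices,
#' olfactory bulb, and superior colliculus), positioned on the default
#' 128x128 grid used by the phantom generator, each with the standard
#' 0.5 mm seed diameter.
#'
#' @return data frame with columns `name`, `row`, `col`, `diameter_mm`.
#' @export
default_seeds <- function() {
  read_seeds(system.file("extdata", "seeds_default.csv", package = "fcois"))
}

#' Pixels covered by a seed
#'
#' All pixels whose centers lie within `diameter_mm / 2` of the seed
#' center (ties at the exact radius included), intersected with the brain
#' mask. At the default 80 um pitch a 0.5 mm seed covers 29 pixels.
#'
#' @param seed one-row data frame (or list) with `row`, `col`,
#'   `diameter_mm`.
#' @param mask a `brain_mask`.
#' @param pixel_pitch_um pixel size; defaults to the mask's.
#' @return data frame of pixel `row`, `col` coordinates.
#' @export
seed_mask <- function(seed, mask, pixel_pitch_um = NULL) {
  pitch <- pixel_pitch_um %||% attr(mask, "pixel_pitch_um") %||% 80
  r_px <- (seed$diameter_mm * 1000 / 2) / pitch
  half <- floor(r_px)
  rows <- max(1, seed$row - half):min(nrow(mask), seed$row + half)
  cols <- max(1, seed$col - half):min(ncol(mask), seed$col + half)
  grid <- expand.grid(row = rows, col = cols)
  d2 <- (grid$row - seed$row)^2 + (grid$col - seed$col)^2
  grid <- grid[d2 <= r_px^2 + 1e-9, , drop = FALSE]
  keep <- mask[cbind(grid$row, grid$col)]
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0)
    stop_fcois(sprintf("seed %s does not intersect the brain mask",
                       seed$name %||% ""), class = "fcois_seed_error")
  rownames(grid) <- NULL
  grid
}

#' Average time trace over a pixel set
#'
#' @param tm a [trace_matrix()].
#' @param pixels data frame of `row`, `col` coordinates (e.g. from
#'   [seed_mask()]).
#' @return numeric trace (unweighted mean over the member pixels).
#' @export
seed_trace <- function(tm, pixels) {
  if (nrow(pixels) == 0)
    stop_fcois("empty pixel set", class = "fcois_seed_error")
  idx <- match(paste(pixels$row, pixels$col),
               paste(tm$pixels$row, tm$pixels$col))
  if (anyNA(idx))
    stop_fcois("pixel set contains pixels outside the trace matrix",
               class = "fcois_seed_error")
  colMeans(tm$traces[idx, , drop = FALSE])
}

#' Seed-based correlation map
#'
#' Pearson correlation between a reference trace and every brain pixel,
#' returned as an image. Constant pixel traces give `NaN` with a warning;
#' a constant reference trace is an error.
#'
#' @param tm a [trace_matrix()].
#' @param reference numeric trace, same length as the trace matrix.
#' @param name optional seed name stored on the map.
#' @return object of class `corr_map`: a matrix of r values with `NA`
#'   outside the mask.
#' @export
correlation_map <- function(tm, reference, name = NULL) {
  if (ncol(tm$traces) < 3)
    stop_fcois("need at least three time points", class = "fcois_input_error")
  if (stats::sd(reference) == 0)
    stop_fcois("reference trace is constant", class = "fcois_seed_error")
  z <- standardize_rows(tm$traces)
  zr <- reference - mean(reference)
  zr <- zr / sqrt(sum(zr^2))
  r <- clamp_correlation(as.vector(z %*% zr))
  if (anyNA(r))
    warning(sprintf("%d constant pixel trace(s) produced NaN correlations",
                    sum(is.na(r))))
  img <- matrix(NA_real_, tm$mask_dim[1], tm$mask_dim[2])
  img[cbind(tm$pixels$row, tm$pixels$col)] <- r
  structure(img, seed = name, pixel_pitch_um = tm$pixel_pitch_um,
            class = c("corr_map", "matrix", "array"))
}

#' Seed correlation maps for a catalogue
#'
#' @param tm a [trace_matrix()].
#' @param seeds seed catalogue data frame (see [read_seeds()]).
#' @param mask the `brain_mask` the traces were extracted with.
#' @return named list of `corr_map` objects.
#' @export
seed_correlation_maps <- function(tm, seeds, mask) {
  maps <- lapply(seq_len(nrow(seeds)), function(i) {
    px <- seed_mask(seeds[i, ], mask)
    correlation_map(tm, seed_trace(tm, px), name = seeds$name[i])
  })
  names(maps) <- seeds$name
  maps
}

#' Full pixel-by-pixel correlation matrix
#'
#' Pearson correlation between every pair of brain pixels. Row `i` equals
#' the correlation map obtained with pixel `i` as a single-pixel seed. For
#' large masks the N x N matrix becomes prohibitive; above `max_pixels`
#' an error suggests subsampling with `stride`.
#'
#' @param tm a [trace_matrix()].
#' @param stride keep every `stride`-th pixel (in the stored pixel order).
#' @param max_pixels guard on the matrix dimension.
#' @return object of class `corr_matrix` with attribute `pixels` (the
#'   index map of retained pixels).
#' @export
full_correlation_matrix <- function(tm, stride = 1, max_pixels = 6000) {
  keep <- seq(1, nrow(tm$traces), by = stride)
  if (length(keep) > max_pixels)
    stop_fcois(sprintf(
      "%d pixels exceed the %d-pixel cap; increase `stride` or `max_pixels`",
      length(keep), max_pixels), class = "fcois_memory_guard")
  if (length(keep) < 2)
    stop_fcois("need at least two pixels", class = "fcois_input_error")
  z <- standardize_rows(tm$traces[keep, , drop = FALSE])
  r <- clamp_correlation(tcrossprod(z))
  diag(r) <- 1
  structure(r, pixels = tm$pixels[keep, , drop = FALSE],
            class = c("corr_matrix", "matrix", "array"))
}

new_svd_result <- function(values, vectors, total) {
  structure(list(d = values, u = vectors,
                 variance_fraction = cumsum(values) / total,
                 total = total),
            class = "svd_result")
}

#' Dominant connectivity patterns by singular value decomposition
#'
#' Decomposes a symmetric correlation matrix into an ordered set of
#' orthonormal singular vectors; the singular values measure how much of
#' the matrix's total variance each spatial pattern carries. The variance
#' fraction `f(K)` is the sum of the first `K` singular values over the
#' sum of all of them.
#'
#' @param x a `corr_matrix` (or symmetric matrix), or a [trace_matrix()] —
#'   for traces the decomposition is computed without forming the pixel
#'   by pixel matrix, via the time-domain Gram matrix.
#' @param k number of singular vectors to retain (all by default for
#'   matrix input; `min(20, T)` for trace input).
#' @param tol symmetry tolerance for matrix input; beyond it an error is
#'   raised, within it the matrix is symmetrized with a warning.
#' @return object of class `svd_result` with fields `d` (descending
#'   singular values), `u` (orthonormal columns), `variance_fraction`
#'   (cumulative) and `total`.
#' @export
svd_patterns <- function(x, k = NULL, tol = 1e-8) {
  if (inherits(x, "trace_matrix")) return(svd_patterns_traces(x, k %||% 20))
  x <- unclass(x)
  if (!all(is.finite(x)))
    stop_fcois("matrix contains non-finite values", class = "fcois_input_error")
  asym <- max(abs(x - t(x)))
  if (asym > tol * max(1, max(abs(x))))
    stop_fcois("matrix is not symmetric (max asymmetry ", format(asym), ")",
               class = "fcois_input_error")
  if (asym > 0) {
    warning("matrix symmetrized (max asymmetry ", format(asym), ")")
    x <- (x + t(x)) / 2
  }
  e <- eigen(x, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)
  values <- abs(e$values)[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  signs <- sign(e$values)[ord]
  res <- new_svd_result(values, vectors, sum(values))
  res$signs <- signs        # eigenvalue signs, for exact reconstruction
  if (!is.null(k)) {
    res$u <- res$u[, seq_len(min(k, ncol(res$u))), drop = FALSE]
  }
  res
}

# SVD of the pixel correlation matrix computed from the traces themselves:
# with Z the row-standardized traces (so C = Z Z'), the eigenvalues of the
# small T x T Gram matrix Z'Z are the singular values of C and the spatial
# patterns are U = Z V / sqrt(lambda). Avoids materializing C.
svd_patterns_traces <- function(tm, k = 20) {
  z <- standardize_rows(tm$traces)
  if (anyNA(z))
    stop_fcois("constant pixel traces present; cannot decompose",
               class = "fcois_input_error")
  g <- crossprod(z)                     # T x T
  e <- eigen(g, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12
  values <- e$values[pos]
  k <- min(k, length(values))
  u <- z %*% e$vectors[, seq_len(k), drop = FALSE]
  u <- sweep(u, 2, sqrt(values[seq_len(k)]), "/")
  res <- new_svd_result(values, u, sum(values))
  res$signs <- rep(1, length(values))
  res
}

#' @export
print.svd_result <- function(x, ...) {
  cat(sprintf("<svd_result> %d singular values; f(1)=%.3f f(4)=%.3f f(10)=%.3f\n",
              length(x$d), x$variance_fraction[1],
              x$variance_fraction[min(4, length(x$d))],
              x$variance_fraction[min(10, length(x$d))]))
  invisible(x)
}

#' Spatial correlation between two correlation maps
#'
#' Pearson correlation over in-mask pixels, the standard split-half
#' reliability measure for seed maps computed from consecutive halves of
#' a recording.
#'
#' @param map_a,map_b `corr_map` objects on the same mask.
#' @return Pearson r.
#' @export
split_half_spatial_correlation <- function(map_a, map_b) {
  in_a <- !is.na(unclass(map_a))
  in_b <- !is.na(unclass(map_b))
  if (!identical(dim(map_a), dim(map_b)) || !identical(in_a, in_b))
    stop_fcois("maps are not on the same mask", class = "fcois_input_error")
  stats::cor(unclass(map_a)[in_a], unclass(map_b)[in_b])
}
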