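#' Plot a correlation map
#'
#' Image of seed correlation values on the brain, blue-white-red from
#' r = -1 to 1, gray outside the mask.
#'
#' @param x a `corr_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.corr_map <- function(x, ...) {
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  img <- t(unclass(x))[, nrow(x):1, drop = FALSE]
  graphics::image(img, zlim = c(-1, 1), col = pal, axes = FALSE,
                  asp = nrow(x) / ncol(x),
                  main = attr(x, "seed") %||% "correlation map", ...)
  invisible(x)
}

#' Plot a label map
#'
#' @param x a `label_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.label_map <- function(x, ...) {
  v <- unclass(x)
  k <- max(1L, max(v, na.rm = TRUE))
  pal <- c("gray85", grDevices::hcl.colors(k, "Spectral"))
  img <- t(v)[, nrow(v):1, drop = FALSE]
  graphics::image(img, zlim = c(0, k), col = pal, axes = FALSE,
                  asp = nrow(x) / ncol(x), ...)
  invisible(x)
}

#' Plot a parcel linkage tree
#'
#' Dendrogram with merge heights on the 1 - r scale.
#'
#' @param x a `linkage_tree`.
#' @param ... passed to [plot.hclust][stats::hclust()].
#' @export
plot.linkage_tree <- function(x, ...) {
  plot(x$hclust, ylab = "1 - r", xlab = "parcel", sub = "", main = "", ...)
  invisible(x)
}

#' Plot a power spectrum
#'
#' Log-log periodogram, the standard QC view for resting-state traces
#' (physiological peaks near 2.5 and 10 Hz are visible before filtering
#' and absent after).
#'
#' @param spec data frame from [power_spectrum()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_power_spectrum <- function(spec, ...) {
  keep <- spec$frequency > 0 & spec$power > 0
  graphics::plot(spec$frequency[keep], spec$power[keep], type = "l",
                 log = "xy", xlab = "frequency (Hz)", ylab = "power", ...)
  invisible(spec)
}

#' Border statistics as a tidy table
#'
#' @param x result of [border_uncertainty()].
#' @return data frame with one row per border plus an overall row.
#' @export
tidy_border_uncertainty <- function(x) {
  rbind(data.frame(border = "overall", n = x$overall[["n"]],
                   median_um = x$overall[["median_um"]],
                   p95_um = x$overall[["p95_um"]]),
        x$per_border)
}
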