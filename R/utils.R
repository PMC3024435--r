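#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Pixel coordinates are 1-based
# (row, col); physical positions refer to pixel centers.

stop_fcois <- function(..., class = "fcois_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

#' Pixel index table for a mask
#'
#' Returns the (row, col) coordinates of all `TRUE` pixels of a mask in
#' column-major order, the order in which trace matrices store pixels.
#'
#' @param mask logical matrix.
#' @return data frame with integer columns `row` and `col`.
#' @export
mask_pixels <- function(mask) {
  idx <- which(mask)
  data.frame(row = ((idx - 1L) %% nrow(mask)) + 1L,
             col = ((idx - 1L) %/% nrow(mask)) + 1L)
}

# Row-standardize a pixels x time matrix so that tcrossprod() gives the
# Pearson correlation matrix. Rows with zero variance become NaN rows.
standardize_rows <- function(x) {
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- NaN
  x / nrm
}

clamp_correlation <- function(r) {
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

# Deterministic fingerprint of an integer label vector, for cycle detection.
label_key <- function(labels) paste(labels, collapse = ",")
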