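#' Label map
#'
#' Per-pixel parcel assignment on the image grid: `NA` outside the brain
#' mask, `0` for in-mask pixels not (yet) assigned, positive integers for
#' parcels.
#'
#' @param labels integer matrix (or vector over mask pixels together with
#'   `pixels`/`dim`).
#' @param pixels optional pixel map when `labels` is a vector.
#' @param dim grid dimensions when `labels` is a vector.
#' @param n_slots number of label slots defined by the initialization
#'   (empty slots allowed).
#' @param names optional character vector naming the label ids.
#' @param pixel_pitch_um pixel size in micrometers.
#' @return object of class `label_map`.
#' @export
label_map <- function(labels, pixels = NULL, dim = NULL, n_slots = NULL,
                      names = NULL, pixel_pitch_um = 80) {
  if (!is.matrix(labels)) {
    img <- matrix(NA_integer_, dim[1], dim[2])
    img[cbind(pixels$row, pixels$col)] <- as.integer(labels)
    labels <- img
  }
  structure(labels,
            n_slots = n_slots %||% max(0L, labels, na.rm = TRUE),
            label_names = names, pixel_pitch_um = pixel_pitch_um,
            class = c("label_map", "matrix", "array"))
}

#' @export
print.label_map <- function(x, ...) {
  v <- x[!is.na(x)]
  cat(sprintf("<label_map> %dx%d grid, %d parcels, %d/%d pixels assigned\n",
              nrow(x), ncol(x), length(unique(v[v > 0])),
              sum(v > 0), length(v)))
  invisible(x)
}

#' Label vector over a set of pixels
#'
#' Looks up the parcel label of each pixel of a pixel map (e.g.
#' `tm$pixels` of a [trace_matrix()]), in order.
#'
#' @param lm a [label_map()].
#' @param pixels data frame with `row`, `col` columns.
#' @return integer vector of labels.
#' @export
labels_for_pixels <- function(lm, pixels) {
  as.integer(unclass(lm)[cbind(pixels$row, pixels$col)])
}

#' Parcel initialization from singular vectors
#'
#' Each pixel is assigned to the singular vector with the largest absolute
#' coefficient at that pixel; each of the `k` groups is then split by
#' coefficient sign, defining `2k` label slots (vector `j` gives slots
#' `2j-1` for positive and `2j` for negative coefficients). Slots left
#' empty are reported with a warning but remain defined.
#'
#' @param svd an `svd_result` whose `u` has one row per mask pixel.
#' @param tm the [trace_matrix()] the decomposition was computed from
#'   (supplies the pixel map).
#' @param k number of leading singular vectors (default 10, giving 20
#'   slots).
#' @return a [label_map()] with `n_slots = 2k`.
#' @export
init_from_svd <- function(svd, tm, k = 10) {
  if (!is_count(k)) stop_fcois("k must be a positive integer",
                               class = "fcois_input_error")
  if (ncol(svd$u) < k)
    stop_fcois(sprintf("decomposition has %d < %d components", ncol(svd$u), k),
               class = "fcois_input_error")
  u <- svd$u[, seq_len(k), drop = FALSE]
  comp <- max.col(abs(u), ties.method = "first")
  coef <- u[cbind(seq_len(nrow(u)), comp)]
  lab <- 2L * (comp - 1L) + ifelse(coef >= 0, 1L, 2L)
  empty <- setdiff(seq_len(2L * k), unique(lab))
  if (length(empty) > 0)
    warning(sprintf("%d of %d label slots are empty", length(empty), 2L * k))
  label_map(lab, tm$pixels, tm$mask_dim, n_slots = 2L * k,
            pixel_pitch_um = tm$pixel_pitch_um)
}

#' Parcel initialization from a seed catalogue
#'
#' Seed-disc pixels receive the seed's label; all other in-mask pixels
#' start unassigned and are captured by the first assignment pass of
#' [iterate_parcellation()]. Pixels covered by overlapping discs take the
#' earlier-listed seed's label (a message reports the ties).
#'
#' @param seeds seed catalogue data frame (>= 2 seeds).
#' @param mask a `brain_mask`.
#' @return a [label_map()] with one slot per seed.
#' @export
init_from_seeds <- function(seeds, mask) {
  if (nrow(seeds) < 2)
    stop_fcois("need at least two seeds", class = "fcois_input_error")
  img <- matrix(NA_integer_, nrow(mask), ncol(mask))
  img[unclass(mask)] <- 0L
  overlaps <- 0L
  for (i in seq_len(nrow(seeds))) {
    px <- seed_mask(seeds[i, ], mask)
    cur <- img[cbind(px$row, px$col)]
    overlaps <- overlaps + sum(cur > 0, na.rm = TRUE)
    free <- which(cur == 0)
    img[cbind(px$row, px$col)[free, , drop = FALSE]] <- i
  }
  if (overlaps > 0)
    message(sprintf("%d overlapping disc pixel(s) kept their earlier label",
                    overlaps))
  label_map(img, n_slots = nrow(seeds), names = seeds$name,
            pixel_pitch_um = attr(mask, "pixel_pitch_um") %||% 80)
}

#' Parcel initialization from a square tiling
#'
#' Divides the grid into `tile` x `tile` squares (partial squares at the
#' edges included), intersects them with the mask and drops empty tiles.
#'
#' @param mask a `brain_mask`.
#' @param tile tile side in pixels (default 25).
#' @return a [label_map()] with contiguous tile labels.
#' @export
init_from_tiling <- function(mask, tile = 25) {
  if (!is_count(tile)) stop_fcois("tile must be a positive integer",
                                  class = "fcois_input_error")
  nr <- nrow(mask); nc <- ncol(mask)
  tr <- (seq_len(nr) - 1L) %/% tile
  tc <- (seq_len(nc) - 1L) %/% tile
  raw <- outer(tr, tc, function(a, b) a * (max(tc) + 1L) + b + 1L)
  img <- matrix(NA_integer_, nr, nc)
  img[unclass(mask)] <- raw[unclass(mask)]
  present <- sort(unique(img[!is.na(img)]))
  img[] <- match(img, present)
  label_map(img, n_slots = length(present),
            pixel_pitch_um = attr(mask, "pixel_pitch_um") %||% 80)
}

#' Iterative winner-take-all parcellation
#'
#' Alternates two steps until a fixed point: (1) each parcel's time trace
#' is the mean over its member pixels; (2) every in-mask pixel is assigned
#' to the parcel whose trace it correlates with most strongly (ties broken
#' toward the lowest parcel id, so reruns are deterministic). After each
#' assignment, parcels smaller than `min_size` pixels are eliminated and
#' their pixels reassigned on the next pass — this prevents degenerate
#' single-pixel parcels, which would trivially win their own pixel.
#' Iteration stops when no pixel changes parcel, when a previously seen
#' label configuration recurs (a cycle), or at `max_iter`.
#'
#' @param tm a [trace_matrix()] (typically after [preprocess_traces()]).
#' @param init a [label_map()] from one of the `init_from_*()` functions.
#' @param min_size minimum parcel size in pixels (default 10).
#' @param max_iter iteration cap.
#' @return list with `labels` (a [label_map()] with contiguous ids),
#'   `converged`, `iterations`, and `history` (per-iteration pixel change
#'   and parcel counts).
#' @export
iterate_parcellation <- function(tm, init, min_size = 10, max_iter = 100) {
  z <- standardize_rows(tm$traces)
  if (anyNA(z))
    stop_fcois("constant pixel traces cannot be parcellated",
               class = "fcois_input_error")
  lab <- labels_for_pixels(init, tm$pixels)
  if (anyNA(lab))
    stop_fcois("initialization does not cover the trace matrix mask",
               class = "fcois_input_error")
  ids <- seq_len(attr(init, "n_slots"))
  # drop empty and undersized initial parcels just as after an assignment
  sizes <- tabulate(lab, nbins = max(ids))
  active <- ids[sizes[ids] >= min_size]
  if (length(active) == 0)
    stop_fcois("no parcel meets the minimum size", class = "fcois_degenerate_error")
  seen_keys <- character()
  history <- list()
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # step 1: parcel traces = mean over member pixels (active parcels only)
    centers <- vapply(active, function(j) {
      rows <- which(lab == j)
      colMeans(tm$traces[rows, , drop = FALSE])
    }, numeric(ncol(tm$traces)))          # T x P
    zc <- centers - rep(colMeans(centers), each = nrow(centers))
    nrm <- sqrt(colSums(zc^2))
    if (any(nrm == 0))
      stop_fcois("a parcel has a constant mean trace",
                 class = "fcois_degenerate_error")
    zc <- sweep(zc, 2, nrm, "/")
    # step 2: winner-take-all assignment, ties to the lowest parcel id
    r <- z %*% zc                          # N x P correlations
    new_lab <- active[max.col(r, ties.method = "first")]
    changed <- sum(new_lab != lab)
    lab <- new_lab
    # prune undersized parcels; their pixels reassign next pass
    sizes <- tabulate(lab, nbins = max(ids))
    pruned <- active[sizes[active] < min_size]
    active <- active[sizes[active] >= min_size]
    if (length(active) == 0)
      stop_fcois("all parcels pruned", class = "fcois_degenerate_error")
    history[[it]] <- list(changed = changed, n_parcels = length(active),
                          pruned = pruned)
    if (changed == 0 && length(pruned) == 0) { converged <- TRUE; break }
    key <- label_key(lab)
    if (key %in% seen_keys) break         # cycle detected
    seen_keys <- c(seen_keys, key)
  }
  if (!converged && it >= max_iter)
    warning("parcellation did not converge within max_iter")
  # contiguous ids in order of original slots
  final_ids <- sort(unique(lab[lab %in% active]))
  relab <- match(lab, final_ids)
  relab[is.na(relab)] <- 0L               # pixels of parcels pruned at stop
  out <- label_map(relab, tm$pixels, tm$mask_dim, n_slots = length(final_ids),
                   pixel_pitch_um = tm$pixel_pitch_um)
  attr(out, "source_slots") <- final_ids
  list(labels = out, converged = converged, iterations = it,
       history = history)
}

#' Parcel-to-parcel correlation matrix
#'
#' Pearson correlation between the mean time traces of every pair of
#' parcels of a converged parcellation.
#'
#' @param tm a [trace_matrix()].
#' @param labels a [label_map()].
#' @return `corr_matrix` with one row per parcel (dimnames carry parcel
#'   ids); parcels with constant traces give `NaN` rows with a warning.
#' @export
parcel_correlation_matrix <- function(tm, labels) {
  lab <- labels_for_pixels(labels, tm$pixels)
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0)
    stop_fcois("no parcels in label map", class = "fcois_input_error")
  centers <- vapply(ids, function(j)
    colMeans(tm$traces[lab == j, , drop = FALSE]),
    numeric(ncol(tm$traces)))
  r <- clamp_correlation(stats::cor(centers))
  if (anyNA(r)) warning("parcel(s) with constant traces produced NaN rows")
  diag(r) <- ifelse(is.na(diag(r)), NA_real_, 1)
  dimnames(r) <- list(ids, ids)
  structure(r, class = c("corr_matrix", "matrix", "array"))
}

#' Hierarchical clustering of parcels
#'
#' Agglomerative clustering of parcels with distance `1 - r` between
#' parcel traces, so perfectly correlated parcels merge at height 0 and
#' perfectly anticorrelated ones at height 2. Single linkage by default
#' (configurable to average or complete).
#'
#' @param pmat parcel `corr_matrix` from [parcel_correlation_matrix()].
#' @param method linkage method passed to [stats::hclust()].
#' @return object of class `linkage_tree` wrapping the `hclust` result.
#' @export
cluster_parcels <- function(pmat, method = c("single", "average", "complete")) {
  method <- match.arg(method)
  if (nrow(pmat) < 2)
    stop_fcois("need at least two parcels", class = "fcois_input_error")
  if (anyNA(pmat)) {
    bad <- rownames(pmat)[apply(is.na(unclass(pmat)), 1, any)]
    stop_fcois("non-finite distances for parcel(s) ",
               paste(bad, collapse = ", "), class = "fcois_input_error")
  }
  d <- stats::as.dist(1 - unclass(pmat))
  hc <- stats::hclust(d, method = method)
  structure(list(hclust = hc, parcels = rownames(pmat), method = method),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> %d parcels, %s linkage, heights [%.3f, %.3f]\n",
              length(x$parcels), x$method,
              min(x$hclust$height), max(x$hclust$height)))
  invisible(x)
}

#' Cut a parcel tree into networks
#'
#' @param tree a `linkage_tree`.
#' @param k number of clusters, or
#' @param h height (`1 - r`) at which to cut.
#' @return integer vector of network memberships named by parcel id.
#' @export
cut_parcel_tree <- function(tree, k = NULL, h = NULL) {
  stats::cutree(tree$hclust, k = k, h = h)
}

#' Export a parcel tree as Newick
#'
#' @param tree a `linkage_tree`.
#' @param path output file.
#' @export
write_parcel_tree_newick <- function(tree, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop_fcois("Newick export requires the 'ape' package",
               class = "fcois_config_error")
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

# Border elements of a label map: the midpoints between differently
# labeled in-mask 4-neighbors ("cracks"), with the adjacent label pair.
# Representing borders between pixels (rather than by pixels on either
# side) makes border displacement symmetric: shifting a straight border
# by one pixel moves every crack by exactly one pixel pitch.
border_cracks <- function(lm) {
  x <- unclass(lm)
  nr <- nrow(x); nc <- ncol(x)
  out <- list()
  # vertical neighbors (r, c) vs (r + 1, c)
  a <- x[-nr, , drop = FALSE]; b <- x[-1, , drop = FALSE]
  hit <- which(!is.na(a) & !is.na(b) & a != b, arr.ind = TRUE)
  if (nrow(hit) > 0)
    out[[1]] <- cbind(row = hit[, 1] + 0.5, col = hit[, 2],
                      lab1 = pmin(a[hit], b[hit]), lab2 = pmax(a[hit], b[hit]))
  # horizontal neighbors (r, c) vs (r, c + 1)
  a <- x[, -nc, drop = FALSE]; b <- x[, -1, drop = FALSE]
  hit <- which(!is.na(a) & !is.na(b) & a != b, arr.ind = TRUE)
  if (nrow(hit) > 0)
    out[[2]] <- cbind(row = hit[, 1], col = hit[, 2] + 0.5,
                      lab1 = pmin(a[hit], b[hit]), lab2 = pmax(a[hit], b[hit]))
  do.call(rbind, out)
}

#' Border displacement between two parcellations
#'
#' Borders are represented by the midpoints between differently labeled
#' 4-neighbor pixels. For every border element of parcellation A, the
#' Euclidean distance to the nearest border element of parcellation B is
#' computed in micrometers, and summarized overall and per border (per
#' pair of adjacent labels in A) by the median and 95th percentile. This
#' quantifies how far functional borders move between two parcellations
#' of the same brain, e.g. from split halves of a session.
#'
#' @param labels_a,labels_b [label_map()]s on the same grid.
#' @param pixel_pitch_um pixel size; defaults to the maps'.
#' @return list with `overall` (named vector: n, median_um, p95_um) and
#'   `per_border` (data frame keyed by the adjacent label pair in A).
#' @export
border_uncertainty <- function(labels_a, labels_b, pixel_pitch_um = NULL) {
  if (!identical(dim(labels_a), dim(labels_b)))
    stop_fcois("label maps are on different grids", class = "fcois_input_error")
  pitch <- pixel_pitch_um %||% attr(labels_a, "pixel_pitch_um") %||% 80
  ba <- border_cracks(labels_a)
  bb <- border_cracks(labels_b)
  if (is.null(ba) || is.null(bb))
    stop_fcois("a parcellation has no internal borders",
               class = "fcois_input_error")
  nn <- vapply(seq_len(nrow(ba)), function(i) {
    min((bb[, "row"] - ba[i, "row"])^2 + (bb[, "col"] - ba[i, "col"])^2)
  }, numeric(1))
  dist_um <- sqrt(nn) * pitch
  key <- paste(ba[, "lab1"], ba[, "lab2"], sep = "-")
  per <- do.call(rbind, lapply(split(dist_um, key), function(v) {
    data.frame(n = length(v), median_um = stats::median(v),
               p95_um = stats::quantile(v, 0.95, names = FALSE))
  }))
  per <- cbind(border = rownames(per), per)
  rownames(per) <- NULL
  list(overall = c(n = length(dist_um),
                   median_um = stats::median(dist_um),
                   p95_um = stats::quantile(dist_um, 0.95, names = FALSE)),
       per_border = per)
}
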