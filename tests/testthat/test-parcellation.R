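test_that("SVD initialization assigns by largest |coefficient| and sign", {
  # 4-pixel toy with known vectors: exhaustive hand table
  u <- rbind(c(0.9, 0.1),
             c(-0.8, 0.3),
             c(0.2, 0.6),
             c(0.1, -0.7))
  svd <- structure(list(d = c(2, 1), u = u,
                        variance_fraction = c(2 / 3, 1), total = 3),
                   class = "svd_result")
  tm <- trace_matrix(matrix(rnorm(8), 4, 2), 1,
                     data.frame(row = 1:4, col = 1))
  lm <- suppressWarnings(init_from_svd(svd, tm, k = 2))
  # slots: vec1+ = 1, vec1- = 2, vec2+ = 3, vec2- = 4
  expect_equal(labels_for_pixels(lm, tm$pixels), c(1, 2, 3, 4))
  expect_equal(attr(lm, "n_slots"), 4)
  expect_error(init_from_svd(svd, tm, k = 0), class = "fcois_input_error")
  # k = 10 defines 20 slots by construction
  sim <- small_phantom()
  s <- svd_patterns(sim$tm, k = 10)
  lm10 <- suppressWarnings(init_from_svd(s, sim$tm, k = 10))
  expect_equal(attr(lm10, "n_slots"), 20)
})

test_that("seed initialization labels discs and leaves the rest unassigned", {
  sim <- small_phantom()
  seeds <- scaled_seeds()
  lm <- init_from_seeds(seeds, sim$mask)
  expect_equal(attr(lm, "n_slots"), 16)
  lab <- labels_for_pixels(lm, sim$tm$pixels)
  expect_true(any(lab == 0))                       # unassigned pixels exist
  expect_setequal(setdiff(unique(lab), 0), 1:16)   # sixteen seed labels
  # overlap: shared pixels take the earlier-listed label
  two <- data.frame(name = c("a", "b"), row = c(30, 30), col = c(30, 32),
                    diameter_mm = c(0.5, 0.5))
  expect_message(lm2 <- init_from_seeds(two, sim$mask), "overlapping")
  shared <- intersect(
    do.call(paste, seed_mask(two[1, ], sim$mask)),
    do.call(paste, seed_mask(two[2, ], sim$mask)))
  expect_gt(length(shared), 0)
  img <- unclass(lm2)
  for (p in shared) {
    rc <- as.integer(strsplit(p, " ")[[1]])
    expect_equal(img[rc[1], rc[2]], 1L)
  }
})

test_that("tiling initialization enumerates mask-intersected squares", {
  # full 128 mask, 25 px tiles: ceiling(128/25)^2 = 36 tiles with partials
  full <- brain_mask(matrix(TRUE, 128, 128), 80)
  lm <- init_from_tiling(full, 25)
  expect_equal(attr(lm, "n_slots"), 36)
  # toy 10x10 mask with a corner cut: enumeration oracle
  m <- matrix(TRUE, 10, 10); m[1:5, 1:5] <- FALSE
  lm2 <- init_from_tiling(brain_mask(m, 80), 5)
  expect_equal(attr(lm2, "n_slots"), 3)            # empty tile removed
  img <- unclass(lm2)
  expect_true(all(is.na(img[1:5, 1:5])))
  expect_equal(length(unique(img[!is.na(img)])), 3)
})

test_that("iteration recovers planted blocks and prunes small parcels", {
  # noise-free 2-block toy: 12 pixels, two latent traces
  set.seed(21)
  l1 <- rnorm(60); l2 <- rnorm(60)
  traces <- rbind(matrix(rep(l1, each = 6), 6),
                  matrix(rep(l2, each = 6), 6))
  tm <- trace_matrix(traces, 1, data.frame(row = 1:12, col = 1))
  # an arbitrary unbalanced split (a perfectly balanced split is the one
  # degenerate init: both parcel means coincide and all pixels tie)
  init <- label_map(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 1L, 1L),
                    tm$pixels, c(12, 1), n_slots = 2)
  res <- iterate_parcellation(tm, init, min_size = 3)
  expect_true(res$converged)
  lab <- labels_for_pixels(res$labels, tm$pixels)
  expect_equal(mclust::adjustedRandIndex(lab, rep(1:2, each = 6)), 1)
  # converged output is a fixed point: one more pass changes nothing
  again <- iterate_parcellation(tm, res$labels, min_size = 3)
  expect_equal(again$iterations, 1)
  expect_identical(labels_for_pixels(again$labels, tm$pixels), lab)
  # a parcel seeded too small is eliminated and absorbed
  init_bad <- label_map(c(rep(1L, 6), rep(2L, 5), 3L), tm$pixels,
                        c(12, 1), n_slots = 3)
  res2 <- iterate_parcellation(tm, init_bad, min_size = 3)
  lab2 <- labels_for_pixels(res2$labels, tm$pixels)
  expect_equal(length(unique(lab2)), 2)
  expect_equal(mclust::adjustedRandIndex(lab2, rep(1:2, each = 6)), 1)
  # all parcels pruned is a degenerate error
  expect_error(iterate_parcellation(tm, init, min_size = 13),
               class = "fcois_degenerate_error")
})

test_that("no converged parcel is below the minimum size", {
  sim <- small_phantom()
  res <- iterate_parcellation(sim$tm, init_from_tiling(sim$mask, 13))
  lab <- labels_for_pixels(res$labels, sim$tm$pixels)
  expect_true(res$converged)
  expect_true(all(table(lab[lab > 0]) >= 10))
  # contiguous ids after pruning
  expect_equal(sort(unique(lab[lab > 0])),
               seq_len(attr(res$labels, "n_slots")))
})

test_that("parcel correlation matrices match the brute-force loop", {
  set.seed(5)
  traces <- matrix(rnorm(8 * 50), 8, 50)
  traces[5:6, ] <- traces[1:2, ]                # parcels 1 and 3 identical
  tm <- trace_matrix(traces, 1, data.frame(row = 1:8, col = 1))
  lm <- label_map(rep(1:4, each = 2), tm$pixels, c(8, 1), n_slots = 4)
  pm <- parcel_correlation_matrix(tm, lm)
  expect_equal(dim(pm), c(4, 4))
  expect_equal(unname(diag(pm)), rep(1, 4))
  expect_equal(pm[1, 3], 1)
  means <- rbind(colMeans(traces[1:2, ]), colMeans(traces[3:4, ]),
                 colMeans(traces[5:6, ]), colMeans(traces[7:8, ]))
  for (i in 1:4) for (j in 1:4)
    expect_equal(pm[i, j], pearson_loop(means[i, ], means[j, ]),
                 tolerance = 1e-12)
  # single parcel: 1x1 matrix
  lm1 <- label_map(rep(1L, 8), tm$pixels, c(8, 1), n_slots = 1)
  expect_equal(unname(unclass(parcel_correlation_matrix(tm, lm1))),
               matrix(1, 1, 1))
})

test_that("parcel clustering uses 1 - r heights and matches the oracle", {
  as_pm <- function(r) structure(r, dimnames = list(seq_len(nrow(r)),
                                                    seq_len(nrow(r))),
                                 class = c("corr_matrix", "matrix", "array"))
  # perfectly correlated pair merges at 0, anticorrelated pair at 2
  expect_equal(cluster_parcels(as_pm(matrix(1, 2, 2)))$hclust$height, 0)
  expect_equal(cluster_parcels(as_pm(rbind(c(1, -1),
                                           c(-1, 1))))$hclust$height, 2)
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- 1
  r[3, 4] <- r[4, 3] <- -1
  r[1, 3] <- r[3, 1] <- r[1, 4] <- r[4, 1] <- 0.5
  r[2, 3] <- r[3, 2] <- r[2, 4] <- r[4, 2] <- 0.5
  tree <- cluster_parcels(as_pm(r))
  expect_equal(sort(tree$hclust$height),
               sort(single_linkage_heights(1 - r)))
  expect_true(all(tree$hclust$height >= 0 & tree$hclust$height <= 2))
  # random toy against the exhaustive single-linkage oracle
  set.seed(3)
  x <- matrix(rnorm(6 * 30), 6, 30)
  rr <- cor(t(x))
  pm2 <- structure(rr, dimnames = list(1:6, 1:6),
                   class = c("corr_matrix", "matrix", "array"))
  tree2 <- cluster_parcels(pm2)
  expect_equal(tree2$hclust$height, single_linkage_heights(1 - rr),
               tolerance = 1e-12)
  # leaf count equals parcel count; cutting works by k and height
  expect_length(tree2$parcels, 6)
  expect_equal(max(cut_parcel_tree(tree2, k = 3)), 3)
  na <- pm2; na[1, 2] <- na[2, 1] <- NA
  expect_error(cluster_parcels(na), class = "fcois_input_error")
})

test_that("border displacement is zero for identical maps, one pitch for a shift", {
  img <- matrix(1L, 20, 20)
  img[11:20, ] <- 2L
  a <- label_map(img, pixel_pitch_um = 80)
  expect_equal(unname(border_uncertainty(a, a)$overall[["median_um"]]), 0)
  img2 <- matrix(1L, 20, 20)
  img2[12:20, ] <- 2L                     # border shifted one pixel
  b <- label_map(img2, pixel_pitch_um = 80)
  bu <- border_uncertainty(a, b)
  expect_equal(unname(bu$overall[["median_um"]]), 80)
  expect_equal(unname(bu$overall[["p95_um"]]), 80)
  # orthogonal stripes: distances finite and below the grid diagonal
  img3 <- matrix(rep(rep(1:2, each = 10), 20), 20, 20)   # vertical split
  cval <- border_uncertainty(a, label_map(img3, pixel_pitch_um = 80))
  expect_true(all(is.finite(cval$overall)))
  expect_lt(cval$overall[["p95_um"]], 80 * sqrt(2) * 20)
  # single-parcel map has no borders
  expect_error(border_uncertainty(a, label_map(matrix(1L, 20, 20),
                                               pixel_pitch_um = 80)),
               class = "fcois_input_error")
})
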