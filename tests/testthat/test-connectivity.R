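test_that("seed discs contain the lattice points within the radius", {
  mask <- brain_mask(matrix(TRUE, 20, 20), 80)
  # 0.5 mm at 80 um pitch: radius 3.125 px; lattice-counting oracle
  px <- seed_mask(list(row = 10, col = 10, diameter_mm = 0.5), mask)
  oracle <- 0
  for (dr in -4:4) for (dc in -4:4)
    if (dr^2 + dc^2 <= 3.125^2) oracle <- oracle + 1
  expect_equal(nrow(px), oracle)
  expect_equal(nrow(px), 29)            # approximately 30 pixels
  # sub-pitch diameter: exactly the center pixel
  one <- seed_mask(list(row = 5, col = 5, diameter_mm = 0.05), mask)
  expect_equal(unlist(one, use.names = FALSE), c(5, 5))
  # disc clipped by the mask keeps only in-mask pixels
  m2 <- matrix(TRUE, 20, 20); m2[, 10:20] <- FALSE
  clipped <- seed_mask(list(row = 10, col = 9, diameter_mm = 0.5),
                       brain_mask(m2, 80))
  expect_true(all(clipped$col <= 9))
  expect_error(seed_mask(list(row = 10, col = 15, diameter_mm = 0.2),
                         brain_mask(m2, 80)), class = "fcois_seed_error")
})

test_that("seed traces average member pixels", {
  tm <- trace_matrix(rbind(c(1, 3), c(3, 5)), 1,
                     data.frame(row = c(1, 3), col = c(3, 5)))
  expect_equal(seed_trace(tm, data.frame(row = c(1, 3), col = c(3, 5))),
               c(2, 4))
  expect_equal(seed_trace(tm, data.frame(row = 1, col = 3)), c(1, 3))
  expect_error(seed_trace(tm, data.frame(row = integer(), col = integer())),
               class = "fcois_seed_error")
})

test_that("correlation maps are Pearson r against every pixel", {
  set.seed(4)
  n <- 900
  seed_tr <- rnorm(n)
  rho <- 0.9
  corr_px <- rho * seed_tr + sqrt(1 - rho^2) * rnorm(n)
  traces <- rbind(seed_tr, -seed_tr, corr_px, rnorm(n))
  tm <- trace_matrix(traces, 1, data.frame(row = 1:4, col = 1))
  m <- correlation_map(tm, seed_tr)
  vals <- unclass(m)[cbind(1:4, 1)]
  expect_equal(vals[1], 1)
  expect_equal(vals[2], -1)
  # planted correlation recovered within the Fisher-z sampling bound,
  # and equal to the brute-force loop oracle
  expect_equal(vals[3], rho, tolerance = 0.03 / rho)
  expect_equal(vals[3], pearson_loop(corr_px, seed_tr), tolerance = 1e-12)
  expect_true(all(vals >= -1 & vals <= 1))
  expect_error(correlation_map(tm, rep(1, n)), class = "fcois_seed_error")
  # constant pixels flag NaN with a warning
  tm$traces[4, ] <- 2
  expect_warning(m2 <- correlation_map(tm, seed_tr), "constant")
  expect_true(is.na(unclass(m2)[4, 1]))
})

test_that("the full correlation matrix matches the pairwise loop oracle", {
  set.seed(9)
  traces <- matrix(rnorm(5 * 40), 5, 40)
  traces[2, ] <- traces[1, ]                  # two identical pixels
  tm <- trace_matrix(traces, 1, data.frame(row = 1:5, col = 1))
  cm <- full_correlation_matrix(tm)
  expect_equal(unname(diag(cm)), rep(1, 5))
  expect_equal(unclass(cm), t(unclass(cm)))
  expect_equal(cm[1, 2], 1)
  for (i in 1:5) for (j in 1:5)
    expect_equal(cm[i, j], pearson_loop(traces[i, ], traces[j, ]),
                 tolerance = 1e-12)
  # row i equals the map with pixel i as a single-pixel seed
  m1 <- correlation_map(tm, traces[3, ])
  expect_equal(unname(cm[3, ]), unclass(m1)[cbind(1:5, 1)])
  expect_error(full_correlation_matrix(tm, max_pixels = 3),
               class = "fcois_memory_guard")
})

test_that("singular value patterns satisfy the decomposition contract", {
  # identity matrix: all singular values equal, f(4) = 0.4
  s <- svd_patterns(structure(diag(10), class = c("corr_matrix", "matrix", "array")))
  expect_equal(s$d, rep(1, 10))
  expect_equal(s$variance_fraction[4], 0.4)
  # rank-1 matrix: f(1) = 1
  v <- rnorm(8); v <- v / sqrt(sum(v^2))
  s1 <- svd_patterns(v %*% t(v))
  expect_equal(s1$variance_fraction[1], 1, tolerance = 1e-12)
  # two-block toy: two dominant components against the eigen oracle
  blk <- matrix(0.02, 12, 12)
  blk[1:6, 1:6] <- 0.95; blk[7:12, 7:12] <- 0.95
  diag(blk) <- 1
  s2 <- svd_patterns(blk)
  expect_gte(s2$variance_fraction[2], 0.95)
  expect_equal(s2$d, sort(abs(eigen(blk, symmetric = TRUE)$values),
                          decreasing = TRUE))
  # orthonormality, monotone fractions, exact reconstruction
  expect_lt(max(abs(crossprod(s2$u) - diag(12))), 1e-8)
  expect_true(all(diff(s2$variance_fraction) >= -1e-12))
  expect_equal(s2$variance_fraction[12], 1)
  recon <- s2$u %*% diag(s2$d * s2$signs) %*% t(s2$u)
  expect_lt(max(abs(recon - blk)), 1e-8)
  expect_error(svd_patterns(matrix(rnorm(16), 4, 4)),
               class = "fcois_input_error")
})

test_that("trace-based decomposition agrees with the matrix route", {
  sim <- small_phantom()
  tm <- sim$tm
  keep <- seq(1, nrow(tm$traces), by = 4)
  sub <- tm
  sub$traces <- tm$traces[keep, , drop = FALSE]
  sub$pixels <- tm$pixels[keep, , drop = FALSE]
  cm <- full_correlation_matrix(sub)
  s_mat <- svd_patterns(cm)
  s_tr <- svd_patterns(sub, k = 10)
  nz <- seq_along(s_tr$d)
  expect_equal(s_tr$d, s_mat$d[nz], tolerance = 1e-6)
  expect_equal(s_tr$variance_fraction[10], s_mat$variance_fraction[10],
               tolerance = 1e-6)
  # spatial patterns match up to sign
  for (k in 1:5)
    expect_equal(abs(sum(s_tr$u[, k] * s_mat$u[, k])), 1, tolerance = 1e-6)
})

test_that("split-half spatial correlation behaves like Pearson r", {
  sim <- small_phantom()
  seeds <- scaled_seeds()
  m <- correlation_map(sim$tm, seed_trace(sim$tm,
                                          seed_mask(seeds[3, ], sim$mask)))
  expect_equal(split_half_spatial_correlation(m, m), 1)
  neg <- m; neg[] <- -unclass(m)
  expect_equal(split_half_spatial_correlation(m, neg), -1)
  other <- m
  other[32, ] <- NA                       # knock out an in-mask row
  expect_error(split_half_spatial_correlation(m, other),
               class = "fcois_input_error")
})
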