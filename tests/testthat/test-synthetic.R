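test_that("phantom geometry is a symmetric partition of the mask", {
  cfg <- phantom_config(grid = 64)
  geom <- make_phantom_geometry(cfg)
  m <- matrix(as.vector(unclass(geom$mask)), nrow(geom$mask))
  # mask symmetric under left-right flip
  expect_identical(m, m[, ncol(m):1])
  # every in-mask pixel belongs to exactly one region
  img <- unclass(geom$truth)
  expect_true(all(img[m] > 0))
  expect_true(all(is.na(img[!m])))
  expect_equal(attr(geom$truth, "n_slots"), 12)
  # region pixel counts match an explicit rasterization loop
  ctr <- (64 + 1) / 2; a <- 0.455 * 64; b <- 0.355 * 64
  counts <- integer(12)
  for (r in 1:64) for (c in 1:64) {
    if (((r - ctr) / a)^2 + ((c - ctr) / b)^2 <= 1) {
      band <- min(6, max(1, 1 + floor((r - (ctr - a)) / (2 * a / 6))))
      reg <- 2 * (band - 1) + if (c <= ctr) 1 else 2
      counts[reg] <- counts[reg] + 1
    }
  }
  expect_equal(unname(tabulate(img[m], 12)), counts)
  expect_true(all(counts >= cfg$min_size))
  expect_error(phantom_config(networks = character()),
               class = "fcois_config_error")
})

test_that("network traces hit the target correlation exactly and in band", {
  cfg <- phantom_config(grid = 32, duration_s = 600)
  lat <- simulate_network_traces(cfg, seed = 3)
  target <- attr(lat, "target")
  expect_equal(unname(cor(t(lat))), unname(target), tolerance = 1e-8)
  # homotopic 0.8 and the configured anticorrelation present
  expect_equal(target["frontal_L", "frontal_R"], 0.8)
  expect_equal(target["frontal_L", "somatosensory_R"], -0.5)
  # spectral power outside the band below 1% of total
  ps <- power_spectrum(lat[1, ], cfg$rate_hz)
  inband <- ps$frequency >= 0.005 & ps$frequency <= 0.1
  expect_lt(sum(ps$power[-1][!inband[-1]]) / sum(ps$power[-1]), 0.01)
  # reproducible under a fixed seed
  lat2 <- simulate_network_traces(cfg, seed = 3)
  expect_identical(lat, lat2)
  # a perfectly correlated pair gives identical traces
  cfg2 <- phantom_config(grid = 32, networks = "solo", homotopic_r = 1,
                         anticorrelated = list(), duration_s = 300)
  lat3 <- simulate_network_traces(cfg2, seed = 1)
  expect_equal(lat3[1, ], lat3[2, ], tolerance = 1e-8)
  # an infeasible target is rejected with its smallest eigenvalue
  cfg3 <- phantom_config(grid = 32, networks = c("a", "b"),
                         homotopic_r = 0.9,
                         anticorrelated = list(c("a", "b", -0.96)))
  expect_error(simulate_network_traces(cfg3, seed = 1),
               class = "fcois_config_error")
})

test_that("rendered hemodynamics carry networks, physiology and coupling", {
  cfg <- phantom_config(grid = 32, duration_s = 300, noise_sd = 0,
                        global_weight = 0)
  sim <- simulate_phantom(cfg, seed = 2, species = c("hbo", "hbr"))
  tm <- phantom_traces(sim$hemo)
  lab <- labels_for_pixels(sim$truth, tm$pixels)
  # zero noise, zero global: within-region pixel pairs correlate at 1
  # after preprocessing
  pp <- preprocess_traces(tm)
  i <- which(lab == 3)[1:2]
  expect_equal(cor(pp$traces[i[1], ], pp$traces[i[2], ]), 1, tolerance = 1e-6)
  # raw pixel spectrum peaks at the configured physiological frequencies
  ps <- power_spectrum(tm$traces[1, ], cfg$rate_hz)
  near <- function(f) ps$frequency > f - 0.05 & ps$frequency < f + 0.05
  away <- ps$frequency > 1 & !near(2.5) & !near(10)
  expect_gt(max(ps$power[near(2.5)]), 100 * max(ps$power[away]))
  expect_gt(max(ps$power[near(10)]), 100 * max(ps$power[away]))
  # inverse HbR coupling with the configured ratio
  expect_equal(phantom_traces(sim$hemo, "hbr")$traces,
               -cfg$hbr_ratio * tm$traces)
})

test_that("within-network correlation falls monotonically with noise", {
  mean_within_r <- function(noise_sd) {
    cfg <- phantom_config(grid = 32, duration_s = 300, noise_sd = noise_sd)
    sim <- simulate_phantom(cfg, seed = 6)
    pp <- preprocess_traces(phantom_traces(sim$hemo))
    lab <- labels_for_pixels(sim$truth, pp$pixels)
    z <- pp$traces / sqrt(rowSums(pp$traces^2))
    mean(vapply(1:12, function(j) {
      i <- which(lab == j)[1:5]
      mean((z[i, ] %*% t(z[i, ]))[upper.tri(diag(5))])
    }, numeric(1)))
  }
  rs <- vapply(c(0, 1, 4, 16), mean_within_r, numeric(1))
  expect_true(all(diff(rs) < 0))
  expect_equal(rs[1], 1, tolerance = 1e-6)
})

test_that("phantoms are bit-reproducible under a fixed seed", {
  cfg <- phantom_config(grid = 32, duration_s = 120)
  a <- simulate_phantom(cfg, seed = 13)
  b <- simulate_phantom(cfg, seed = 13)
  expect_identical(a$hemo$hbo, b$hemo$hbo)
  expect_identical(a$latents, b$latents)
  c <- simulate_phantom(cfg, seed = 14)
  expect_false(identical(a$hemo$hbo, c$hemo$hbo))
})

test_that("raw-frame rendering is the exact forward optical model", {
  cfg <- phantom_config(grid = 32, duration_s = 150, noise_sd = 0.1)
  sim <- simulate_phantom(cfg, seed = 4, masked = FALSE,
                          species = c("hbo", "hbr"))
  model <- toy_optical_model()
  stream <- render_raw_frames(sim$hemo, model, phi0 = 80)
  # stream rate is n_wavelengths x the hemodynamic rate
  expect_equal(stream$frame_rate_hz, 120)
  expect_true(all(stream$frames > 0))
  # zero concentration changes give a constant stream at phi0
  flat <- sim$hemo
  flat$hbo[] <- 0; flat$hbr[] <- 0
  st0 <- render_raw_frames(flat, model, phi0 = 80)
  expect_true(all(st0$frames == 80))
  # full round trip through demux + spectroscopy (no noise in the optics)
  ch <- demux_wavelengths(stream)
  back <- intensity_to_hemoglobin(ch, model, smooth = FALSE)
  center <- function(a) sweep(a, c(2, 3), apply(a, c(2, 3), mean))
  hbo_t <- ifelse(is.na(sim$hemo$hbo), 0, sim$hemo$hbo)
  rel <- max(abs(center(back$hbo) - center(hbo_t))) / max(abs(center(hbo_t)))
  expect_lt(rel, 1e-6)
})
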