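# Fixtures are built in code at test time; nothing binary is stored.

# A tiny well-conditioned optical model (arbitrary coefficients, so no
# test depends on the bundled demo extinction values).
toy_optical_model <- function() {
  optical_model(
    wavelengths_nm = c(470, 530, 590, 630),
    extinction = rbind(c(1.0, 2.0),
                       c(2.0, 1.0),
                       c(0.5, 1.5),
                       c(1.5, 0.3)) * 1e-3,
    pathlength_mm = c(1, 2, 3, 4))
}

# Deterministic interleaved stream: cycle of 4 wavelengths, values encode
# (frame, pixel) so demux bookkeeping is fully checkable.
toy_stream <- function(n_cycles = 3, side = 4, rate = 120) {
  tags <- c("478", "588", "610", "625")
  nt <- n_cycles * length(tags)
  frames <- array(0, c(nt, side, side))
  for (t in seq_len(nt)) frames[t, , ] <- t + outer(seq_len(side), seq_len(side)) / 100
  frame_stream(frames, tags, rate, pixel_pitch_um = 80)
}

# Small phantom shared by several test files (computed once per session).
small_phantom_env <- new.env(parent = emptyenv())
small_phantom <- function(noise_sd = 1, seed = 7, grid = 64, duration_s = 300) {
  key <- paste(noise_sd, seed, grid, duration_s, sep = "_")
  if (is.null(small_phantom_env[[key]])) {
    cfg <- phantom_config(grid = grid, duration_s = duration_s,
                          noise_sd = noise_sd)
    sim <- simulate_phantom(cfg, seed = seed)
    sim$tm <- preprocess_traces(phantom_traces(sim$hemo))
    small_phantom_env[[key]] <- sim
  }
  small_phantom_env[[key]]
}

# Default seed catalogue rescaled from the 128 grid to a smaller one.
scaled_seeds <- function(grid = 64) {
  s <- default_seeds()
  s$row <- round(s$row * grid / 128)
  s$col <- round(s$col * grid / 128)
  s
}

# Brute-force Pearson correlation (independent of the package's
# standardized-matrix route).
pearson_loop <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# Exhaustive single-linkage agglomeration on a distance matrix; returns
# the merge heights in order, for comparison with hclust.
single_linkage_heights <- function(d) {
  d <- as.matrix(d)
  active <- lapply(seq_len(nrow(d)), identity)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(active)) for (j in seq_len(i - 1)) {
      h <- min(d[active[[i]], active[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    active[[best[3]]] <- c(active[[best[3]]], active[[best[2]]])
    active[[best[2]]] <- NULL
  }
  heights
}

# Amplitude transfer of a filter at frequency f0, measured by projecting
# the output onto the input quadrature pair (an FFT-bin measurement).
measured_gain <- function(y, x, f0, fs) {
  t <- (seq_along(x) - 1) / fs
  cs <- cos(2 * pi * f0 * t); sn <- sin(2 * pi * f0 * t)
  amp <- function(v) sqrt(sum(v * cs)^2 + sum(v * sn)^2)
  amp(y) / amp(x)
}
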