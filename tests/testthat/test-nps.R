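# nps: periodogram normalisation, radial averaging, noise SD

test_that("white noise gives a flat spectrum at sigma^2 dx dy", {
  tr <- phantom_truth(rng_seed = 7)                 # sigma 10, white
  vol <- fixture("nps_white", simulate_noise_volume(tr, grid_size = 160L,
                                                    n_slices = 4L))
  res <- nps_2d(vol, list(size = 64L), list(slice_gap = 0L, max_slices = 4L))
  expect_gte(res$n_rois, 64)
  expect_lt(abs(mean(res$nps1d$power) - 25) / 25, 0.05)
  # flat, not just flat on average; the first rings hold very few DFT bins
  # and are correspondingly noisier, so judge flatness above 0.1 lp/mm
  keep <- res$nps1d$frequency >= 0.1
  expect_lt(max(abs(res$nps1d$power[keep] - 25)) / 25, 0.15)
  expect_true(all(res$nps2d >= 0))
  # point-reflection symmetry of the 2D spectrum (real input); the first
  # fftshifted row/column is the unpaired Nyquist line and is skipped
  n <- nrow(res$nps2d)
  core <- res$nps2d[2:n, 2:n]
  flipped <- core[rev(seq_len(n - 1)), rev(seq_len(n - 1))]
  expect_lt(max(abs(core - flipped)) / 25, 1e-10)
})

test_that("Parseval: spectrum integral equals the detrended variance", {
  tr <- phantom_truth(rng_seed = 7)
  vol <- fixture("nps_white", simulate_noise_volume(tr, grid_size = 160L,
                                                    n_slices = 4L))
  res <- nps_2d(vol, list(size = 64L), list(slice_gap = 0L, max_slices = 4L))
  df <- 1 / (64 * vol$dx)
  expect_lt(abs(sum(res$nps2d) * df^2 - res$noise_sd^2) / res$noise_sd^2,
            0.05)
})

test_that("subtracted and unsubtracted modes agree on stationary noise", {
  tr <- phantom_truth(rng_seed = 7)
  vols <- lapply(1:4, function(i)
    simulate_noise_volume(tr, 160L, n_slices = 2L, seed_offset = i))
  un <- nps_2d(vols, list(size = 64L), list(slice_gap = 0L, max_slices = 2L),
               "unsubtracted")
  su <- nps_2d(vols, list(size = 64L), list(slice_gap = 0L, max_slices = 2L),
               "subtracted")
  # the first rings average only a handful of DFT bins and dominate the
  # full-curve RMS; agreement is judged above 0.1 lp/mm here (the larger
  # acceptance fixture checks the full curve)
  keep <- un$nps1d$frequency >= 0.1
  expect_lt(sqrt(mean((un$nps1d$power[keep] - su$nps1d$power[keep])^2)) / 25,
            0.05)
  expect_error(nps_2d(vols[1], mode = "subtracted"), "two volumes")
})

test_that("polynomial detrending absorbs a planar ramp", {
  tr <- phantom_truth(rng_seed = 7)
  vol <- fixture("nps_white", simulate_noise_volume(tr, grid_size = 160L,
                                                    n_slices = 4L))
  ramped <- vol
  ramp <- outer(rep(0.1, 160), seq_len(160) - 1)   # 0.1 HU per pixel along x
  for (k in 1:4) ramped$voxels[, , k] <- vol$voxels[, , k] + ramp
  a <- nps_2d(vol, list(size = 64L), list(slice_gap = 0L, max_slices = 4L))
  b <- nps_2d(ramped, list(size = 64L), list(slice_gap = 0L, max_slices = 4L))
  expect_lt(max(abs(a$nps1d$power - b$nps1d$power)) / 25, 0.02)
})

test_that("radial averaging handles flat, isotropic and ring spectra", {
  n <- 64L
  fx <- sort(ctiq:::fft_freq(n, 0.5))
  flat <- list(nps2d = matrix(3, n, n), fx = fx, fy = fx)
  rf <- radial_average(flat)
  expect_true(all(rf$power == 3))

  # ring-shaped spectrum peaked at 0.3 lp/mm
  fr <- sqrt(outer(fx^2, fx^2, `+`))
  ring <- list(nps2d = exp(-(fr - 0.3)^2 / (2 * 0.03^2)), fx = fx, fy = fx)
  r1 <- radial_average(ring)
  expect_lt(abs(peak_frequency(r1) - 0.3), 1 / (n * 0.5) + 1e-9)

  # isotropic input: radial average equals a single radial cut within 2%
  iso2d <- exp(-fr / 0.6)
  riso <- radial_average(list(nps2d = iso2d, fx = fx, fy = fx))
  i0 <- which(fx == 0)                    # fy = 0 row, fx >= 0
  cutf <- fx[i0:n]
  comp <- stats::approx(riso$frequency, riso$power, xout = cutf[cutf > 0.1])$y
  expect_lt(max(abs(comp - exp(-cutf[cutf > 0.1] / 0.6)) /
                  exp(-cutf[cutf > 0.1] / 0.6)), 0.02)
})

test_that("peak_frequency picks the maximum bin with low-frequency ties", {
  mono <- data.frame(frequency = c(0.1, 0.2, 0.3), power = c(3, 2, 1))
  expect_equal(peak_frequency(mono), 0.1)
  tied <- data.frame(frequency = c(0.1, 0.2, 0.3), power = c(2, 3, 3))
  expect_equal(peak_frequency(tied), 0.2)
  zero <- data.frame(frequency = c(0.1, 0.2), power = c(0, 0))
  expect_error(peak_frequency(zero), "no peak")
})

test_that("band-pass kernel peak lands at the designed frequency", {
  k <- dog_kernel()
  fgrid <- seq(0.01, 1, by = 0.005)
  h2 <- kernel_transfer_sq(k, fgrid, rep(0, length(fgrid)), 0.5, 0.5)
  f_design <- fgrid[which.max(h2)]
  tr <- phantom_truth(noise_kernel = k, rng_seed = 11)
  vols <- lapply(1:2, function(i)
    simulate_noise_volume(tr, 256L, 0.5, n_slices = 2L, seed_offset = i))
  res <- nps_2d(vols, list(size = 128L), list(slice_gap = 1L, max_slices = 2L))
  expect_lt(abs(res$peak_frequency - f_design), 1 / (128 * 0.5) + 1e-9)
})

test_that("noise_sd matches hand arithmetic and white-noise truth", {
  flat <- image_volume(matrix(5, 32, 32), 0.5, 0.5)
  expect_equal(noise_sd(flat, circular_roi(0, 0, 10)), 0)

  two <- image_volume(matrix(c(0, 2), 1, 2), 1, 1)
  # diameter 1: both pixel centres sit exactly on the (inclusive) boundary
  expect_equal(noise_sd(two, circular_roi(0, 0, 1)), sqrt(2))

  one <- image_volume(matrix(1, 1, 1), 1, 1)
  expect_error(noise_sd(one, circular_roi(0, 0, 1)), "2 pixels")

  tr <- phantom_truth(rng_seed = 7)
  vol <- fixture("nps_white", simulate_noise_volume(tr, grid_size = 160L,
                                                    n_slices = 4L))
  # ROI of ~10^4 px: SD within 3% (chi-square SE ~ 1/sqrt(2n) ~ 0.7%)
  sd_est <- noise_sd(vol, circular_roi(0, 0, 57))
  expect_lt(abs(sd_est - 10) / 10, 0.03)
})

test_that("doubling n_rois shrinks the RMS deviation by about sqrt(2)", {
  # lowest bins excluded: their deterministic detrending bias does not
  # average down with more ROIs
  rmsdev <- function(vol, nsl) {
    v <- vol
    v$voxels <- vol$voxels[, , seq_len(nsl), drop = FALSE]
    r <- nps_2d(v, list(size = 64L), list(slice_gap = 0L, max_slices = nsl))
    keep <- r$nps1d$frequency >= 0.1
    sqrt(mean((r$nps1d$power[keep] - 25)^2))
  }
  r1 <- r2 <- numeric(10)
  for (k in 1:10) {
    tr <- phantom_truth(rng_seed = 200 + k)
    vol <- simulate_noise_volume(tr, 160L, 0.5, n_slices = 4L)
    r1[k] <- rmsdev(vol, 2L)    # 32 ROIs
    r2[k] <- rmsdev(vol, 4L)    # 64 ROIs
  }
  ratio <- mean(r1) / mean(r2)
  expect_gte(ratio, 1.2)
  expect_lte(ratio, 1.7)
})

test_that("nps_2d validates its inputs", {
  tr <- phantom_truth()
  vol <- simulate_noise_volume(tr, grid_size = 32L)
  expect_error(nps_2d(vol, list(size = 64L)), "ROI")
})
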