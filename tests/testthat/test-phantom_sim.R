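# phantom_sim: generators against closed-form and quadrature oracles

test_that("phantom_truth validates parameters", {
  expect_error(phantom_truth(psf_sigma = -1))
  expect_error(phantom_truth(slice_fwhm = 0))
  expect_error(phantom_truth(noise_kernel = matrix(1, 2, 2)), "odd")
})

test_that("blurred-disc rendering matches an independent quadrature oracle", {
  # the generator's closed-form profile vs direct numeric convolution
  prof <- ctiq:::disc_blur_profile(4, 0.3)
  r <- c(0, 2, 3.5, 4, 4.5, 5.5)
  expect_lt(max(abs(prof(r) - disc_blur_quad(4, 0.3, r))), 1e-6)
})

test_that("wire image: centroid, flux conservation, second moment", {
  tr <- phantom_truth(noise_sigma_white = 0)
  pos <- c(0.4, -0.3)
  vol <- fixture("wire_offcentre", simulate_wire_image(tr,
                                                       wire_position = pos))
  img <- vol$voxels[, , 1]
  x <- ctiq:::pixel_x(vol); y <- ctiq:::pixel_y(vol)
  w <- img / sum(img)
  cx <- sum(outer(rep(1, length(y)), x) * w)
  cy <- sum(outer(y, rep(1, length(x))) * w)
  expect_lt(abs(cx - pos[1]), 1e-3)
  expect_lt(abs(cy - pos[2]), 1e-3)

  # total excess signal invariant to psf_sigma (convolution conserves flux)
  s1 <- sum(vol$voxels)
  s2 <- sum(simulate_wire_image(phantom_truth(psf_sigma = 0.35,
                                              noise_sigma_white = 0),
                                wire_position = pos)$voxels)
  expect_lt(abs(s1 - s2) / s1, 1e-3)

  # per-axis second central moment: sigma^2 + d^2/16 + dx^2/12
  tr2 <- phantom_truth(psf_sigma = 0.2, noise_sigma_white = 0)
  v2 <- simulate_wire_image(tr2, wire_position = c(0.025, 0.025))
  img2 <- v2$voxels[, , 1]
  w2 <- img2 / sum(img2)
  x2 <- ctiq:::pixel_x(v2)
  mx <- sum(outer(rep(1, 256), x2) * w2)
  m2 <- sum((outer(rep(1, 256), x2) - mx)^2 * w2)
  pred <- 0.2^2 + tr2$wire_diameter^2 / 16 + v2$dx^2 / 12
  expect_lt(abs(m2 - pred) / pred, 1e-3)
})

test_that("wire image validates geometry", {
  tr <- phantom_truth()
  expect_error(simulate_wire_image(tr, wire_position = c(6.2, 0)), "margin")
  expect_error(simulate_wire_image(phantom_truth(psf_sigma = 0,
                                                 wire_diameter = 1e-5)),
               "unresolvable")
})

test_that("rod image matches the blurred-disc quadrature oracle", {
  tr <- phantom_truth(noise_sigma_white = 0)
  vol <- fixture("rod_default", simulate_rod_image(tr))
  img <- vol$voxels[, , 1]
  centre_val <- img[80, 80]
  expect_lt(abs(centre_val - tr$rod_contrast) / tr$rod_contrast, 1e-3)

  # radial profile vs independent 1D numeric convolution, area-averaged
  x <- ctiq:::pixel_x(vol); y <- ctiq:::pixel_y(vol)
  os <- 8; off <- ((seq_len(os) - 0.5) / os - 0.5) * vol$dx
  sub <- expand.grid(ox = off, oy = off)
  for (idx in list(c(80, 110), c(80, 119), c(60, 100))) {
    px <- x[idx[2]]; py <- y[idx[1]]
    pred <- tr$rod_contrast *
      mean(disc_blur_quad(tr$rod_radius, tr$psf_sigma,
                          sqrt((px + sub$ox)^2 + (py + sub$oy)^2)))
    expect_lt(abs(img[idx[1], idx[2]] - pred) /
                max(abs(pred), tr$rod_contrast * 0.005),
              0.005)
  }

  # zero contrast -> uniform image
  v0 <- simulate_rod_image(phantom_truth(rod_contrast = 0,
                                         noise_sigma_white = 0))
  expect_equal(max(v0$voxels) - min(v0$voxels), 0)

  expect_error(simulate_rod_image(tr, rod_centre = c(4, 0)), "border")
  expect_error(simulate_rod_image(phantom_truth(rod_radius = 0.5)),
               "10 pixels")
})

test_that("noise volume variance follows sum(h^2)", {
  # identity kernel: variance within 3 SE over >= 64 ROIs
  tr <- phantom_truth(rng_seed = 7)
  vol <- simulate_noise_volume(tr, grid_size = 160L, n_slices = 4L)
  block_var <- function(m) stats::var(as.vector(m))
  rois <- apply(array(vol$voxels, c(20, 8, 20, 8, 4)), c(2, 4, 5),
                block_var)           # 8 x 8 x 4 = 256 disjoint 20x20 ROIs
  se <- 100 * sqrt(2 / (400 - 1)) / sqrt(length(rois))
  expect_lt(abs(mean(rois) - 100), 3 * se)

  # two-tap averaging kernel (embedded in odd dims): sum(h^2) = 1/2
  k <- matrix(c(0.5, 0.5, 0), 3, 1)
  tr2 <- phantom_truth(noise_kernel = k, rng_seed = 8)
  vol2 <- simulate_noise_volume(tr2, grid_size = 160L, n_slices = 4L)
  rois2 <- apply(array(vol2$voxels, c(20, 8, 20, 8, 4)), c(2, 4, 5),
                 block_var)
  expect_lt(abs(mean(rois2) - 50), 3 * se / 2)

  # determinism
  expect_identical(simulate_noise_volume(tr)$voxels,
                   simulate_noise_volume(tr)$voxels)
})

test_that("foil stack follows the slice profile", {
  # gaussian amplitude at +/- fwhm/2 is half the peak
  expect_equal(slice_profile_amplitude(c(-0.225, 0.225), "gaussian", 0.45),
               c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(slice_profile_amplitude(c(-0.225, 0, 0.225),
                                       "trapezoid", 0.45)[c(1, 3)],
               c(0.5, 0.5), tolerance = 1e-6)

  # total integral over z matches numeric quadrature for both shapes
  roiv <- NULL
  for (shape in c("gaussian", "trapezoid")) {
    tr <- phantom_truth(noise_sigma_white = 0, slice_profile = shape)
    vol <- simulate_foil_stack(tr, z_increment = 0.05, z_extent = 1.8)
    roi <- circular_roi(0, 0, 23 * vol$dx)
    mask <- ctiq:::roi_mask(vol, roi)
    resp <- apply(vol$voxels, 3, function(s) mean(s[mask]))
    # in-plane disc factor from the central slice (z = 0, amplitude 1)
    disc <- mean(vol$voxels[, , (dim(vol$voxels)[3] + 1) / 2][mask]) /
      tr$foil_contrast
    quad <- tr$foil_contrast * disc *
      stats::integrate(function(z)
        slice_profile_amplitude(z, shape, tr$slice_fwhm), -2, 2)$value
    expect_lt(abs(sum(resp) * vol$dz - quad) / quad, 0.01)
    # zero-noise stack is symmetric about the foil
    expect_equal(resp, rev(resp), tolerance = 1e-12)
  }

  expect_error(simulate_foil_stack(phantom_truth(), 0.2, 4), "fwhm/3")
  expect_error(simulate_foil_stack(phantom_truth(), 0.1, 1), "4 FWHM")
})

test_that("low-contrast module has nominal amplitudes and is deterministic", {
  tr <- phantom_truth(noise_sigma_white = 0)
  vol <- fixture("lc_noiseless", simulate_low_contrast_module(tr))
  lay <- vol$truth$lc_layout
  expect_equal(sort(unique(lay$contrast_hu)), c(3, 5, 10))
  expect_equal(lay$contrast_hu, 10 * lay$contrast_pct)

  # zero noise: central-ROI mean contrast within 2% of nominal for
  # diameter >= 10 psf_sigma (central quarter-diameter ROI avoids edge blur)
  x <- ctiq:::pixel_x(vol); y <- ctiq:::pixel_y(vol)
  big <- lay[lay$diameter >= 10 * tr$psf_sigma, ]
  for (i in seq_len(nrow(big))) {
    rr2 <- outer((y - big$cy[i])^2, (x - big$cx[i])^2, `+`)
    m <- mean(vol$voxels[, , 1][rr2 <= (0.25 * big$diameter[i])^2])
    expect_lt(abs(m - big$contrast_hu[i]) / big$contrast_hu[i], 0.02)
  }

  tr2 <- phantom_truth(rng_seed = 33)
  expect_identical(simulate_low_contrast_module(tr2, grid_size = 340L)$voxels,
                   simulate_low_contrast_module(tr2, grid_size = 340L)$voxels)
})

test_that("insert module: nominal HUs, noise behaviour, unknown materials", {
  tr <- phantom_truth(noise_sigma_white = 0)
  vol <- simulate_insert_module(tr)
  meas <- measure_insert_hu(vol, vol$truth$insert_layout)
  expect_lt(max(abs(meas - tr$insert_hus[names(meas)])), 0.01)

  # with noise sigma = 10 the ROI mean stays within 4 SE of nominal
  trn <- phantom_truth(noise_sigma_white = 10, rng_seed = 3)
  voln <- simulate_insert_module(trn, noise = TRUE)
  roi_n <- length(extract_roi_pixels(voln, circular_roi(25, 0, 10)))
  mn <- measure_insert_hu(voln, voln$truth$insert_layout)
  expect_true(all(abs(mn - trn$insert_hus[names(mn)]) <=
                    4 * 10 / sqrt(roi_n)))

  expect_error(simulate_insert_module(tr, materials = c("air", "gold")),
               "unknown material")
})
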