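#' Ground-truth parameter set for the digital phantoms
#'
#' Bundles every generator parameter so that each simulated image carries its
#' own analytic ground truth: downstream recovery tests compare estimates
#' against these values, never against hard-coded numbers.
#'
#' Defaults emulate the measurement conditions of an abdominal UHRCT
#' evaluation: a 50-um tungsten wire for the point-method MTF, a Teflon rod
#' (+990 HU over a water-equivalent background) for the circular-edge MTF, a
#' Gaussian slice profile, ACR-style insert nominals, and a CTP515-like
#' low-contrast layout with contrasts 1.0/0.5/0.3% of 1000 HU over nine
#' diameters 2-15 mm.
#'
#' @param psf_sigma Isotropic in-plane Gaussian PSF standard deviation, mm.
#' @param wire_diameter Wire diameter, mm.
#' @param wire_contrast Wire disc amplitude over background, HU.
#' @param rod_radius Rod radius, mm.
#' @param rod_contrast Rod amplitude over background, HU.
#' @param background_hu Background level, HU.
#' @param noise_sigma_white SD of the pre-filter white Gaussian noise, HU.
#' @param noise_kernel Small 2D convolution kernel (odd dimensions) defining
#'   the noise correlation; the identity 1x1 kernel gives white noise.
#' @param slice_profile `"gaussian"` or `"trapezoid"` longitudinal profile.
#' @param slice_fwhm Full width at half maximum of the slice profile, mm.
#' @param foil_contrast Peak amplitude of the foil response, HU.
#' @param insert_hus Named vector of nominal insert HU values.
#' @param lc_diameters Low-contrast object diameters, mm.
#' @param lc_contrasts Low-contrast levels, percent of 1000 HU.
#' @param rng_seed Integer seed making every generator deterministic.
#' @return An object of class `phantom_truth`.
#' @export
phantom_truth <- function(psf_sigma = 0.1874,
                          wire_diameter = 0.05,
                          wire_contrast = 50000,
                          rod_radius = 4,
                          rod_contrast = 990,
                          background_hu = 0,
                          noise_sigma_white = 10,
                          noise_kernel = matrix(1, 1, 1),
                          slice_profile = c("gaussian", "trapezoid"),
                          slice_fwhm = 0.45,
                          foil_contrast = 1000,
                          insert_hus = c(air = -1000, ldpe = -95, water = 0,
                                         acrylic = 120, teflon = 990),
                          lc_diameters = c(2, 3, 4, 5, 6, 7, 8, 9, 15),
                          lc_contrasts = c(1.0, 0.5, 0.3),
                          rng_seed = 1L) {
  slice_profile <- match.arg(slice_profile)
  stopifnot(psf_sigma >= 0, slice_fwhm > 0, noise_sigma_white >= 0,
            wire_diameter > 0, rod_radius > 0,
            all(lc_diameters > 0), length(insert_hus) > 0)
  if (!is.matrix(noise_kernel) || any(dim(noise_kernel) %% 2 != 1))
    stop("noise_kernel must be a matrix with odd dimensions")
  structure(
    list(psf_sigma = psf_sigma, wire_diameter = wire_diameter,
         wire_contrast = wire_contrast, rod_radius = rod_radius,
         rod_contrast = rod_contrast, background_hu = background_hu,
         noise_sigma_white = noise_sigma_white, noise_kernel = noise_kernel,
         slice_profile = slice_profile, slice_fwhm = slice_fwhm,
         foil_contrast = foil_contrast, insert_hus = insert_hus,
         lc_diameters = lc_diameters, lc_contrasts = lc_contrasts,
         rng_seed = as.integer(rng_seed)),
    class = "phantom_truth"
  )
}

# run expr with a private RNG stream; the caller's RNG state is untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Radial profile of a uniform disc of radius R convolved with an isotropic
# Gaussian of SD sigma. Exact closed form: the blurred value at distance r
# from the disc centre is P(|r + N2(0, sigma^2 I)| <= R), i.e. a noncentral
# chi-square CDF. Returned as a fast interpolating function.
disc_blur_profile <- function(R, sigma) {
  if (sigma <= 0) return(function(r) as.numeric(r <= R))
  rmax <- R + 7 * sigma
  rg <- seq(0, rmax, length.out = 4096L)
  v <- stats::pchisq((R / sigma)^2, df = 2, ncp = (rg / sigma)^2)
  f <- stats::approxfun(rg, v, rule = 2)
  function(r) {
    out <- numeric(length(r))
    inside <- r < rmax
    out[inside] <- f(r[inside])
    out
  }
}

# mean over os x os blocks, collapsing an (nr*os) x (nc*os) matrix to nr x nc
block_mean <- function(M, os) {
  nr <- nrow(M) %/% os; nc <- ncol(M) %/% os
  m1 <- matrix(colMeans(matrix(M, nrow = os)), nrow = nr)   # row blocks
  t(matrix(colMeans(matrix(t(m1), nrow = os)), nrow = nc))  # col blocks
}

# Render discs blurred by a Gaussian PSF on an oversampled grid (default 8x),
# then downsample by area averaging. discs: data.frame(cx, cy, radius, amp).
render_discs <- function(n_row, n_col, pitch, discs, sigma,
                         oversample = 8L, background = 0) {
  os <- as.integer(oversample)
  osp <- pitch / os
  nro <- n_row * os; nco <- n_col * os
  xo <- (seq_len(nco) - 1 - (nco - 1) / 2) * osp
  yo <- ((nro - 1) / 2 - (seq_len(nro) - 1)) * osp
  canvas <- matrix(0, nro, nco)
  for (i in seq_len(nrow(discs))) {
    d <- discs[i, ]
    prof <- disc_blur_profile(d$radius, sigma)
    ext <- d$radius + 7 * sigma + osp
    jx <- which(abs(xo - d$cx) <= ext)
    jy <- which(abs(yo - d$cy) <= ext)
    if (!length(jx) || !length(jy)) next
    rr <- sqrt(outer((yo[jy] - d$cy)^2, (xo[jx] - d$cx)^2, `+`))
    canvas[jy, jx] <- canvas[jy, jx] + d$amp * prof(rr)
  }
  block_mean(canvas, os) + background
}

# White Gaussian field convolved (circularly, via FFT) with a small kernel.
# Circular convolution keeps the field stationary, so the analytic NPS
# sigma^2 * dx * dy * |H(f)|^2 holds exactly at the DFT frequencies.
correlated_noise <- function(n_row, n_col, sigma_white, kernel) {
  w <- matrix(stats::rnorm(n_row * n_col, sd = sigma_white), n_row, n_col)
  if (all(dim(kernel) == c(1L, 1L))) return(w * kernel[1, 1])
  kr <- nrow(kernel); kc <- ncol(kernel)
  K <- matrix(0, n_row, n_col)
  # embed kernel with its centre at (1,1), wrapping negative offsets
  rc <- (kr + 1L) %/% 2L; cc <- (kc + 1L) %/% 2L
  for (a in seq_len(kr)) for (b in seq_len(kc)) {
    ia <- ((a - rc) %% n_row) + 1L
    ib <- ((b - cc) %% n_col) + 1L
    K[ia, ib] <- K[ia, ib] + kernel[a, b]
  }
  Re(stats::fft(stats::fft(w) * stats::fft(K), inverse = TRUE)) /
    (n_row * n_col)
}

# Discrete-space Fourier transform magnitude squared of a noise kernel at
# frequencies (fx, fy) in lp/mm; used as the analytic NPS shape |H(f)|^2.
#' Analytic squared transfer of a noise kernel
#'
#' Evaluates `|H(fx, fy)|^2`, where H is the discrete-space Fourier transform
#' of the kernel on a grid with spacing (dx, dy). Together with the white
#' noise SD this gives the generator's analytic noise power spectrum
#' `sigma^2 * dx * dy * |H|^2`.
#'
#' @param kernel 2D kernel matrix (odd dimensions).
#' @param fx,fy Frequencies, lp/mm (recycled to a common length).
#' @param dx,dy Grid spacing, mm.
#' @return `|H|^2`, same length as the frequency input.
#' @export
kernel_transfer_sq <- function(kernel, fx, fy, dx, dy) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  rc <- (kr + 1L) %/% 2L; cc <- (kc + 1L) %/% 2L
  n <- max(length(fx), length(fy))
  fx <- rep_len(fx, n); fy <- rep_len(fy, n)
  H <- complex(real = rep(0, n))
  for (a in seq_len(kr)) for (b in seq_len(kc)) {
    # row offset moves along y, column offset along x
    H <- H + kernel[a, b] *
      exp(-2i * pi * (fy * (a - rc) * dy + fx * (b - cc) * dx))
  }
  Mod(H)^2
}

#' Difference-of-Gaussians noise kernel
#'
#' A small band-pass kernel producing a ring-shaped noise power spectrum,
#' qualitatively mimicking the band-shaped NPS of filtered-backprojection CT
#' noise. Normalised so that the kernel's total power `sum(h^2)` is 1, which
#' keeps the image noise variance equal to the white-noise variance.
#'
#' @param sigma1,sigma2 SDs (in pixels) of the positive and negative Gaussian
#'   lobes; `sigma1 < sigma2`.
#' @param half_size Kernel half width in pixels (kernel is
#'   `2*half_size+1` square).
#' @return Kernel matrix.
#' @export
dog_kernel <- function(sigma1 = 1, sigma2 = 2.5, half_size = 8L) {
  g <- function(s) {
    u <- seq(-half_size, half_size)
    k <- exp(-outer(u^2, u^2, `+`) / (2 * s^2))
    k / sum(k)
  }
  h <- g(sigma1) - g(sigma2)
  h / sqrt(sum(h^2))
}

attach_truth <- function(vol, truth, extra = NULL) {
  vol$truth <- c(unclass(truth), extra)
  vol
}

#' Simulate a thin-wire point-response image
#'
#' Renders the wire as a small disc of `wire_diameter` at a (sub-pixel)
#' position, convolved with the Gaussian PSF on an oversampled grid and
#' downsampled by area averaging, plus optional correlated noise.
#'
#' @param truth A [phantom_truth()].
#' @param grid_size Image dimension, pixels (square).
#' @param pixel_pitch Pixel spacing, mm.
#' @param wire_position Wire centre `c(x, y)` in mm.
#' @param noise Add noise at `truth$noise_sigma_white`? Default `FALSE`
#'   (point-method MTF fixtures are conventionally near-noiseless).
#' @return An [image_volume()] with the ground truth attached as `$truth`.
#' @export
simulate_wire_image <- function(truth, grid_size = 256L, pixel_pitch = 0.05,
                                wire_position = c(0, 0), noise = FALSE) {
  stopifnot(inherits(truth, "phantom_truth"))
  osp <- pixel_pitch / 8
  if (truth$psf_sigma < osp / 8 && truth$wire_diameter < osp / 8)
    stop("wire and PSF both below 1/8 oversampled pixel: unresolvable")
  half <- (grid_size - 1) / 2 * pixel_pitch
  margin <- 10 * truth$psf_sigma + truth$wire_diameter
  if (any(abs(wire_position) + margin > half))
    stop("wire does not fit in the grid with a 10-sigma margin")
  img <- render_discs(grid_size, grid_size, pixel_pitch,
                      data.frame(cx = wire_position[1], cy = wire_position[2],
                                 radius = truth$wire_diameter / 2,
                                 amp = truth$wire_contrast),
                      truth$psf_sigma, background = truth$background_hu)
  if (noise && truth$noise_sigma_white > 0)
    img <- img + with_seed(truth$rng_seed,
                           correlated_noise(grid_size, grid_size,
                                            truth$noise_sigma_white,
                                            truth$noise_kernel))
  attach_truth(image_volume(img, pixel_pitch, pixel_pitch),
               truth, list(wire_position = wire_position))
}

#' Simulate a high-contrast rod (circular edge) image
#'
#' @inheritParams simulate_wire_image
#' @param rod_centre Rod centre `c(x, y)`, mm.
#' @param noise Add correlated noise?
#' @return An [image_volume()] with `$truth`.
#' @export
simulate_rod_image <- function(truth, grid_size = 160L, pixel_pitch = 0.1,
                               rod_centre = c(0, 0), noise = FALSE) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (truth$rod_radius < 10 * pixel_pitch)
    stop("rod radius must be at least 10 pixels")
  half <- (grid_size - 1) / 2 * pixel_pitch
  if (any(abs(rod_centre) + truth$rod_radius + 5 * truth$psf_sigma > half))
    stop("rod touches the image border")
  img <- render_discs(grid_size, grid_size, pixel_pitch,
                      data.frame(cx = rod_centre[1], cy = rod_centre[2],
                                 radius = truth$rod_radius,
                                 amp = truth$rod_contrast),
                      truth$psf_sigma, background = truth$background_hu)
  if (noise && truth$noise_sigma_white > 0)
    img <- img + with_seed(truth$rng_seed,
                           correlated_noise(grid_size, grid_size,
                                            truth$noise_sigma_white,
                                            truth$noise_kernel))
  attach_truth(image_volume(img, pixel_pitch, pixel_pitch),
               truth, list(rod_centre = rod_centre))
}

#' Simulate a uniform noise volume
#'
#' Each slice is background plus a white Gaussian field (SD
#' `noise_sigma_white`, i.i.d. across slices) convolved with the noise
#' kernel. The analytic NPS is `sigma^2 * dx * dy * |H(f)|^2` (see
#' [kernel_transfer_sq()]) and the analytic variance is
#' `sigma^2 * sum(kernel^2)`.
#'
#' @inheritParams simulate_wire_image
#' @param n_slices Number of slices.
#' @param seed_offset Added to `truth$rng_seed`, so repeat scans of the same
#'   phantom (for subtracted-NPS pairs) get independent noise.
#' @return An [image_volume()] with `$truth`.
#' @export
simulate_noise_volume <- function(truth, grid_size = 160L, pixel_pitch = 0.5,
                                  n_slices = 1L, seed_offset = 0L) {
  stopifnot(inherits(truth, "phantom_truth"))
  vox <- array(0, c(grid_size, grid_size, n_slices))
  with_seed(truth$rng_seed + seed_offset, {
    for (k in seq_len(n_slices))
      vox[, , k] <- truth$background_hu +
        correlated_noise(grid_size, grid_size, truth$noise_sigma_white,
                         truth$noise_kernel)
  })
  attach_truth(image_volume(vox, pixel_pitch, pixel_pitch), truth)
}

#' Longitudinal slice-profile amplitude
#'
#' Normalised (peak 1) response of the slice profile at longitudinal
#' distance z from the foil. `"gaussian"`: `exp(-z^2 / (2 sigma^2))` with
#' `sigma = fwhm / 2.35482`. `"trapezoid"`: convolution of two boxes of
#' widths `fwhm` and `fwhm/2`, whose FWHM is exactly `fwhm`.
#'
#' @param z Longitudinal positions, mm.
#' @param shape `"gaussian"` or `"trapezoid"`.
#' @param fwhm Full width at half maximum, mm.
#' @return Amplitudes in `[0, 1]`.
#' @export
slice_profile_amplitude <- function(z, shape = c("gaussian", "trapezoid"),
                                    fwhm = 0.45) {
  shape <- match.arg(shape)
  if (shape == "gaussian") {
    s <- fwhm / (2 * sqrt(2 * log(2)))
    exp(-z^2 / (2 * s^2))
  } else {
    w1 <- fwhm; w2 <- fwhm / 2      # rect(w1) (x) rect(w2), peak-normalised
    a <- pmin(w1 / 2, z + w2 / 2) - pmax(-w1 / 2, z - w2 / 2)
    pmax(a, 0) / w2
  }
}

#' Simulate a thin-foil z-stack for the slice sensitivity profile
#'
#' An in-plane uniform disc whose per-slice amplitude follows the slice
#' profile, sampled at the requested z increment and centred in the stack.
#'
#' @inheritParams simulate_wire_image
#' @param z_increment Slice increment, mm (must be `<= fwhm / 3`).
#' @param z_extent Total stack length, mm (must be `>= 4 * fwhm` so that the
#'   tails provide a background estimate).
#' @param disc_radius In-plane disc radius, mm.
#' @param noise Add noise (i.i.d. per slice)?
#' @return An [image_volume()] with `$truth`.
#' @export
simulate_foil_stack <- function(truth, z_increment, z_extent,
                                grid_size = 64L, pixel_pitch = 0.5,
                                disc_radius = 10, noise = FALSE) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (z_increment > truth$slice_fwhm / 3)
    stop("z_increment must be <= fwhm/3")
  if (z_extent < 4 * truth$slice_fwhm)
    stop("z_extent must span at least 4 FWHM (tails needed for background)")
  z <- seq(-z_extent / 2, z_extent / 2, by = z_increment)
  amp <- truth$foil_contrast *
    slice_profile_amplitude(z, truth$slice_profile, truth$slice_fwhm)
  disc <- render_discs(grid_size, grid_size, pixel_pitch,
                       data.frame(cx = 0, cy = 0, radius = disc_radius,
                                  amp = 1),
                       truth$psf_sigma, background = 0)
  vox <- array(0, c(grid_size, grid_size, length(z)))
  for (k in seq_along(z))
    vox[, , k] <- truth$background_hu + amp[k] * disc
  if (noise && truth$noise_sigma_white > 0)
    with_seed(truth$rng_seed, {
      for (k in seq_along(z))
        vox[, , k] <- vox[, , k] +
          correlated_noise(grid_size, grid_size, truth$noise_sigma_white,
                           truth$noise_kernel)
    })
  attach_truth(image_volume(vox, pixel_pitch, pixel_pitch,
                            dz = z_increment, origin_z = z[1]),
               truth, list(foil_z = 0, disc_radius = disc_radius))
}

# Lay the low-contrast objects on a single ring in one sector per contrast
# level, with the ring radius computed from the non-overlap requirement
# (object + background annulus + clearance); returns data.frame layout.
lc_layout_ring <- function(diameters, contrasts, clearance = 2) {
  d <- rep(diameters, times = length(contrasts))
  ct <- rep(contrasts, each = length(diameters))
  # space needed along the ring on each side of an object: the CNR background
  # annulus extends to 0.95 * diameter from the centre
  halfspan <- 0.95 * d + clearance / 2
  need <- sum(2 * halfspan)
  radius <- need / (2 * pi) * 1.05
  ang <- cumsum(2 * halfspan) - halfspan
  ang <- ang / need * 2 * pi
  data.frame(cx = radius * cos(ang), cy = radius * sin(ang),
             diameter = d, contrast_pct = ct,
             contrast_hu = 10 * ct, ring_radius = radius)
}

#' Simulate a CTP515-like low-contrast module
#'
#' Discs at known positions with contrast expressed in percent of 1000 HU
#' (1% = 10 HU), blurred by the PSF and overlaid with correlated noise. The
#' layout (positions, diameters, contrasts) is attached as ground truth for
#' the low-contrast reader.
#'
#' @inheritParams simulate_wire_image
#' @param n_slices Number of slices (for slab-averaged readouts).
#' @param noise_scale Multiplies `truth$noise_sigma_white`; a dose change by
#'   factor k corresponds to `noise_scale = 1/sqrt(k)`.
#' @param seed_offset Added to the seed for independent repeats.
#' @return An [image_volume()] with `$truth` (including `$lc_layout`).
#' @export
simulate_low_contrast_module <- function(truth, grid_size = NULL,
                                         pixel_pitch = 0.5, n_slices = 1L,
                                         noise_scale = 1, seed_offset = 0L) {
  stopifnot(inherits(truth, "phantom_truth"))
  layout <- lc_layout_ring(truth$lc_diameters, truth$lc_contrasts)
  # collision check among object + annulus footprints
  n <- nrow(layout)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    dist <- sqrt((layout$cx[i] - layout$cx[j])^2 +
                   (layout$cy[i] - layout$cy[j])^2)
    if (dist < 0.95 * layout$diameter[i] + 0.5 * layout$diameter[j] ||
        dist < 0.95 * layout$diameter[j] + 0.5 * layout$diameter[i])
      stop("low-contrast layout objects overlap")
  }
  rmax <- max(layout$ring_radius + 0.95 * layout$diameter) + 4
  if (is.null(grid_size)) grid_size <- 2L * ceiling(rmax / pixel_pitch) + 2L
  half <- (grid_size - 1) / 2 * pixel_pitch
  if (rmax > half) stop("grid too small for the layout")
  discs <- data.frame(cx = layout$cx, cy = layout$cy,
                      radius = layout$diameter / 2, amp = layout$contrast_hu)
  sig <- render_discs(grid_size, grid_size, pixel_pitch, discs,
                      truth$psf_sigma, background = truth$background_hu)
  vox <- array(0, c(grid_size, grid_size, n_slices))
  for (k in seq_len(n_slices)) vox[, , k] <- sig
  if (truth$noise_sigma_white > 0 && noise_scale > 0)
    with_seed(truth$rng_seed + seed_offset, {
      for (k in seq_len(n_slices))
        vox[, , k] <- vox[, , k] +
          correlated_noise(grid_size, grid_size,
                           noise_scale * truth$noise_sigma_white,
                           truth$noise_kernel)
    })
  attach_truth(image_volume(vox, pixel_pitch, pixel_pitch),
               truth, list(lc_layout = layout))
}

#' Simulate an HU-insert (sensitometry) module
#'
#' Cylindrical inserts at known positions on a ring, with nominal HU values
#' from `truth$insert_hus`, blurred by the PSF, plus optional noise.
#'
#' @inheritParams simulate_wire_image
#' @param materials Which inserts to place; defaults to all materials in
#'   `truth$insert_hus`. Unknown names are an error.
#' @param insert_radius Insert radius, mm.
#' @param ring_radius Radius of the ring of insert centres, mm.
#' @param n_slices Number of slices.
#' @param noise Add noise?
#' @return An [image_volume()] with `$truth` (including `$insert_layout`).
#' @export
simulate_insert_module <- function(truth, grid_size = 160L, pixel_pitch = 0.5,
                                   materials = names(truth$insert_hus),
                                   insert_radius = 6, ring_radius = 25,
                                   n_slices = 1L, noise = FALSE) {
  stopifnot(inherits(truth, "phantom_truth"))
  unknown <- setdiff(materials, names(truth$insert_hus))
  if (length(unknown))
    stop("unknown material key: ", paste(unknown, collapse = ", "))
  m <- length(materials)
  ang <- 2 * pi * (seq_len(m) - 1) / m
  layout <- data.frame(material = materials,
                       cx = ring_radius * cos(ang),
                       cy = ring_radius * sin(ang),
                       radius = insert_radius,
                       nominal_hu = unname(truth$insert_hus[materials]))
  if (m > 1 && 2 * ring_radius * sin(pi / m) < 2 * insert_radius + 2)
    stop("inserts overlap on the ring")
  discs <- data.frame(cx = layout$cx, cy = layout$cy, radius = layout$radius,
                      amp = layout$nominal_hu - truth$background_hu)
  sig <- render_discs(grid_size, grid_size, pixel_pitch, discs,
                      truth$psf_sigma, background = truth$background_hu)
  vox <- array(0, c(grid_size, grid_size, n_slices))
  for (k in seq_len(n_slices)) vox[, , k] <- sig
  if (noise && truth$noise_sigma_white > 0)
    with_seed(truth$rng_seed, {
      for (k in seq_len(n_slices))
        vox[, , k] <- vox[, , k] +
          correlated_noise(grid_size, grid_size, truth$noise_sigma_white,
                           truth$noise_kernel)
    })
  attach_truth(image_volume(vox, pixel_pitch, pixel_pitch),
               truth, list(insert_layout = layout))
}
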