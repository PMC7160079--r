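#' Modulation transfer function curve
#'
#' @param frequencies Spatial frequencies, lp/mm, ascending from 0.
#' @param modulation Modulation values; 1 at zero frequency.
#' @param method Label: `"wire"` or `"edge"`.
#' @return An object of class `mtf_curve`.
#' @export
mtf_curve <- function(frequencies, modulation, method = NA_character_) {
  stopifnot(length(frequencies) == length(modulation),
            !is.unsorted(frequencies, strictly = TRUE))
  structure(list(frequencies = frequencies, modulation = modulation,
                 method = method), class = "mtf_curve")
}

#' @export
print.mtf_curve <- function(x, ...) {
  cat(sprintf("<mtf_curve> %s method, %d samples, 0-%.3g lp/mm\n",
              x$method, length(x$frequencies), max(x$frequencies)))
  f50 <- tryCatch(mtf_percent_frequency(x, 50), error = function(e) NA)
  if (!is.na(f50)) cat(sprintf("  f50 = %.3g lp/mm\n", f50))
  invisible(x)
}

# |sinc| pixel-aperture MTF of the sampling grid (area-averaged pixels)
aperture_mtf <- function(f, a) {
  out <- rep(1, length(f))
  nz <- f != 0
  out[nz] <- abs(sin(pi * f[nz] * a) / (pi * f[nz] * a))
  out
}

# finite-wire aperture MTF |2 J1(pi f d) / (pi f d)|
wire_aperture_mtf <- function(f, d) {
  out <- rep(1, length(f))
  nz <- f != 0
  u <- pi * f[nz] * d
  out[nz] <- abs(2 * besselJ(u, 1) / u)
  out
}

# DFT frequencies (cycles per mm) for n samples at spacing h, unshifted order
fft_freq <- function(n, h) {
  k <- seq_len(n) - 1
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / (n * h)
}

#' MTF by the thin-wire (point) method
#'
#' Locates the wire by intensity-weighted centroid, crops a square ROI around
#' it, subtracts a background annulus, zero-pads, takes the 2D DFT magnitude
#' and radially averages it. The finite diameter of the wire and the pixel
#' sampling aperture of the reconstruction grid are both deconvolved by
#' closed-form division (each is optional), then the curve is normalised to 1
#' at zero frequency and truncated at the Nyquist frequency.
#'
#' @param vol An [image_volume()] containing a single bright wire.
#' @param search_roi Optional [circular_roi()] restricting the wire search.
#' @param opts List of options: `crop` (ROI side, px, default 32), `pad`
#'   (zero-padded DFT size, default 256), `annulus` (inner/outer background
#'   annulus radii in px, default `c(8, 12)`), `bin` (radial bin width,
#'   lp/mm, default `1/(pad*dx)`), `correct_wire` (default `TRUE`),
#'   `wire_diameter` (mm, default 0.05), `correct_aperture` (default `TRUE`),
#'   `slice` (default 1).
#' @return An [mtf_curve()].
#' @export
mtf_from_wire <- function(vol, search_roi = NULL, opts = list()) {
  stopifnot(inherits(vol, "image_volume"))
  if (abs(vol$dx - vol$dy) > 1e-9)
    stop("wire MTF requires isotropic in-plane pixels")
  o <- utils::modifyList(
    list(crop = 32L, pad = 256L, annulus = c(8, 12), bin = NULL,
         correct_wire = TRUE, wire_diameter = 0.05,
         correct_aperture = TRUE, slice = 1L), opts)
  img <- vol$voxels[, , o$slice]
  mask <- if (is.null(search_roi)) matrix(TRUE, nrow(img), ncol(img))
          else roi_mask(vol, search_roi)
  region <- img[mask]
  bg <- stats::median(region)
  noise <- stats::mad(region)
  pk <- max(img[mask])
  if (pk - bg <= 5 * noise)
    stop("no wire found: peak is not 5 SD above background")
  idx <- which(img == pk & mask, arr.ind = TRUE)[1, ]
  # intensity-weighted centroid in a local window
  hw <- o$crop %/% 2
  ri <- max(1, idx[1] - hw):min(nrow(img), idx[1] + hw)
  ci <- max(1, idx[2] - hw):min(ncol(img), idx[2] + hw)
  w <- pmax(img[ri, ci] - bg, 0)
  cr <- sum(row(w) * w) / sum(w) + ri[1] - 1
  cc <- sum(col(w) * w) / sum(w) + ci[1] - 1
  r0 <- round(cr); c0 <- round(cc)
  if (r0 - hw < 3 || r0 + hw - 1 > nrow(img) - 2 ||
      c0 - hw < 3 || c0 + hw - 1 > ncol(img) - 2)
    stop("wire too close to the image border for the requested crop")
  rows <- (r0 - hw):(r0 + hw - 1)
  cols <- (c0 - hw):(c0 + hw - 1)
  crop <- img[rows, cols]
  # background from a surrounding annulus (pixel units, centred on the wire)
  dpx <- sqrt(outer((rows - cr)^2, (cols - cc)^2, `+`))
  ann <- dpx >= o$annulus[1] & dpx <= o$annulus[2]
  if (!any(ann)) stop("background annulus empty; enlarge the crop")
  crop <- crop - mean(crop[ann])
  padded <- matrix(0, o$pad, o$pad)
  padded[seq_len(nrow(crop)), seq_len(ncol(crop))] <- crop
  F2 <- Mod(stats::fft(padded))
  fx <- fft_freq(o$pad, vol$dx)
  fr <- sqrt(outer(fx^2, fx^2, `+`))   # row freqs vary along y; |f| symmetric
  binw <- o$bin %||% (1 / (o$pad * vol$dx))
  bin <- round(as.vector(fr) / binw)
  mag <- tapply(as.vector(F2), bin, mean)       # empty bins never appear
  freq <- as.numeric(names(mag)) * binw
  ord <- order(freq)
  freq <- freq[ord]; mag <- as.numeric(mag[ord])
  if (o$correct_wire) mag <- mag / wire_aperture_mtf(freq, o$wire_diameter)
  if (o$correct_aperture) mag <- mag / aperture_mtf(freq, vol$dx)
  mag <- mag / mag[1]
  keep <- freq <= 1 / (2 * max(vol$dx, vol$dy)) + 1e-12
  mtf_curve(freq[keep], mag[keep], method = "wire")
}

# Kasa algebraic circle fit; returns centre, radius, rms residual
circle_fit <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  sol <- qr.solve(A, x^2 + y^2)
  cx <- sol[1]; cy <- sol[2]
  R <- sqrt(sol[3] + cx^2 + cy^2)
  res <- sqrt(mean((sqrt((x - cx)^2 + (y - cy)^2) - R)^2))
  list(cx = cx, cy = cy, radius = R, residual = res)
}

# bilinear interpolation of img (physical coords as in pixel_x/pixel_y)
interp_image <- function(vol, img, xq, yq) {
  x <- pixel_x(vol); y <- pixel_y(vol)
  cj <- (xq - x[1]) / vol$dx + 1
  ri <- (y[1] - yq) / vol$dy + 1
  j0 <- pmin(pmax(floor(cj), 1), ncol(img) - 1)
  i0 <- pmin(pmax(floor(ri), 1), nrow(img) - 1)
  tx <- cj - j0; ty <- ri - i0
  img[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
    img[cbind(i0, j0 + 1)] * tx * (1 - ty) +
    img[cbind(i0 + 1, j0)] * (1 - tx) * ty +
    img[cbind(i0 + 1, j0 + 1)] * tx * ty
}

#' MTF by the circular-edge method
#'
#' Estimates the rod centre (thresholded centroid refined by a circle fit to
#' the half-maximum contour), bins all pixel values by radial distance into
#' an oversampled edge spread function, differentiates to the line spread
#' function, applies a Hann window about the LSF peak, and takes the DFT
#' magnitude. The pixel sampling aperture is optionally deconvolved; the
#' curve is normalised at zero frequency and truncated at Nyquist.
#'
#' @param vol An [image_volume()] containing one high-contrast disc.
#' @param opts Options: `oversample` (radial bins per pixel, default 8),
#'   `window` (Hann window full width, mm, default 8), `n_rays` (contour rays
#'   for the circle fit, default 360), `pad` (DFT length, default 2048),
#'   `correct_aperture` (default `TRUE`), `max_residual` (circle-fit RMS
#'   residual limit in px, default 0.5), `slice` (default 1).
#' @return An [mtf_curve()].
#' @export
mtf_from_circular_edge <- function(vol, opts = list()) {
  stopifnot(inherits(vol, "image_volume"))
  if (abs(vol$dx - vol$dy) > 1e-9)
    stop("edge MTF requires isotropic in-plane pixels")
  o <- utils::modifyList(
    list(oversample = 8L, window = 8, n_rays = 360L, pad = 2048L,
         correct_aperture = TRUE, max_residual = 0.5, slice = 1L), opts)
  img <- vol$voxels[, , o$slice]
  border <- c(img[1, ], img[nrow(img), ], img[, 1], img[, ncol(img)])
  bg <- stats::median(border)
  hi <- max(img)
  if (hi - bg < 10) stop("no high-contrast disc found")
  thr <- (hi + bg) / 2
  inside <- img > thr
  if (any(inside[1, ]) || any(inside[nrow(img), ]) ||
      any(inside[, 1]) || any(inside[, ncol(img)]))
    stop("rod truncated by the image border")
  x <- pixel_x(vol); y <- pixel_y(vol)
  cx0 <- sum(outer(rep(1, nrow(img)), x)[inside]) / sum(inside)
  cy0 <- sum(outer(y, rep(1, ncol(img)))[inside]) / sum(inside)
  r0 <- sqrt(sum(inside) * vol$dx * vol$dy / pi)
  # half-maximum contour points along rays
  ang <- 2 * pi * (seq_len(o$n_rays) - 1) / o$n_rays
  rs <- seq(0.5 * r0, 1.5 * r0, by = vol$dx / 4)
  px <- py <- numeric(0)
  for (a in ang) {
    prof <- interp_image(vol, img, cx0 + rs * cos(a), cy0 + rs * sin(a))
    k <- which(prof[-length(prof)] >= thr & prof[-1] < thr)
    if (!length(k)) next
    k <- k[1]
    t <- (thr - prof[k]) / (prof[k + 1] - prof[k])
    rc <- rs[k] + t * (rs[k + 1] - rs[k])
    px <- c(px, cx0 + rc * cos(a)); py <- c(py, cy0 + rc * sin(a))
  }
  if (length(px) < 8) stop("too few edge points for the circle fit")
  fit <- circle_fit(px, py)
  if (fit$residual / vol$dx > o$max_residual)
    stop(sprintf("circle fit residual %.2f px exceeds %.2f px",
                 fit$residual / vol$dx, o$max_residual))
  # oversampled radial ESF
  rr <- sqrt(outer((y - fit$cy)^2, (x - fit$cx)^2, `+`))
  L <- o$window / 2 + 2
  sel <- rr >= max(0, fit$radius - L) & rr <= fit$radius + L
  w <- vol$dx / o$oversample
  bin <- floor(rr[sel] / w)
  esf <- tapply(img[sel], bin, mean)
  bidx <- as.numeric(names(esf))
  full <- seq(min(bidx), max(bidx))
  rmid <- (full + 0.5) * w
  ev <- rep(NA_real_, length(full))
  ev[match(bidx, full)] <- esf
  if (anyNA(ev))   # fill empty oversampled bins by linear interpolation
    ev <- stats::approx(rmid[!is.na(ev)], ev[!is.na(ev)], xout = rmid,
                        rule = 2)$y
  lsf <- (ev[-(1:2)] - ev[seq_len(length(ev) - 2)]) / (2 * w)
  rl <- rmid[-c(1, length(rmid))]
  pk <- rl[which.max(abs(lsf))]
  hann <- ifelse(abs(rl - pk) <= o$window / 2,
                 0.5 * (1 + cos(2 * pi * (rl - pk) / o$window)), 0)
  lsf <- lsf * hann
  n <- max(o$pad, length(lsf))
  padded <- c(lsf, rep(0, n - length(lsf)))
  mag <- Mod(stats::fft(padded))
  freq <- (seq_len(n) - 1) / (n * w)
  keep <- freq <= 1 / (2 * vol$dx) + 1e-12
  freq <- freq[keep]; mag <- mag[keep]
  if (o$correct_aperture) mag <- mag / aperture_mtf(freq, vol$dx)
  mag <- mag / mag[1]
  mtf_curve(freq, mag, method = "edge")
}

#' Frequency at which the MTF falls to a given percentage
#'
#' Walks the curve upward in frequency and returns the first downward
#' crossing of `percent/100`, located by linear interpolation between the
#' bracketing samples.
#'
#' @param curve An [mtf_curve()].
#' @param percent Threshold in percent, in (0, 100).
#' @return Frequency, lp/mm.
#' @export
mtf_percent_frequency <- function(curve, percent) {
  stopifnot(inherits(curve, "mtf_curve"), percent > 0, percent < 100)
  p <- percent / 100
  m <- curve$modulation; f <- curve$frequencies
  for (i in seq_along(m)[-1]) {
    if (m[i - 1] > p && m[i] <= p) {
      return(f[i - 1] + (p - m[i - 1]) / (m[i] - m[i - 1]) * (f[i] - f[i - 1]))
    }
  }
  stop(sprintf("threshold not reached: MTF never falls to %g%% below Nyquist",
               percent))
}

#' Edge MTF as a function of off-centre position
#'
#' Applies [mtf_from_circular_edge()] to one rod volume per labelled offset,
#' for resolution-falloff reporting.
#'
#' @param volumes_by_offset Named list of [image_volume()]s; names are offsets
#'   in mm (e.g. `"0"`, `"50"`, `"100"`).
#' @param opts Passed to [mtf_from_circular_edge()].
#' @return List with `curves` (named list of [mtf_curve()]) and `summary`
#'   (data.frame of offset and f50).
#' @export
mtf_vs_position <- function(volumes_by_offset, opts = list()) {
  stopifnot(is.list(volumes_by_offset), length(volumes_by_offset) > 0,
            !is.null(names(volumes_by_offset)))
  curves <- lapply(names(volumes_by_offset), function(nm) {
    tryCatch(mtf_from_circular_edge(volumes_by_offset[[nm]], opts),
             error = function(e)
               stop("offset ", nm, " mm: ", conditionMessage(e)))
  })
  names(curves) <- names(volumes_by_offset)
  f50 <- vapply(curves, mtf_percent_frequency, numeric(1), percent = 50)
  list(curves = curves,
       summary = data.frame(offset_mm = as.numeric(names(curves)),
                            f50 = unname(f50)))
}
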