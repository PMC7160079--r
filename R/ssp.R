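#' Slice sensitivity profile from a thin-foil z-stack
#'
#' Plots the mean HU inside an in-plane circular ROI against longitudinal
#' position, subtracts the background estimated from the outer 10% of slices
#' at each end of the stack, and peak-normalises the result.
#'
#' @param vol An [image_volume()] foil stack.
#' @param roi A [circular_roi()] inside the disc footprint; default a
#'   23-voxel-diameter ROI at the in-plane centre.
#' @param tail_fraction Fraction of slices at each end used for the
#'   background estimate (default 0.1).
#' @return An object of class `ssp_curve` with fields `z` (mm), `response`
#'   (peak 1) and `fwhm` (mm).
#' @export
ssp_from_foil <- function(vol, roi = NULL, tail_fraction = 0.1) {
  stopifnot(inherits(vol, "image_volume"))
  n <- dim(vol$voxels)[3]
  if (n < 10) stop("foil stack too short")
  if (is.null(roi)) roi <- circular_roi(0, 0, 23 * vol$dx)
  z <- slice_z(vol)
  mask <- roi_mask(vol, roi)
  resp <- vapply(seq_len(n), function(k) mean(vol$voxels[, , k][mask]),
                 numeric(1))
  nt <- max(1L, floor(tail_fraction * n))
  bgr <- mean(resp[c(seq_len(nt), seq(n - nt + 1, n))])
  resp <- resp - bgr
  ipk <- which.max(resp)
  if (ipk == 1L || ipk == n)
    stop("no interior peak: profile maximum sits on the first/last slice")
  resp <- resp / resp[ipk]
  structure(list(z = z, response = resp,
                 fwhm = fwhm_of(z, resp, ipk)),
            class = "ssp_curve")
}

#' @export
print.ssp_curve <- function(x, ...) {
  cat(sprintf("<ssp_curve> %d slices, dz=%.4g mm, FWHM = %.4g mm\n",
              length(x$z), diff(x$z[1:2]), x$fwhm))
  invisible(x)
}

# half-maximum crossings nearest the peak, walking outward, linear interp
fwhm_of <- function(z, resp, ipk = which.max(resp)) {
  half <- resp[ipk] / 2
  left <- NA_real_
  for (i in seq(ipk, 2)) {
    if (resp[i - 1] < half && resp[i] >= half) {
      left <- z[i - 1] + (half - resp[i - 1]) / (resp[i] - resp[i - 1]) *
        (z[i] - z[i - 1])
      break
    }
  }
  right <- NA_real_
  for (i in seq(ipk, length(z) - 1)) {
    if (resp[i] >= half && resp[i + 1] < half) {
      right <- z[i] + (half - resp[i]) / (resp[i + 1] - resp[i]) *
        (z[i + 1] - z[i])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop("profile does not cross half maximum on both sides of the peak")
  right - left
}

#' Full width at half maximum of a profile
#'
#' Distance between the two half-maximum crossings nearest the peak, each
#' located by linear interpolation, walking outward from the peak (robust to
#' noisy secondary crossings in the tails).
#'
#' @param curve An `ssp_curve`, or a list/data.frame with `z` and `response`.
#' @return FWHM in the units of `z`.
#' @export
fwhm <- function(curve) {
  z <- curve$z; resp <- curve$response
  stopifnot(length(z) == length(resp), length(z) >= 3)
  fwhm_of(z, resp)
}
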