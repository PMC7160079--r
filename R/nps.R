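# Noise power spectrum estimation on uniform-phantom stacks.
#
# Conventions: the 2D NPS of an Nx x Ny ROI with pixel area dx*dy is
#   NPS(fx, fy) = dx*dy / (Nx*Ny) * |DFT2(detrended ROI)|^2       [HU^2 mm^2]
# averaged over ROIs and slices. With this normalisation Parseval gives
#   sum(NPS) * dfx * dfy = variance of the detrended noise,
# where dfx = 1/(Nx dx), dfy = 1/(Ny dy).

# order-2 2D polynomial detrend; design matrix cached per ROI size
detrend_poly2 <- local({
  cache <- list()
  function(roi) {
    n <- nrow(roi); m <- ncol(roi)
    key <- paste(n, m)
    if (is.null(cache[[key]])) {
      u <- (row(roi) - (n + 1) / 2) / n
      v <- (col(roi) - (m + 1) / 2) / m
      X <- cbind(1, as.vector(u), as.vector(v), as.vector(u)^2,
                 as.vector(u * v), as.vector(v)^2)
      cache[[key]] <<- list(X = X, XtXi = solve(crossprod(X)))
    }
    cc <- cache[[key]]
    y <- as.vector(roi)
    matrix(y - cc$X %*% (cc$XtXi %*% crossprod(cc$X, y)), n, m)
  }
})

# top-left corners of a square ROI grid with the given overlap
roi_grid <- function(n_row, n_col, size, overlap = 0.5) {
  step <- max(1L, as.integer(round(size * (1 - overlap))))
  r0 <- seq(1L, n_row - size + 1L, by = step)
  c0 <- seq(1L, n_col - size + 1L, by = step)
  expand.grid(r = r0, c = c0)
}

# slice indices separated by at least `gap` slices, at most `max_n` of them
select_slices <- function(n, gap, max_n = 3L) {
  idx <- seq(1L, n, by = gap + 1L)
  utils::head(idx, max_n)
}

#' 2D noise power spectrum of uniform volumes
#'
#' Unsubtracted mode: each ROI is detrended with a fitted 2D second-order
#' polynomial and its scaled periodogram accumulated. Subtracted mode: slices
#' at identical positions from consecutive pairs of volumes are differenced,
#' the same periodogram is accumulated, and the result is divided by 2
#' (variance of a difference of i.i.d. fields). Used slices within one volume
#' are separated by at least `opts$slice_gap` slices to minimise longitudinal
#' noise correlation.
#'
#' @param volumes An [image_volume()] or list of them (>= 2 for subtracted
#'   mode; subtracted pairs are `(1,2), (3,4), ...`).
#' @param roi_spec List: `size` (ROI side, px, default 128), `overlap`
#'   (fraction, default 0.5).
#' @param opts List: `slice_gap` (default 15), `max_slices` per volume
#'   (default 3).
#' @param mode `"unsubtracted"` or `"subtracted"`.
#' @return An object of class `nps_result` with `nps2d` (fftshift-ordered
#'   matrix, HU^2 mm^2), `fx`, `fy` (lp/mm), `nps1d` (radial average),
#'   `peak_frequency`, `noise_sd` (HU, detrended, first ROI of first used
#'   slice convention does not apply: SD is pooled over all ROIs), `n_rois`
#'   and `mode`.
#' @export
nps_2d <- function(volumes, roi_spec = list(), opts = list(),
                   mode = c("unsubtracted", "subtracted")) {
  mode <- match.arg(mode)
  if (inherits(volumes, "image_volume")) volumes <- list(volumes)
  stopifnot(all(vapply(volumes, inherits, TRUE, "image_volume")))
  if (mode == "subtracted" && length(volumes) < 2)
    stop("subtracted mode requires at least two volumes")
  rs <- utils::modifyList(list(size = 128L, overlap = 0.5), roi_spec)
  o <- utils::modifyList(list(slice_gap = 15L, max_slices = 3L), opts)
  v1 <- volumes[[1]]
  d <- dim(v1$voxels)
  if (rs$size > min(d[1], d[2])) stop("ROI grid empty: ROI larger than image")
  grid <- roi_grid(d[1], d[2], rs$size, rs$overlap)
  if (nrow(grid) == 0) stop("ROI grid empty")
  slices <- select_slices(d[3], o$slice_gap, o$max_slices)
  dx <- v1$dx; dy <- v1$dy
  scale <- dx * dy / (rs$size^2)
  acc <- matrix(0, rs$size, rs$size)
  var_acc <- 0
  n_rois <- 0L

  take <- function(img, g) img[g$r:(g$r + rs$size - 1L),
                               g$c:(g$c + rs$size - 1L)]
  if (mode == "unsubtracted") {
    for (vol in volumes) for (k in slices) {
      img <- vol$voxels[, , k]
      for (i in seq_len(nrow(grid))) {
        roi <- detrend_poly2(take(img, grid[i, ]))
        acc <- acc + Mod(stats::fft(roi))^2
        var_acc <- var_acc + sum(roi^2) / (length(roi) - 1)
        n_rois <- n_rois + 1L
      }
    }
  } else {
    pairs <- matrix(seq_len(2 * (length(volumes) %/% 2)), ncol = 2,
                    byrow = TRUE)
    for (p in seq_len(nrow(pairs))) for (k in slices) {
      img <- volumes[[pairs[p, 1]]]$voxels[, , k] -
        volumes[[pairs[p, 2]]]$voxels[, , k]
      for (i in seq_len(nrow(grid))) {
        roi <- take(img, grid[i, ])
        roi <- roi - mean(roi)
        acc <- acc + Mod(stats::fft(roi))^2 / 2
        var_acc <- var_acc + sum(roi^2) / (length(roi) - 1) / 2
        n_rois <- n_rois + 1L
      }
    }
  }
  nps2d <- scale * acc / n_rois
  # reorder to fftshifted axes
  sh <- function(n) c(seq(ceiling(n / 2) + 1, n), seq_len(ceiling(n / 2)))
  nps2d <- nps2d[sh(rs$size), sh(rs$size)]
  fy <- sort(fft_freq(rs$size, dy))
  fx <- sort(fft_freq(rs$size, dx))
  nps1d <- radial_average_freq(nps2d, fx, fy)
  structure(list(nps2d = nps2d, fx = fx, fy = fy, nps1d = nps1d,
                 peak_frequency = peak_frequency(nps1d),
                 noise_sd = sqrt(var_acc / n_rois),
                 n_rois = n_rois, mode = mode),
            class = "nps_result")
}

#' @export
print.nps_result <- function(x, ...) {
  cat(sprintf("<nps_result> %s, %d ROIs, noise SD %.2f HU, peak %.3g lp/mm\n",
              x$mode, x$n_rois, x$noise_sd, x$peak_frequency))
  invisible(x)
}

radial_average_freq <- function(nps2d, fx, fy) {
  df <- min(diff(fx)[1], diff(fy)[1])
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  bin <- round(as.vector(fr) / df)
  keep <- bin > 0                      # exclude the zero-frequency bin
  pw <- tapply(as.vector(nps2d)[keep], bin[keep], mean)
  data.frame(frequency = as.numeric(names(pw)) * df,
             power = as.numeric(pw))
}

#' Radially averaged 1D NPS
#'
#' Bins `|f|` into rings one DFT frequency step wide and averages the power
#' in each ring; the zero-frequency bin is excluded.
#'
#' @param nps An `nps_result` (or a list with `nps2d`, `fx`, `fy`).
#' @return data.frame with `frequency` (lp/mm) and `power` (HU^2 mm^2).
#' @export
radial_average <- function(nps) {
  stopifnot(!is.null(nps$nps2d), !is.null(nps$fx), !is.null(nps$fy))
  radial_average_freq(nps$nps2d, nps$fx, nps$fy)
}

#' Peak frequency of a 1D NPS
#'
#' Frequency of the maximum-power bin; ties resolve to the lowest frequency.
#'
#' @param nps1d data.frame with `frequency` and `power`.
#' @return Frequency, lp/mm.
#' @export
peak_frequency <- function(nps1d) {
  stopifnot(nrow(nps1d) > 0)
  if (all(nps1d$power == 0)) stop("all-zero NPS curve has no peak")
  nps1d$frequency[which.max(nps1d$power)]
}

#' Noise magnitude (standard deviation) in a ROI
#'
#' Sample SD (n-1 denominator) of the ROI pixels after removing a fitted
#' order-2 2D polynomial, the same detrending used by the unsubtracted NPS.
#' ROIs too small to support the 6-term fit (< 18 pixels) are mean-subtracted
#' only.
#'
#' @param vol An [image_volume()].
#' @param roi A [circular_roi()].
#' @return Noise SD, HU.
#' @export
noise_sd <- function(vol, roi) {
  stopifnot(inherits(vol, "image_volume"), inherits(roi, "circular_roi"))
  mask <- roi_mask(vol, roi)
  slices <- roi$slices %||% 1L
  vals <- vol$voxels[, , slices[1]][mask]
  if (length(vals) < 2) stop("ROI must contain at least 2 pixels")
  if (length(vals) >= 18) {
    x <- pixel_x(vol); y <- pixel_y(vol)
    xx <- outer(rep(1, length(y)), x)[mask]
    yy <- outer(y, rep(1, length(x)))[mask]
    X <- cbind(1, xx, yy, xx^2, xx * yy, yy^2)
    vals <- vals - X %*% qr.solve(crossprod(X), crossprod(X, vals))
  } else {
    vals <- vals - mean(vals)
  }
  sqrt(sum(vals^2) / (length(vals) - 1))
}
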