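#' ACR-style CT-number uniformity test
#'
#' Places a centre ROI at the image centre and four peripheral ROIs at the
#' 12, 3, 6 and 9 o'clock positions, at a radius of
#' `phantom_diameter/2 - edge_margin - roi_diameter/2`, on the chosen slice.
#' The test passes when every peripheral mean is within `limit` HU of the
#' centre mean.
#'
#' @param vol An [image_volume()] of a uniform phantom.
#' @param phantom_diameter Phantom diameter, mm (default 320, a standard
#'   water phantom).
#' @param roi_diameter ROI diameter, mm (default 32).
#' @param limit Tolerance, HU (default 5, the ACR limit).
#' @param edge_margin Distance kept between ROI edge and phantom edge, mm.
#' @param slice Slice index; default the central slice.
#' @return An object of class `uniformity_report` with `centre_mean`,
#'   `peripheral_means` (named "12", "3", "6", "9"), `diffs`, `limit`,
#'   `pass`.
#' @export
uniformity_test <- function(vol, phantom_diameter = 320, roi_diameter = 32,
                            limit = 5, edge_margin = 10, slice = NULL) {
  stopifnot(inherits(vol, "image_volume"))
  slice <- slice %||% ((dim(vol$voxels)[3] + 1L) %/% 2L)
  rr <- phantom_diameter / 2 - edge_margin - roi_diameter / 2
  if (rr <= 0) stop("ROI does not fit inside the phantom")
  pos <- list(`12` = c(0, rr), `3` = c(rr, 0),
              `6` = c(0, -rr), `9` = c(-rr, 0))
  mean_roi <- function(cx, cy) {
    roi <- circular_roi(cx, cy, roi_diameter, slices = slice)
    mean(extract_roi_pixels(vol, roi))
  }
  centre <- mean_roi(0, 0)
  periph <- vapply(pos, function(p) mean_roi(p[1], p[2]), numeric(1))
  diffs <- periph - centre
  structure(list(centre_mean = centre, peripheral_means = periph,
                 diffs = diffs, limit = limit,
                 pass = all(abs(diffs) <= limit)),
            class = "uniformity_report")
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat(sprintf("<uniformity_report> centre %.2f HU; diffs: %s; %s\n",
              x$centre_mean,
              paste(sprintf("%s=%.2f", names(x$diffs), x$diffs),
                    collapse = ", "),
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Expected CT-number ranges for standard materials
#'
#' ACR-style closed intervals (HU) used by [ct_number_check()].
#'
#' @return data.frame with `material`, `lo`, `hi`.
#' @export
default_material_ranges <- function() {
  data.frame(material = c("air", "ldpe", "water", "acrylic", "teflon"),
             lo = c(-1005, -107, -7, 110, 850),
             hi = c(-970, -84, 7, 135, 970))
}

#' CT-number accuracy check against material ranges
#'
#' A material passes when `lo <= measured <= hi` (bounds inclusive).
#'
#' @param measured Named numeric vector of measured HU per material.
#' @param ranges data.frame with `material`, `lo`, `hi`; defaults to
#'   [default_material_ranges()].
#' @return data.frame with `material`, `value`, `lo`, `hi`, `pass`.
#' @export
ct_number_check <- function(measured, ranges = default_material_ranges()) {
  stopifnot(is.numeric(measured), !is.null(names(measured)),
            all(ranges$lo <= ranges$hi))
  missing <- setdiff(names(measured), ranges$material)
  if (length(missing))
    stop("no expected range for material: ", paste(missing, collapse = ", "))
  i <- match(names(measured), ranges$material)
  data.frame(material = names(measured), value = unname(measured),
             lo = ranges$lo[i], hi = ranges$hi[i],
             pass = unname(measured >= ranges$lo[i] &
                             measured <= ranges$hi[i]))
}

#' Measure insert CT numbers over a slab
#'
#' Per material, the mean HU over a circular ROI at the insert centre,
#' averaged across the slices spanning the requested slab thickness around
#' the stack centre.
#'
#' @param vol An [image_volume()] of the insert module.
#' @param insert_layout data.frame with `material`, `cx`, `cy` and (for the
#'   overlap check) `radius`; e.g. the `$truth$insert_layout` attached by
#'   [simulate_insert_module()].
#' @param roi_diameter ROI diameter, mm (default 10).
#' @param slab_thickness Slab to average over, mm; `NULL` uses all slices.
#' @return Named numeric vector of HU per material.
#' @export
measure_insert_hu <- function(vol, insert_layout, roi_diameter = 10,
                              slab_thickness = NULL) {
  stopifnot(inherits(vol, "image_volume"),
            all(c("material", "cx", "cy") %in% names(insert_layout)))
  n <- nrow(insert_layout)
  if (!is.null(insert_layout$radius) && n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      dist <- sqrt((insert_layout$cx[i] - insert_layout$cx[j])^2 +
                     (insert_layout$cy[i] - insert_layout$cy[j])^2)
      if (dist < roi_diameter / 2 + insert_layout$radius[j] ||
          dist < roi_diameter / 2 + insert_layout$radius[i])
        stop("ROI would overlap two inserts")
    }
  }
  nz <- dim(vol$voxels)[3]
  slices <- if (is.null(slab_thickness)) seq_len(nz) else {
    z <- slice_z(vol)
    zc <- mean(range(z))
    which(abs(z - zc) <= slab_thickness / 2)
  }
  if (!length(slices)) stop("slab contains no slices")
  out <- vapply(seq_len(n), function(i) {
    roi <- circular_roi(insert_layout$cx[i], insert_layout$cy[i],
                        roi_diameter, slices = slices)
    mean(extract_roi_pixels(vol, roi))
  }, numeric(1))
  stats::setNames(out, insert_layout$material)
}
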