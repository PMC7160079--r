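#' Contrast-to-noise ratio of low-contrast objects
#'
#' For each object in the layout: CNR = (mean inside a disc ROI at 0.8x the
#' object diameter - mean of a surrounding background annulus) / SD of the
#' background annulus. Slices spanning `slab_thickness` around the stack
#' centre are averaged first (slab readout).
#'
#' @param vol An [image_volume()] of a low-contrast module.
#' @param layout data.frame with `cx`, `cy`, `diameter`, `contrast_pct`
#'   (e.g. `$truth$lc_layout` from [simulate_low_contrast_module()]).
#' @param slab_thickness mm; `NULL` averages all slices.
#' @param annulus Background annulus radii as multiples of the object
#'   diameter, default `c(0.65, 0.95)`.
#' @return data.frame with `diameter`, `contrast_pct`, `mean_in`, `mean_bg`,
#'   `sd_bg`, `cnr`, `area_px` (nominal object area in pixels).
#' @export
measure_object_cnr <- function(vol, layout, slab_thickness = NULL,
                               annulus = c(0.65, 0.95)) {
  stopifnot(inherits(vol, "image_volume"),
            all(c("cx", "cy", "diameter") %in% names(layout)))
  n <- nrow(layout)
  # the annulus of object i must not reach into any neighbouring object
  if (n > 1) for (i in seq_len(n)) for (j in seq_len(n)[-i]) {
    dist <- sqrt((layout$cx[i] - layout$cx[j])^2 +
                   (layout$cy[i] - layout$cy[j])^2)
    if (dist < annulus[2] * layout$diameter[i] + 0.5 * layout$diameter[j])
      stop("background annulus overlaps a neighbouring object")
  }
  nz <- dim(vol$voxels)[3]
  slices <- if (is.null(slab_thickness)) seq_len(nz) else {
    z <- slice_z(vol)
    which(abs(z - mean(range(z))) <= slab_thickness / 2)
  }
  slab <- apply(vol$voxels[, , slices, drop = FALSE], c(1, 2), mean)
  svol <- image_volume(slab, vol$dx, vol$dy, vol$dz)
  x <- pixel_x(svol); y <- pixel_y(svol)
  out <- lapply(seq_len(n), function(i) {
    d <- layout$diameter[i]
    rr2 <- outer((y - layout$cy[i])^2, (x - layout$cx[i])^2, `+`)
    inside <- rr2 <= (0.4 * d)^2
    bg <- rr2 >= (annulus[1] * d)^2 & rr2 <= (annulus[2] * d)^2
    if (sum(inside) < 1 || sum(bg) < 2)
      stop("object too small for the pixel grid: diameter ", d, " mm")
    mi <- mean(slab[inside]); mb <- mean(slab[bg]); sb <- stats::sd(slab[bg])
    data.frame(diameter = d,
               contrast_pct = layout$contrast_pct[i] %||% NA_real_,
               mean_in = mi, mean_bg = mb, sd_bg = sb,
               cnr = if (sb > 0) (mi - mb) / sb else Inf,
               area_px = pi * (d / 2)^2 / (vol$dx * vol$dy))
  })
  do.call(rbind, out)
}

#' Count visible low-contrast objects by a Rose-like rule
#'
#' An object is visible when `CNR * sqrt(object area in pixels)` meets the
#' rule threshold. This replaces a human reader with an explicit,
#' deterministic criterion; the threshold is calibratable and no claim is
#' made of reproducing human counts.
#'
#' @param per_object Output of [measure_object_cnr()].
#' @param rule_threshold Visibility threshold (default 4.0).
#' @return An object of class `visibility_result` with `per_object`
#'   (including `visible` flags), `counts` (named by contrast level) and
#'   `rule_threshold`.
#' @export
count_visible <- function(per_object, rule_threshold = 4.0) {
  stopifnot(all(c("cnr", "area_px", "contrast_pct") %in% names(per_object)))
  per_object$visible <- per_object$cnr * sqrt(per_object$area_px) >=
    rule_threshold
  counts <- tapply(per_object$visible, per_object$contrast_pct, sum)
  structure(list(per_object = per_object,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 rule_threshold = rule_threshold),
            class = "visibility_result")
}

#' @export
print.visibility_result <- function(x, ...) {
  cat(sprintf("<visibility_result> threshold %.2f; visible per contrast: %s\n",
              x$rule_threshold,
              paste(sprintf("%s%%: %d", names(x$counts), x$counts),
                    collapse = ", ")))
  invisible(x)
}

#' Scalar visibility score
#'
#' Total number of visible objects across contrast levels (optionally
#' weighted per level), scalarising the per-contrast counts for dose
#' matching.
#'
#' @param result A `visibility_result`, or a named numeric vector of counts.
#' @param weights Optional named weights per contrast level.
#' @return Numeric score.
#' @export
visibility_score <- function(result, weights = NULL) {
  counts <- if (inherits(result, "visibility_result")) result$counts
            else result
  if (length(counts) == 0) return(0)
  if (is.null(weights)) return(sum(counts))
  stopifnot(!is.null(names(counts)), all(names(counts) %in% names(weights)))
  sum(counts * weights[names(counts)])
}

#' Dose needed to match a reference visibility score
#'
#' Given visibility scores at an ascending series of doses, finds the
#' smallest dose whose score reaches the reference score, refined by linear
#' interpolation on the score axis between the bracketing doses, and reports
#' the percent dose increase relative to `base_dose`.
#'
#' @param doses Ascending dose values (e.g. CTDIvol, mGy, or mA as a proxy).
#' @param scores Visibility score at each dose.
#' @param reference_score Score of the comparator system.
#' @param base_dose Dose the percent increase is expressed against.
#' @return An object of class `dose_match_result` with `matched_dose`,
#'   `percent_increase`, `reached` and the inputs.
#' @export
dose_match <- function(doses, scores, reference_score, base_dose) {
  if (length(doses) != length(scores)) stop("doses/scores length mismatch")
  if (is.unsorted(doses, strictly = TRUE)) stop("doses must be ascending")
  i <- which(scores >= reference_score)
  if (!length(i)) {
    return(structure(list(doses = doses, scores = scores,
                          reference_score = reference_score,
                          base_dose = base_dose, matched_dose = NA_real_,
                          percent_increase = NA_real_, reached = FALSE),
                     class = "dose_match_result"))
  }
  i <- i[1]
  matched <- if (i == 1) doses[1] else {
    doses[i - 1] + (reference_score - scores[i - 1]) /
      (scores[i] - scores[i - 1]) * (doses[i] - doses[i - 1])
  }
  structure(list(doses = doses, scores = scores,
                 reference_score = reference_score, base_dose = base_dose,
                 matched_dose = matched,
                 percent_increase = 100 * (matched / base_dose - 1),
                 reached = TRUE),
            class = "dose_match_result")
}

#' @export
print.dose_match_result <- function(x, ...) {
  if (x$reached)
    cat(sprintf("<dose_match_result> matched dose %.3g (%+.1f%% vs base)\n",
                x$matched_dose, x$percent_increase))
  else
    cat("<dose_match_result> reference score not reached on the dose grid\n")
  invisible(x)
}
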