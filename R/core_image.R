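#' CT image volume
#'
#' Container for a stack of reconstructed CT slices in Hounsfield units,
#' together with the geometry needed to interpret them physically. Voxels are
#' stored as a 3D array indexed `[row, col, slice]`; in-plane physical
#' coordinates are in mm with the origin at the image centre (a proxy for the
#' CT isocentre), x increasing with column and y increasing upwards (i.e.
#' decreasing row index).
#'
#' @param voxels 3D numeric array of HU values, `[row, col, slice]`. A matrix
#'   is promoted to a single-slice volume.
#' @param dx,dy In-plane pixel spacing, mm (strictly positive).
#' @param dz Slice increment, mm (strictly positive).
#' @param origin_z Physical z position of the first slice, mm.
#' @param meta Optional [acquisition_meta()] record.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, dx, dy, dz = dx, origin_z = 0, meta = NULL) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (!all(is.finite(voxels))) stop("voxel HU values must all be finite")
  for (s in list(dx = dx, dy = dy, dz = dz)) {
    if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
      stop("dx, dy and dz must be single strictly positive numbers")
  }
  if (!is.null(meta) && !inherits(meta, "acquisition_meta"))
    stop("meta must be an acquisition_meta object or NULL")
  structure(
    list(voxels = voxels, dx = dx, dy = dy, dz = dz,
         origin_z = origin_z, meta = meta),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d px, %d slice(s)\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing: dx=%g dy=%g dz=%g mm, origin_z=%g mm\n",
              x$dx, x$dy, x$dz, x$origin_z))
  cat(sprintf("  HU range: [%.1f, %.1f]\n",
              min(x$voxels), max(x$voxels)))
  if (!is.null(x$meta))
    cat(sprintf("  mode: %s, %g mA, %g s, pitch %g\n",
                x$meta$mode_label %||% "?", x$meta$tube_current,
                x$meta$rotation_time, x$meta$pitch))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Acquisition metadata
#'
#' Scan parameters attached to a volume. Only arithmetic actually used by the
#' metrics (effective mAs) is computed from them; the rest is provenance.
#'
#' @param tube_current Tube current, mA (>= 0).
#' @param rotation_time Gantry rotation time, s (> 0).
#' @param pitch Helical pitch, dimensionless (> 0).
#' @param kvp Tube voltage, kV.
#' @param ctdi_vol Volume CT dose index, mGy (optional).
#' @param mode_label Free-text resolution-mode label (e.g. "NR", "HR",
#'   "SHR", "MDCT").
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(tube_current, rotation_time, pitch,
                             kvp = 120, ctdi_vol = NULL, mode_label = NULL) {
  if (pitch <= 0) stop("pitch must be > 0")
  if (rotation_time <= 0) stop("rotation_time must be > 0")
  if (tube_current < 0) stop("tube_current must be >= 0")
  structure(
    list(tube_current = tube_current, rotation_time = rotation_time,
         pitch = pitch, kvp = kvp, ctdi_vol = ctdi_vol,
         mode_label = mode_label),
    class = "acquisition_meta"
  )
}

#' Effective tube current-time product
#'
#' For helical scanning, effective mAs = tube current x rotation time / pitch.
#'
#' @param meta An [acquisition_meta()] record.
#' @return Effective mAs (unrounded).
#' @export
effective_mas <- function(meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  if (meta$pitch == 0) stop("pitch must be non-zero")
  meta$tube_current * meta$rotation_time / meta$pitch
}

#' Circular region of interest
#'
#' A circle in in-plane physical coordinates (mm, origin at the image centre)
#' applied to one or more slices.
#'
#' @param cx,cy Centre, mm.
#' @param diameter Diameter, mm (> 0).
#' @param slices Integer slice index or vector of indices; `NULL` means all.
#' @return An object of class `circular_roi`.
#' @export
circular_roi <- function(cx, cy, diameter, slices = NULL) {
  if (diameter <= 0) stop("ROI diameter must be > 0")
  structure(list(cx = cx, cy = cy, diameter = diameter, slices = slices),
            class = "circular_roi")
}

# Physical x coordinates (mm) of pixel-column centres, y of pixel-row centres,
# and z of slices, under the centre-origin convention.
pixel_x <- function(vol) (seq_len(dim(vol$voxels)[2]) - 1 -
                            (dim(vol$voxels)[2] - 1) / 2) * vol$dx
pixel_y <- function(vol) ((dim(vol$voxels)[1] - 1) / 2 -
                            (seq_len(dim(vol$voxels)[1]) - 1)) * vol$dy
slice_z <- function(vol) vol$origin_z + (seq_len(dim(vol$voxels)[3]) - 1) * vol$dz

# logical mask of pixels whose centre lies within the circle (boundary
# inclusive), plus a check that the circle is inside the grid
roi_mask <- function(vol, roi) {
  x <- pixel_x(vol); y <- pixel_y(vol)
  r <- roi$diameter / 2
  if (roi$cx - r < min(x) - vol$dx / 2 || roi$cx + r > max(x) + vol$dx / 2 ||
      roi$cy - r < min(y) - vol$dy / 2 || roi$cy + r > max(y) + vol$dy / 2)
    stop("ROI extends outside the image bounds")
  outer(y - roi$cy, x - roi$cx, function(a, b) a^2 + b^2) <= r^2
}

#' Extract pixel values inside a circular ROI
#'
#' Returns the HU values of all pixels whose centre lies inside (or exactly
#' on) the ROI circle, over the requested slices.
#'
#' @param vol An [image_volume()].
#' @param roi A [circular_roi()].
#' @return Numeric vector of HU values.
#' @export
extract_roi_pixels <- function(vol, roi) {
  stopifnot(inherits(vol, "image_volume"), inherits(roi, "circular_roi"))
  mask <- roi_mask(vol, roi)
  slices <- roi$slices %||% seq_len(dim(vol$voxels)[3])
  if (any(slices < 1 | slices > dim(vol$voxels)[3]))
    stop("ROI slice index outside the stack")
  as.numeric(vapply(slices, function(k) vol$voxels[, , k][mask],
                    numeric(sum(mask))))
}

# ---- file I/O -------------------------------------------------------------
#
# Two plain interchange formats, both uint16 voxel payloads with DICOM-style
# rescale (HU = stored * slope + intercept) and a JSON sidecar carrying
# geometry and acquisition metadata:
#   "tiff" : multi-page 16-bit TIFF <base>.tif  + sidecar <base>.json
#   "raw"  : little-endian uint16   <base>.raw  + sidecar <base>.json
# Integer-valued HU round-trip bit-exactly (slope 1); non-integer HU are
# quantised over the full 16-bit range (relative error ~1e-5 of the range).

sidecar_path <- function(base) paste0(base, ".json")

choose_rescale <- function(v) {
  lo <- min(v); hi <- max(v)
  if (all(v == round(v)) && (hi - lo) <= 65535) {
    list(slope = 1, intercept = lo)
  } else {
    list(slope = if (hi > lo) (hi - lo) / 65535 else 1, intercept = lo)
  }
}

#' Write an image volume to disk
#'
#' Writes the voxel payload as uint16 with rescale slope/intercept plus a JSON
#' sidecar holding the spacing, origin, rescale and acquisition metadata.
#'
#' @param vol An [image_volume()].
#' @param path Output path base; the extension (`.tif`/`.raw`) and the
#'   `.json` sidecar are appended.
#' @param format `"tiff"` (multi-page 16-bit TIFF) or `"raw"` (little-endian
#'   uint16 stream, slice-major).
#' @return The sidecar path, invisibly.
#' @export
write_volume <- function(vol, path, format = c("tiff", "raw")) {
  stopifnot(inherits(vol, "image_volume"))
  format <- match.arg(format)
  if (length(vol$voxels) == 0) stop("cannot write an empty volume")
  if (!dir.exists(dirname(path)))
    stop("unwritable path: directory does not exist: ", dirname(path))
  rs <- choose_rescale(vol$voxels)
  stored <- round((vol$voxels - rs$intercept) / rs$slope)
  stored[stored < 0] <- 0; stored[stored > 65535] <- 65535
  d <- dim(vol$voxels)
  data_file <- paste0(path, if (format == "tiff") ".tif" else ".raw")
  if (format == "tiff") {
    pages <- lapply(seq_len(d[3]), function(k) stored[, , k] / 65535)
    tiff::writeTIFF(pages, data_file, bits.per.sample = 16L, reduce = FALSE)
  } else {
    con <- file(data_file, "wb")
    on.exit(close(con))
    # writeBin has no unsigned 16-bit type: write as int after wrapping
    x <- as.integer(stored); x[x > 32767L] <- x[x > 32767L] - 65536L
    writeBin(x, con, size = 2L, endian = "little")
  }
  side <- list(format = format, dim = d, dx = vol$dx, dy = vol$dy,
               dz = vol$dz, origin_z = vol$origin_z,
               rescale_slope = rs$slope, rescale_intercept = rs$intercept,
               meta = if (is.null(vol$meta)) NULL else unclass(vol$meta))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(sidecar_path(path))
}

#' Read an image volume from disk
#'
#' Reads a volume written by [write_volume()] (or any conforming TIFF/raw
#' stack with a JSON sidecar), applying the rescale slope/intercept to return
#' HU values. Supported formats: multi-page 16-bit TIFF + sidecar, raw uint16
#' stack + sidecar. DICOM series are not supported; convert to one of the
#' plain formats first.
#'
#' @param path Path base as given to [write_volume()] (without extension),
#'   or the path of the `.json` sidecar itself.
#' @param format_hint Optional `"tiff"` or `"raw"`; defaults to the sidecar's
#'   `format` field.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format_hint = NULL) {
  if (dir.exists(path) || grepl("\\.dcm$", path, ignore.case = TRUE))
    stop("DICOM series are not supported; supply a TIFF or raw stack with ",
         "a JSON sidecar (see write_volume)")
  base <- sub("\\.json$", "", path)
  sc <- sidecar_path(base)
  if (!file.exists(sc))
    stop("missing spacing metadata: sidecar not found: ", sc)
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (f in c("dim", "dx", "dy", "dz"))
    if (is.null(side[[f]]))
      stop("missing spacing metadata: sidecar lacks required field '", f, "'")
  if (length(side$dx) > 1 || length(side$dy) > 1)
    stop("inconsistent spacing across slices: dx/dy must be scalar")
  d <- as.integer(side$dim)
  fmt <- format_hint %||% side$format %||% "tiff"
  if (fmt == "tiff") {
    pages <- tiff::readTIFF(paste0(base, ".tif"), all = TRUE)
    if (length(pages) != d[3]) stop("slice count does not match sidecar dim")
    stored <- array(0, d)
    for (k in seq_len(d[3])) stored[, , k] <- round(pages[[k]] * 65535)
  } else if (fmt == "raw") {
    con <- file(paste0(base, ".raw"), "rb")
    on.exit(close(con))
    x <- readBin(con, "integer", n = prod(d), size = 2L, signed = FALSE,
                 endian = "little")
    if (length(x) != prod(d)) stop("raw payload shorter than sidecar dim")
    stored <- array(as.numeric(x), d)
  } else stop("unknown format: ", fmt)
  slope <- side$rescale_slope %||% 1
  intercept <- side$rescale_intercept %||% 0
  meta <- if (!is.null(side$meta))
    do.call(acquisition_meta, side$meta[!vapply(side$meta, is.null, TRUE)])
  vol <- image_volume(stored * slope + intercept, side$dx, side$dy, side$dz,
                      side$origin_z %||% 0, meta)
  vol
}
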