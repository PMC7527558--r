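#' Histogram mode of a grayscale volume-of-interest
#'
#' Returns the most frequent grayscale index among the voxels selected by
#' `voi`, the "main grayscale index" used to anchor the Hounsfield
#' calibration. Grayscale values must be non-negative integers (scanner
#' indices), as stored in reconstructed stacks. Ties are broken toward the
#' lower index.
#'
#' @param volume Integer-valued array (any dimensionality) of grayscale
#'   indices.
#' @param voi Logical array of the same shape selecting the VOI voxels.
#' @return The modal grayscale index (integer scalar).
#' @export
histogram_mode <- function(volume, voi) {
  stopifnot(is.array(volume) || is.numeric(volume))
  if (!is.logical(voi)) stop("`voi` must be a logical mask", call. = FALSE)
  if (length(voi) != length(volume)) {
    stop("`voi` and `volume` have different sizes", call. = FALSE)
  }
  vals <- volume[voi]
  if (length(vals) == 0) stop("empty VOI: no voxels selected", call. = FALSE)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("grayscale values must be non-negative integers", call. = FALSE)
  }
  tab <- table(vals)
  idx <- as.integer(names(tab))
  # which.max returns the first maximum; names are sorted ascending, so the
  # tie is broken toward the lower grayscale index
  idx[which.max(tab)]
}

#' Fit the two-point grayscale-to-Hounsfield mapping
#'
#' Solves the affine map pinned at the two calibration anchors: the water
#' grayscale index maps to 0 HU and the air grayscale index to -1000 HU.
#' With the scanner protocol used throughout (water at grayscale 133, air at
#' 9) the slope is 1000/124 HU per grayscale unit.
#'
#' @param water_gs Grayscale index of water (maps to 0 HU).
#' @param air_gs Grayscale index of air (maps to -1000 HU).
#' @return An object of class `hu_mapping` with fields `slope`, `intercept`,
#'   `water_gs`, `air_gs`.
#' @export
fit_hu_mapping <- function(water_gs, air_gs) {
  stopifnot(is.numeric(water_gs), is.numeric(air_gs),
            length(water_gs) == 1, length(air_gs) == 1)
  if (water_gs == air_gs) {
    stop("degenerate calibration: water and air anchors coincide",
         call. = FALSE)
  }
  if (air_gs > water_gs) {
    stop("invalid anchors: air grayscale exceeds water grayscale",
         call. = FALSE)
  }
  slope <- 1000 / (water_gs - air_gs)
  structure(
    list(slope = slope, intercept = -slope * water_gs,
         water_gs = water_gs, air_gs = air_gs),
    class = "hu_mapping"
  )
}

#' @export
print.hu_mapping <- function(x, ...) {
  cat(sprintf(
    "<hu_mapping> HU = %.6f * gs %+.4f  (anchors: water gs %s -> 0 HU, air gs %s -> -1000 HU)\n",
    x$slope, x$intercept, format(x$water_gs), format(x$air_gs)))
  invisible(x)
}

#' Apply a Hounsfield mapping to a grayscale volume
#'
#' Element-wise affine transform of grayscale indices to Hounsfield units.
#' HU values are kept as reals (no re-quantization); all thresholding in the
#' pipeline happens in HU space.
#'
#' @param volume Numeric array of grayscale indices.
#' @param map An `hu_mapping` from [fit_hu_mapping()].
#' @param voxel_size Isotropic voxel edge length in mm.
#' @return A `calibrated_volume`: the HU array with attributes `voxel_size`
#'   (mm) and `hu_mapping` (provenance).
#' @export
apply_hu_mapping <- function(volume, map, voxel_size) {
  stopifnot(inherits(map, "hu_mapping"))
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0) {
    stop("`voxel_size` must be a positive scalar (mm)", call. = FALSE)
  }
  hu <- volume * map$slope + map$intercept
  calibrated_volume(hu, voxel_size, map)
}

#' Construct a calibrated HU volume
#'
#' @param hu Numeric array of Hounsfield units.
#' @param voxel_size Isotropic voxel size in mm.
#' @param map Optional `hu_mapping` provenance record.
#' @return A `calibrated_volume` object.
#' @export
calibrated_volume <- function(hu, voxel_size, map = NULL) {
  if (any(!is.finite(hu))) stop("non-finite HU values", call. = FALSE)
  stopifnot(voxel_size > 0)
  structure(hu, voxel_size = voxel_size, hu_mapping = map,
            class = c("calibrated_volume", class(hu)))
}

#' @export
print.calibrated_volume <- function(x, ...) {
  cat(sprintf("<calibrated_volume> %s voxels @ %g mm, HU range [%.1f, %.1f]\n",
              paste(dim(x), collapse = "x"), attr(x, "voxel_size"),
              min(x), max(x)))
  invisible(x)
}

#' Invert a Hounsfield mapping at a threshold
#'
#' Returns the (real-valued) grayscale index whose calibrated value equals
#' `hu_threshold`; convenience inverse for QC overlays on raw stacks.
#'
#' @param map An `hu_mapping`.
#' @param hu_threshold Threshold in HU.
#' @return Grayscale value g with `g * slope + intercept == hu_threshold`.
#' @export
grayscale_threshold <- function(map, hu_threshold) {
  stopifnot(inherits(map, "hu_mapping"))
  (hu_threshold - map$intercept) / map$slope
}

#' Calibrate from a scanned phantom
#'
#' Convenience wrapper for the calibration stage: extracts the modal
#' grayscale index of the water and air VOIs of a calibration-phantom scan
#' and fits the two-point mapping.
#'
#' @param volume Grayscale phantom volume.
#' @param labels Integer label mask (see [calibration_labels()]).
#' @return An `hu_mapping`.
#' @export
calibrate_from_phantom <- function(volume, labels) {
  lab <- calibration_labels()
  water_gs <- histogram_mode(volume, labels == lab[["water"]])
  air_gs <- histogram_mode(volume, labels == lab[["air_tube"]])
  fit_hu_mapping(water_gs, air_gs)
}

#' Read/write a Hounsfield mapping as JSON
#'
#' @param map An `hu_mapping`.
#' @param path File path.
#' @return `write_hu_mapping` returns `path` invisibly; `read_hu_mapping`
#'   returns an `hu_mapping`.
#' @export
write_hu_mapping <- function(map, path) {
  stopifnot(inherits(map, "hu_mapping"))
  jsonlite::write_json(unclass(map), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hu_mapping
#' @export
read_hu_mapping <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- fit_hu_mapping(x$water_gs, x$air_gs)
  stopifnot(abs(m$slope - x$slope) < 1e-9)
  m
}
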