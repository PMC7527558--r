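#' Lung VOI from a label mask
#'
#' Builds the lung volume-of-interest by set algebra on labels: voxels whose
#' label is in `include` minus any whose label is in `exclude`. The standard
#' delineation includes aerated lung and lesions while avoiding the heart
#' and main blood vessels.
#'
#' @param labels Integer label array.
#' @param include Integer labels (or names from [thorax_labels()]) forming
#'   the VOI.
#' @param exclude Labels removed from the VOI (e.g. heart/vessels).
#' @return A `lung_voi`: logical mask with attributes recording how it was
#'   built and which structures were excluded.
#' @export
voi_from_labels <- function(labels,
                            include = c("lung_aerated", "lesion"),
                            exclude = c("heart_vessels")) {
  include <- resolve_labels(include)
  exclude <- resolve_labels(exclude)
  if (length(include) == 0) stop("`include` must be non-empty", call. = FALSE)
  if (length(intersect(include, exclude)) > 0) {
    stop("`include` and `exclude` overlap", call. = FALSE)
  }
  mask <- array(labels %in% include & !(labels %in% exclude), dim(labels))
  if (!any(mask)) stop("empty VOI: no voxels match the label sets", call. = FALSE)
  structure(mask, construction = "label-derived",
            excluded = exclude, class = c("lung_voi", "array"))
}

resolve_labels <- function(x) {
  if (is.character(x)) {
    lab <- thorax_labels()
    unknown <- setdiff(x, names(lab))
    if (length(unknown) > 0) {
      stop("unknown label name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    unname(lab[x])
  } else {
    as.integer(x)
  }
}

#' Lung VOI from an axial slab
#'
#' Mirrors the landmark-based manual delineation rule (top of the lungs at
#' the clavicle-sternum section, bottom at a plane through the liver):
#' restricts the lung compartments to axial slices `[top_slice,
#' bottom_slice]`, with exclusions applied.
#'
#' @param labels Integer label array (third axis = axial).
#' @param top_slice,bottom_slice Slice indices, `top_slice < bottom_slice`.
#' @inheritParams voi_from_labels
#' @return A `lung_voi`.
#' @export
voi_from_slab <- function(labels, top_slice, bottom_slice,
                          include = c("lung_aerated", "lesion"),
                          exclude = c("heart_vessels")) {
  nz <- dim(labels)[3]
  if (top_slice >= bottom_slice) {
    stop("range error: top_slice must be below bottom_slice", call. = FALSE)
  }
  if (top_slice < 1 || bottom_slice > nz) {
    stop("range error: slab outside the grid", call. = FALSE)
  }
  voi <- voi_from_labels(labels, include, exclude)
  keep <- array(FALSE, dim(labels))
  keep[, , top_slice:bottom_slice] <- TRUE
  mask <- voi & keep
  if (!any(mask)) stop("empty VOI: slab contains no lung voxels", call. = FALSE)
  structure(array(mask, dim(labels)), construction = "slab-delimited",
            excluded = attr(voi, "excluded"), class = c("lung_voi", "array"))
}

#' Extract the four lung biomarkers from a calibrated volume
#'
#' Computes, over the lung VOI of a calibrated end-expiration volume, the
#' four scan-derived biomarkers: mean lung density (arithmetic mean HU over
#' the whole VOI), aerated lung volume (voxels strictly below the
#' threshold), non-aerated lung volume (voxels at or above it; a voxel at
#' exactly the threshold counts non-aerated) and their sum, the total lung
#' volume. The aerated/non-aerated threshold is -223 HU, kept constant
#' across all data sets. Volumes are voxel counts times
#' `(voxel_size mm)^3 / 1000` mL.
#'
#' @param volume A `calibrated_volume` (HU array with voxel size).
#' @param voi A `lung_voi` (or logical mask) on the same grid.
#' @param threshold Aerated/non-aerated threshold in HU (default -223).
#' @return A `biomarker_set`: list with `mean_lung_density`,
#'   `aerated_volume`, `non_aerated_volume`, `total_volume` (mL),
#'   `threshold_used`, `n_voxels`.
#' @export
extract_biomarkers <- function(volume, voi, threshold = -223) {
  if (!inherits(volume, "calibrated_volume")) {
    stop("`volume` must be a calibrated_volume (apply the HU mapping first)",
         call. = FALSE)
  }
  if (!identical(dim(volume), dim(voi))) {
    stop("alignment error: VOI grid does not match the volume grid",
         call. = FALSE)
  }
  hu <- as.vector(volume)[as.vector(voi)]
  if (length(hu) == 0) stop("empty VOI", call. = FALSE)
  vv <- voxel_volume_mL(attr(volume, "voxel_size"))
  n_aer <- sum(hu < threshold)
  n_total <- length(hu)
  aerated <- n_aer * vv
  non_aerated <- (n_total - n_aer) * vv
  structure(list(
    mean_lung_density = mean(hu),
    aerated_volume = aerated,
    non_aerated_volume = non_aerated,
    # total as the sum keeps the conservation identity exact in floating point
    total_volume = aerated + non_aerated,
    threshold_used = threshold,
    n_voxels = n_total
  ), class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat(sprintf(
    "<biomarker_set> mean density %.2f HU; aerated %.6g mL + non-aerated %.6g mL = total %.6g mL (%d voxels, threshold %g HU)\n",
    x$mean_lung_density, x$aerated_volume, x$non_aerated_volume,
    x$total_volume, x$n_voxels, x$threshold_used))
  invisible(x)
}

#' Assemble per-scan biomarkers into a longitudinal table
#'
#' Stacks per-scan biomarker sets keyed by animal and week into a
#' long-format table (one row per animal x week). Missing scans are simply
#' absent rows; monotone missingness from sacrifice is allowed. Duplicate
#' (animal, week) keys are rejected.
#'
#' @param records List; each element a list with `animal`, `week`, `group`
#'   (optional) and `biomarkers` (a `biomarker_set`).
#' @return Tibble with columns `animal_id`, `group`, `week`,
#'   `mean_lung_density_hu`, `aerated_ml`, `non_aerated_ml`, `total_ml`,
#'   `threshold_hu`, `n_voxels`.
#' @export
longitudinal_table <- function(records) {
  stopifnot(length(records) > 0)
  rows <- lapply(records, function(r) {
    b <- r$biomarkers
    stopifnot(inherits(b, "biomarker_set"))
    tibble::tibble(
      animal_id = as.character(r$animal),
      group = if (is.null(r$group)) NA_character_ else as.character(r$group),
      week = as.numeric(r$week),
      mean_lung_density_hu = b$mean_lung_density,
      aerated_ml = b$aerated_volume,
      non_aerated_ml = b$non_aerated_volume,
      total_ml = b$total_volume,
      threshold_hu = b$threshold_used,
      n_voxels = b$n_voxels
    )
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out[c("animal_id", "week")]) > 0) {
    stop("integrity error: duplicate (animal, week) key", call. = FALSE)
  }
  out
}
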