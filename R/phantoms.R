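#' Label codes for generated volumes
#'
#' Integer label codes used in the masks emitted by the phantom generators.
#' `calibration_labels()` covers the water/air calibration phantom,
#' `thorax_labels()` the digital mouse thorax.
#'
#' @return Named integer vector of label codes.
#' @export
calibration_labels <- function() {
  c(background = 0L, water = 1L, air_tube = 2L)
}

#' @rdname calibration_labels
#' @export
thorax_labels <- function() {
  c(background = 0L, soft_tissue = 1L, heart_vessels = 2L,
    lung_aerated = 3L, lesion = 4L)
}

#' Specification of a synthetic scan grid and grayscale model
#'
#' Holds the voxel grid, the grayscale anchors the scanner protocol pins the
#' Hounsfield calibration to (water index 133, air index 9 in the study
#' protocol), and the additive Gaussian grayscale noise. Noise is applied in
#' grayscale units, then rounded to the nearest integer index and clipped at
#' zero, so histogram modes of homogeneous regions are preserved.
#'
#' @param grid_shape Integer vector of 3 voxel counts.
#' @param voxel_size Isotropic voxel edge length in mm (50 um = 0.05 mm at
#'   full scanner resolution; coarser grids are equivalent for the
#'   volumetric math).
#' @param water_gs,air_gs Grayscale anchors; must satisfy `water_gs > air_gs`.
#' @param noise_sd Gaussian noise SD in grayscale units (>= 0).
#' @param seed Integer seed for the noise stream.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L), voxel_size = 0.2,
                         water_gs = 133, air_gs = 9, noise_sd = 2,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  if (!(water_gs > air_gs)) {
    stop("invalid phantom spec: water_gs must exceed air_gs", call. = FALSE)
  }
  if (voxel_size <= 0) stop("voxel_size must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 water_gs = water_gs, air_gs = air_gs, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-center coordinates (mm) relative to grid center, per axis
voxel_axes <- function(spec) {
  lapply(spec$grid_shape, function(n) {
    (seq_len(n) - (n + 1) / 2) * spec$voxel_size
  })
}

# Gaussian grayscale noise, rounded to integer indices and clipped at 0
quantize_grayscale <- function(gs, noise_sd, seed, stream) {
  if (noise_sd > 0) {
    set.seed(stream_seed(seed, stream))
    gs <- gs + stats::rnorm(length(gs), sd = noise_sd)
  }
  pmax(round(gs), 0)
}

#' Generate the water/air calibration phantom
#'
#' Emulates the scanned calibration object: an air-filled tube nested inside
#' a water-filled tube, surrounded by background air. Water voxels are drawn
#' around the water grayscale anchor and air voxels around the air anchor,
#' with Gaussian noise rounded to integer grayscale.
#'
#' @param spec A [phantom_spec()]; grid must be at least 32 voxels per axis
#'   to contain the nested cylinders.
#' @return List with `volume` (integer grayscale array), `labels` (integer
#'   array, see [calibration_labels()]) and `spec`.
#' @export
make_calibration_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(spec$grid_shape < 32)) {
    stop("geometry error: grid too small for nested calibration cylinders (need >= 32 voxels per axis)",
         call. = FALSE)
  }
  ax <- voxel_axes(spec)
  half_xy <- min(spec$grid_shape[1:2]) * spec$voxel_size / 2
  r_water <- 0.88 * half_xy
  r_air <- 0.30 * half_xy
  half_z <- spec$grid_shape[3] * spec$voxel_size / 2
  z_extent <- 0.92 * half_z

  r2 <- outer(ax[[1]]^2, ax[[2]]^2, `+`)
  in_z <- abs(ax[[3]]) <= z_extent
  labels <- array(calibration_labels()[["background"]], spec$grid_shape)
  water_slice <- r2 <= r_water^2
  air_slice <- r2 <= r_air^2
  for (k in which(in_z)) {
    sl <- labels[, , k]
    sl[water_slice] <- calibration_labels()[["water"]]
    sl[air_slice] <- calibration_labels()[["air_tube"]]
    labels[, , k] <- sl
  }

  gs <- array(spec$air_gs, spec$grid_shape)
  gs[labels == calibration_labels()[["water"]]] <- spec$water_gs
  gs <- quantize_grayscale(gs, spec$noise_sd, spec$seed, "calibration")
  list(volume = array(gs, spec$grid_shape), labels = labels, spec = spec)
}

#' Specification of the digital mouse thorax
#'
#' Parameters of the synthetic thorax used in place of in-vivo scans: total
#' lung volume at end-expiration, the fraction of lung occupied by
#' hyperdense centrilobular-style lesions (modelled as non-overlapping
#' spheres), and mean HU per compartment. Compartment HU defaults straddle
#' the -223 HU aerated/non-aerated threshold by a wide margin so aerated
#' parenchyma classifies aerated and lesions non-aerated by construction;
#' in-vivo density spreads are not published, so these are plausible
#' synthetic values.
#'
#' @param lung_volume_mL Total lung VOI volume at end-expiration (mL).
#' @param lesion_fraction Fraction of the lung volume occupied by lesions,
#'   in `[0, 1)`.
#' @param lesion_count Number of spherical nodules.
#' @param lung_hu,lesion_hu,soft_tissue_hu Mean HU of aerated lung, lesion
#'   and soft tissue; must satisfy `lung_hu < -223 < lesion_hu`.
#' @param heart Logical; include a heart/vessels compartment.
#' @param seed Integer seed (lesion placement and noise).
#' @return A `thorax_spec` list.
#' @export
thorax_spec <- function(lung_volume_mL = 0.5, lesion_fraction = 0,
                        lesion_count = 8L, lung_hu = -500, lesion_hu = 30,
                        soft_tissue_hu = 40, heart = TRUE, seed = 1L) {
  if (lesion_fraction < 0 || lesion_fraction >= 1) {
    stop("lesion_fraction must be in [0, 1)", call. = FALSE)
  }
  if (!(lung_hu < -223 && -223 < lesion_hu)) {
    stop("compartment HU must straddle the -223 HU threshold (lung_hu < -223 < lesion_hu)",
         call. = FALSE)
  }
  stopifnot(lung_volume_mL > 0, lesion_count >= 1)
  structure(list(lung_volume_mL = lung_volume_mL,
                 lesion_fraction = lesion_fraction,
                 lesion_count = as.integer(lesion_count),
                 lung_hu = lung_hu, lesion_hu = lesion_hu,
                 soft_tissue_hu = soft_tissue_hu, heart = heart,
                 seed = as.integer(seed)),
            class = "thorax_spec")
}

# place n non-overlapping spheres of radius r (mm) inside the lung
# ellipsoid, by seeded rejection sampling in normalized ellipsoid
# coordinates (so placements scale with the lung across breathing phases),
# with restarts if a sequential placement jams
place_lesions <- function(n, r, semi, seed, max_iter = 30000L,
                          restarts = 10L) {
  set.seed(stream_seed(seed, "lesions"))
  margin <- 1 - r / semi  # per-axis center margin keeping spheres inside
  if (any(margin <= 0)) {
    stop("packing error: lesion radius exceeds lung extent", call. = FALSE)
  }
  for (attempt in seq_len(restarts)) {
    centers <- matrix(numeric(0), ncol = 3)
    iter <- 0L
    while (nrow(centers) < n && iter < max_iter) {
      iter <- iter + 1L
      u <- stats::runif(3, -1, 1)
      if (sum((u / margin)^2) > 1) next
      cand <- u * semi
      if (nrow(centers) > 0) {
        d2 <- colSums((t(centers) - cand)^2)
        if (any(d2 < (2 * r)^2)) next
      }
      centers <- rbind(centers, cand)
    }
    if (nrow(centers) == n) return(centers)
  }
  stop("packing error: could not place non-overlapping lesions; reduce lesion_fraction or lesion_count",
       call. = FALSE)
}

#' Generate a digital mouse thorax
#'
#' Builds a labeled grayscale volume: an elliptical soft-tissue body, a lung
#' ellipsoid whose analytic volume matches the requested lung volume, an
#' optional heart/vessel sphere outside the lung, and spherical hyperdense
#' lesions carved out of the lung by seeded rejection sampling. Compartment
#' HU values are pushed through the inverse Hounsfield mapping, noised in
#' grayscale units, and rounded. Voxels are assigned to the compartment
#' containing their center (no partial-volume mixing), so ground-truth
#' volumes are exactly label counts times the voxel volume.
#'
#' @param pspec A [phantom_spec()] (grid, anchors, noise, seed).
#' @param tspec A [thorax_spec()].
#' @param hu_map An `hu_mapping` used to convert compartment HU to
#'   grayscale; defaults to the protocol anchors (133, 9).
#' @param lung_scale Internal inflation factor applied to the aerated
#'   compartment (used by [breathing_series()]); 1 at end-expiration.
#' @return List with `volume`, `labels`, `ground_truth` (aerated_mL,
#'   lesion_mL, total_mL from label counts), `pspec`, `tspec`, `hu_map`,
#'   `lung_scale`.
#' @export
make_thorax_phantom <- function(pspec = phantom_spec(), tspec = thorax_spec(),
                                hu_map = fit_hu_mapping(133, 9),
                                lung_scale = 1) {
  stopifnot(inherits(pspec, "phantom_spec"), inherits(tspec, "thorax_spec"),
            inherits(hu_map, "hu_mapping"), lung_scale > 0)
  lab <- thorax_labels()
  ax <- voxel_axes(pspec)
  extent <- pspec$grid_shape * pspec$voxel_size
  body_semi <- c(0.44, 0.44, 0.48) * extent

  # lung ellipsoid with analytic volume = aerated target + lesion volume
  lesion_mm3 <- tspec$lesion_fraction * tspec$lung_volume_mL * 1000
  aerated_mm3 <- (1 - tspec$lesion_fraction) * tspec$lung_volume_mL * 1000 *
    lung_scale
  lung_mm3 <- aerated_mm3 + lesion_mm3
  ratios <- c(1, 0.8, 1.4)
  a1 <- (lung_mm3 * 3 / (4 * pi * prod(ratios)))^(1 / 3)
  lung_semi <- a1 * ratios
  if (any(lung_semi >= body_semi * 0.98)) {
    stop("geometry error: lung does not fit inside the body for this grid; enlarge the grid or shrink the lung",
         call. = FALSE)
  }

  # squared normalized distances to the body and lung ellipsoids
  edist2 <- function(semi, center = c(0, 0, 0)) {
    dx2 <- ((ax[[1]] - center[1]) / semi[1])^2
    dy2 <- ((ax[[2]] - center[2]) / semi[2])^2
    dz2 <- ((ax[[3]] - center[3]) / semi[3])^2
    outer(outer(dx2, dy2, `+`), dz2, `+`)
  }

  labels <- array(lab[["background"]], pspec$grid_shape)
  labels[edist2(body_semi) <= 1] <- lab[["soft_tissue"]]
  in_lung <- edist2(lung_semi) <= 1
  labels[in_lung] <- lab[["lung_aerated"]]

  if (isTRUE(tspec$heart)) {
    r_heart <- 0.30 * lung_semi[1]
    heart_center <- c(0, lung_semi[2] + 1.15 * r_heart, 0)
    in_heart <- edist2(rep(r_heart, 3), heart_center) <= 1
    labels[in_heart & !in_lung] <- lab[["heart_vessels"]]
  }

  if (tspec$lesion_fraction > 0) {
    r_les <- (3 * (lesion_mm3 / tspec$lesion_count) / (4 * pi))^(1 / 3)
    centers <- place_lesions(tspec$lesion_count, r_les, lung_semi, tspec$seed)
    for (i in seq_len(nrow(centers))) {
      in_les <- edist2(rep(r_les, 3), centers[i, ]) <= 1
      labels[in_les & in_lung] <- lab[["lesion"]]
    }
  }

  vv_mL <- pspec$voxel_size^3 / 1000
  n_aer <- sum(labels == lab[["lung_aerated"]])
  n_les <- sum(labels == lab[["lesion"]])
  ground_truth <- list(aerated_mL = n_aer * vv_mL, lesion_mL = n_les * vv_mL,
                       total_mL = (n_aer + n_les) * vv_mL)

  hu <- array(-1000, pspec$grid_shape)
  hu[labels == lab[["soft_tissue"]]] <- tspec$soft_tissue_hu
  hu[labels == lab[["heart_vessels"]]] <- tspec$soft_tissue_hu
  hu[labels == lab[["lung_aerated"]]] <- tspec$lung_hu
  hu[labels == lab[["lesion"]]] <- tspec$lesion_hu
  gs <- (hu - hu_map$intercept) / hu_map$slope
  gs <- quantize_grayscale(gs, pspec$noise_sd, pspec$seed, "thorax")

  list(volume = array(gs, pspec$grid_shape), labels = labels,
       ground_truth = ground_truth, pspec = pspec, tspec = tspec,
       hu_map = hu_map, lung_scale = lung_scale)
}

#' Thorax volumes across the breathing cycle
#'
#' Re-renders a thorax phantom at the requested respiratory phases, scaling
#' the aerated lung compartment so its analytic volume follows the breathing
#' waveform `v(phi) = V_ee * (1 + tidal_fraction * sin^2(pi * phi))`. Lesion
#' volume is held constant (solid tissue does not inflate); lesion positions
#' scale with the lung. Phase 0 (end-expiration) returns the input phantom
#' unchanged.
#'
#' @param phantom Output of [make_thorax_phantom()].
#' @param model A [respiratory_model()].
#' @param phases Numeric vector of phase fractions in `[0, 1)`.
#' @return List of phantom objects, one per phase, each carrying its `phase`.
#' @export
breathing_series <- function(phantom, model, phases) {
  stopifnot(inherits(model, "respiratory_model"))
  if (any(phases < 0 | phases >= 1)) {
    stop("phases must lie in [0, 1)", call. = FALSE)
  }
  lapply(phases, function(phi) {
    if (phi == 0 || model$tidal_fraction == 0) {
      out <- phantom
    } else {
      out <- make_thorax_phantom(phantom$pspec, phantom$tspec, phantom$hu_map,
                                 lung_scale = lung_volume_factor(phi, model))
    }
    out$phase <- phi
    out
  })
}

#' Breathing waveform volume factor
#'
#' Relative aerated lung volume at phase `phi`:
#' `1 + tidal_fraction * sin^2(pi * phi)`, minimal (1) at end-expiration.
#'
#' @param phi Phase fraction(s) in `[0, 1)`.
#' @param model A [respiratory_model()].
#' @return Numeric factor(s) >= 1.
#' @export
lung_volume_factor <- function(phi, model) {
  1 + model$tidal_fraction * sin(pi * phi)^2
}
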