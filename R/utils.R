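#' Derive a named sub-stream seed from a root seed
#'
#' All randomness in the package flows from one root seed; each stage draws
#' from its own named sub-stream so adding draws to one stage never perturbs
#' another. The sub-seed is a deterministic 31-bit hash of the root seed and
#' the stream name.
#'
#' @param seed Integer root seed.
#' @param stream Character stream name.
#' @return Integer seed in `[0, 2^31)`.
#' @export
stream_seed <- function(seed, stream) {
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(stream)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

#' Instilled particle dose
#'
#' Dose bookkeeping for the instillation protocol: instilled mass equals the
#' instilled volume times the suspension concentration. The study protocol
#' (40 uL at 0.125 mg/uL) delivers 5 mg of crystalline silica per animal.
#'
#' @param volume_uL Instilled volume in microlitres.
#' @param conc_mg_per_uL Suspension concentration in mg/uL.
#' @return Dose in mg.
#' @export
instilled_dose_mg <- function(volume_uL = 40, conc_mg_per_uL = 0.125) {
  stopifnot(volume_uL >= 0, conc_mg_per_uL >= 0)
  volume_uL * conc_mg_per_uL
}

# voxel volume in mL for an isotropic voxel edge in mm
voxel_volume_mL <- function(voxel_size_mm) voxel_size_mm^3 / 1000
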