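#' Write and read volumes as NIfTI
#'
#' Volumes and label masks are exchanged as NIfTI with the isotropic voxel
#' size recorded in the header pixdim. Grayscale/label volumes are stored as
#' unsigned 16-bit integers, calibrated HU volumes as floats.
#'
#' @param volume 3D array (grayscale indices, labels, or HU).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Isotropic voxel size in mm.
#' @param datatype NIfTI datatype; `"uint16"` for grayscale/labels,
#'   `"float"` for HU.
#' @return `write_volume` returns `path` invisibly.
#' @export
write_volume <- function(volume, path, voxel_size, datatype = "uint16") {
  img <- RNifti::asNifti(array(as.vector(volume), dim(volume)))
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname write_volume
#' @return `read_volume` returns a plain array with attribute `voxel_size`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1]
  out <- array(as.vector(img), dim(img))
  attr(out, "voxel_size") <- vs
  out
}

#' Write/read a list-mode event table as CSV
#'
#' @param events Event tibble from [make_listmode_stream()].
#' @param path File path.
#' @return `write_events` returns `path` invisibly; `read_events` a tibble.
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
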