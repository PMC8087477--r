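# NIfTI serialization for volumes and displacement fields. Fields are stored
# as 4D volumes (last axis = vector component) with a JSON sidecar recording
# the displacement units and the composition convention, so a field written
# by one tool is unambiguous to the next.

field_sidecar <- function() {
  list(
    units = "voxels",
    composition_convention =
      "compose(outer, inner)(u) = inner(u) + outer(u + inner(u)); warp(I, compose(outer, inner)) == warp(warp(I, outer), inner)",
    component_axis = "last"
  )
}

#' Write / read an intensity or label volume as NIfTI
#'
#' @param volume 2D or 3D array.
#' @param path output `.nii` / `.nii.gz` path.
#' @param spacing per-axis voxel size in mm (default 1).
#' @return `path`, invisibly (writer) or the array (reader).
#' @export
write_volume_nifti <- function(volume, path, spacing = rep(1, length(dim(volume)))) {
  check_volume(volume)
  img <- RNifti::asNifti(volume, pixdim = spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Write / read a displacement field as NIfTI plus JSON sidecar
#'
#' The field is stored as a (D+1)-dimensional volume whose last axis holds
#' the per-axis displacement components in voxel units; `<path>.json` records
#' the units and composition convention.
#'
#' @param phi displacement field array.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly (writer) or the field array (reader).
#' @export
write_field_nifti <- function(phi, path) {
  check_field(phi)
  RNifti::writeNifti(RNifti::asNifti(phi), path)
  jsonlite::write_json(field_sidecar(), paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_field_nifti
#' @export
read_field_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  check_field(arr)
  arr
}
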