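# Spatial transformation of images by displacement fields: the resampling
# layer that makes intensity-similarity losses trainable without ground-truth
# deformations.

#' Warp an image by a displacement field
#'
#' Pull-back resampling: `output(u) = sum_{v in N(u + phi(u))} I(v)
#' prod_d (1 - |u_d + phi_d(u) - v_d|)` over the 4 (2D) / 8 (3D) corner
#' voxels of the cell containing the sample point — bilinear/trilinear
#' interpolation with non-negative weights summing to 1. Sample coordinates
#' outside the grid are clamped to the boundary (border replication), so
#' warped intensities always stay within the input range. At exactly-integer
#' sample coordinates the floor-based corner cell applies and the weights
#' select the integer voxel exactly; a zero field therefore returns the input
#' bit-exact.
#'
#' @param image 2D or 3D intensity array.
#' @param phi displacement field on the same grid, voxel units.
#' @param method "linear" (default) or "nearest". Nearest-neighbour is meant
#'   for label volumes; see [warp_labels()].
#' @return Warped image, same shape as the input.
#' @export
warp_image <- function(image, phi, method = c("linear", "nearest")) {
  method <- match.arg(method)
  check_volume(image)
  check_field(phi)
  check_same_shape(image, array(0, spatial_shape(phi)), "image and field grid")
  grid_sample(image, field_coords(phi), method = method)
}

#' Warp a label volume by a displacement field
#'
#' Nearest-neighbour resampling at `u + phi(u)`; every output value is drawn
#' from the input label set, so label identity is preserved (no interpolated
#' mixtures). Used to carry ROI maps through a deformation for Dice
#' evaluation.
#'
#' @param labels integer-valued 2D or 3D array.
#' @param phi displacement field on the same grid.
#' @return Warped label volume.
#' @export
warp_labels <- function(labels, phi) {
  check_volume(labels, "labels")
  if (max(abs(labels - round(labels))) > 0) {
    stop("`labels` must be integer-valued")
  }
  check_field(phi)
  check_same_shape(labels, array(0, spatial_shape(phi)), "labels and field grid")
  grid_sample(labels, field_coords(phi), method = "nearest")
}
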