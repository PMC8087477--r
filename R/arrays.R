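# Internal array utilities shared by the field algebra, warping and network
# code. All grids are plain R arrays; a displacement field is an array whose
# last dimension holds one component per spatial axis, in voxel units.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
spatial_shape <- function(field) {
  d <- dim(field)
  d[-length(d)]
}

#' Number of spatial dimensions of a displacement field array
#' @noRd
field_ndim <- function(field) {
  length(dim(field)) - 1L
}

#' Validate a displacement field array: last dim = number of spatial axes,
#' all values finite.
#' @noRd
check_field <- function(phi, name = "phi") {
  if (!is.array(phi) || length(dim(phi)) < 3L) {
    stop(sprintf("`%s` must be an array with spatial dims plus a component axis", name))
  }
  d <- dim(phi)
  nd <- length(d) - 1L
  if (d[length(d)] != nd) {
    stop(sprintf("`%s`: last dimension (%d) must equal the number of spatial axes (%d)",
                 name, d[length(d)], nd))
  }
  if (any(d[-length(d)] < 4L)) {
    stop(sprintf("`%s`: all spatial extents must be >= 4", name))
  }
  if (!all(is.finite(phi))) stop(sprintf("`%s` contains non-finite values", name))
  invisible(phi)
}

#' @noRd
check_volume <- function(v, name = "image") {
  if (!is.array(v) || !(length(dim(v)) %in% c(2L, 3L))) {
    stop(sprintf("`%s` must be a 2D or 3D array", name))
  }
  if (any(dim(v) < 4L)) stop(sprintf("`%s`: all extents must be >= 4", name))
  if (!all(is.finite(v))) stop(sprintf("`%s` contains non-finite values", name))
  invisible(v)
}

#' @noRd
check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must share the same shape (got %s vs %s)",
                 what, paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
  invisible(TRUE)
}

#' Zero displacement field on a grid
#'
#' @param shape integer vector of spatial extents (length 2 or 3).
#' @return Array of shape `c(shape, length(shape))` filled with zeros.
#' @export
zero_field <- function(shape) {
  shape <- as.integer(shape)
  array(0, dim = c(shape, length(shape)))
}

#' Coordinate array along one axis (1-based voxel indices)
#' @noRd
axis_coord <- function(shape, axis) {
  slice.index(array(0L, dim = shape), axis) * 1.0
}

#' List of per-axis coordinate arrays for a grid
#' @noRd
grid_coords <- function(shape) {
  lapply(seq_along(shape), function(a) axis_coord(shape, a))
}

#' Absolute sample coordinates u + phi(u), as a list of per-axis arrays
#' @noRd
field_coords <- function(phi) {
  shp <- spatial_shape(phi)
  nd <- length(shp)
  comps <- field_components(phi)
  lapply(seq_len(nd), function(a) axis_coord(shp, a) + comps[[a]])
}

#' Split a field array into a list of per-component spatial arrays
#' @noRd
field_components <- function(phi) {
  shp <- spatial_shape(phi)
  nd <- length(shp)
  n <- prod(shp)
  lapply(seq_len(nd), function(a) {
    array(phi[(a - 1L) * n + seq_len(n)], dim = shp)
  })
}

#' Rebuild a field array from per-component arrays
#' @noRd
components_to_field <- function(comps) {
  shp <- dim(comps[[1]])
  array(unlist(comps, use.names = FALSE), dim = c(shp, length(comps)))
}

#' Extract / assign a hyper-slab given per-axis index vectors
#' @noRd
arr_slab <- function(x, idx) {
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' @noRd
arr_slab_assign <- function(x, idx, value) {
  do.call(`[<-`, c(list(x), idx, list(value = value)))
}

#' Shift an array along one axis with edge replication.
#' by = +1 returns x(u + e_axis) (value of the next voxel), the last slice
#' replicating the edge; by = -1 symmetric.
#' @noRd
shift_replicate <- function(x, axis, by) {
  d <- dim(x)
  n <- d[axis]
  i <- pmin(pmax(seq_len(n) + by, 1L), n)
  idx <- rep(list(quote(expr = )), length(d))
  idx <- lapply(d, seq_len)
  idx[[axis]] <- i
  arr_slab(x, idx)
}

#' Shift with zero fill outside the grid
#' @noRd
shift_zero <- function(x, axis, by) {
  d <- dim(x)
  n <- d[axis]
  src <- seq_len(n) + by
  keep <- src >= 1L & src <= n
  out <- array(0, dim = d)
  if (!any(keep)) return(out)
  idx_dst <- lapply(d, seq_len)
  idx_src <- idx_dst
  idx_dst[[axis]] <- which(keep)
  idx_src[[axis]] <- src[keep]
  arr_slab_assign(out, idx_dst, arr_slab(x, idx_src))
}

#' Logical mask of voxels at least `margin` voxels away from every boundary
#' @noRd
interior_mask <- function(shape, margin = 1L) {
  m <- array(TRUE, dim = shape)
  for (a in seq_along(shape)) {
    co <- axis_coord(shape, a)
    m <- m & (co > margin) & (co <= shape[a] - margin)
  }
  m
}

#' Run an expression with a temporary RNG seed, restoring the caller's state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
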