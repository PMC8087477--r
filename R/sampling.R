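# Interpolating samplers shared by the warp operator, field composition and
# field inversion. Coordinates are 1-based voxel positions; samples outside
# the grid are clamped to the boundary (border replication), so interpolation
# weights are always non-negative and sum to 1.

#' Sample a scalar grid at arbitrary coordinates.
#'
#' @param img spatial array (2D or 3D).
#' @param coords list of per-axis coordinate arrays (all the same shape).
#' @param method "linear" (bi/trilinear) or "nearest".
#' @return array of samples with the shape of `coords[[1]]`.
#' @noRd
grid_sample <- function(img, coords, method = "linear") {
  shp <- dim(img)
  nd <- length(shp)
  strides <- cumprod(c(1, shp[-nd]))
  out_dim <- dim(coords[[1]]) %||% length(coords[[1]])

  if (method == "nearest") {
    idx <- 1
    for (d in seq_len(nd)) {
      cd <- pmin(pmax(floor(coords[[d]] + 0.5), 1), shp[d])
      idx <- idx + (cd - 1) * strides[d]
    }
    return(array(img[as.vector(idx)], dim = out_dim))
  }

  f <- vector("list", nd)
  w <- vector("list", nd)
  for (d in seq_len(nd)) {
    cd <- pmin(pmax(as.vector(coords[[d]]), 1), shp[d])
    fd <- pmin(floor(cd), shp[d] - 1)
    f[[d]] <- fd
    w[[d]] <- cd - fd
  }
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  out <- 0
  for (k in seq_len(nrow(corners))) {
    b <- corners[k, ]
    idx <- 1
    wt <- 1
    for (d in seq_len(nd)) {
      idx <- idx + (f[[d]] - 1 + b[d]) * strides[d]
      wt <- wt * (if (b[d] == 1L) w[[d]] else 1 - w[[d]])
    }
    out <- out + img[idx] * wt
  }
  array(out, dim = out_dim)
}

#' Derivative of the linear sample with respect to each coordinate.
#'
#' Returns a list of per-axis arrays: the spatial gradient of the interpolated
#' image at the sample locations, under the same floor-based corner rule as
#' `grid_sample`. Where a coordinate was clamped outside the grid the
#' derivative is 0 (the sample saturates there).
#' @noRd
grid_sample_grad <- function(img, coords) {
  shp <- dim(img)
  nd <- length(shp)
  strides <- cumprod(c(1, shp[-nd]))
  out_dim <- dim(coords[[1]]) %||% length(coords[[1]])

  f <- vector("list", nd)
  w <- vector("list", nd)
  inb <- vector("list", nd)
  for (d in seq_len(nd)) {
    cv <- as.vector(coords[[d]])
    inb[[d]] <- as.numeric(cv >= 1 & cv <= shp[d])
    cd <- pmin(pmax(cv, 1), shp[d])
    fd <- pmin(floor(cd), shp[d] - 1)
    f[[d]] <- fd
    w[[d]] <- cd - fd
  }
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  grads <- rep(list(0), nd)
  for (k in seq_len(nrow(corners))) {
    b <- corners[k, ]
    idx <- 1
    for (d in seq_len(nd)) idx <- idx + (f[[d]] - 1 + b[d]) * strides[d]
    val <- img[idx]
    for (a in seq_len(nd)) {
      g <- if (b[a] == 1L) 1 else -1
      for (d in seq_len(nd)) {
        if (d == a) next
        g <- g * (if (b[d] == 1L) w[[d]] else 1 - w[[d]])
      }
      grads[[a]] <- grads[[a]] + val * g
    }
  }
  lapply(seq_len(nd), function(a) array(grads[[a]] * inb[[a]], dim = out_dim))
}

#' Adjoint of linear sampling: scatter-add values back onto the grid with the
#' interpolation weights. Used to backpropagate through the field resampling
#' inside compositions.
#' @noRd
grid_scatter <- function(values, coords, shape) {
  nd <- length(shape)
  strides <- cumprod(c(1, shape[-nd]))
  v <- as.vector(values)
  f <- vector("list", nd)
  w <- vector("list", nd)
  for (d in seq_len(nd)) {
    cd <- pmin(pmax(as.vector(coords[[d]]), 1), shape[d])
    fd <- pmin(floor(cd), shape[d] - 1)
    f[[d]] <- fd
    w[[d]] <- cd - fd
  }
  out <- numeric(prod(shape))
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  for (k in seq_len(nrow(corners))) {
    b <- corners[k, ]
    idx <- 1
    wt <- 1
    for (d in seq_len(nd)) {
      idx <- idx + (f[[d]] - 1 + b[d]) * strides[d]
      wt <- wt * (if (b[d] == 1L) w[[d]] else 1 - w[[d]])
    }
    agg <- rowsum(v * wt, group = as.integer(idx))
    at <- as.integer(rownames(agg))
    out[at] <- out[at] + agg[, 1L]
  }
  array(out, dim = shape)
}

#' Sample each component of a displacement field at given coordinates
#' @noRd
sample_field <- function(phi, coords) {
  comps <- field_components(phi)
  components_to_field(lapply(comps, grid_sample, coords = coords))
}
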