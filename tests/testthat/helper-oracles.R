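# Independent brute-force oracles: per-voxel loop implementations of the
# operations under test, written with plain index arithmetic and kept free of
# the package's vectorized code paths.

# Linear-interpolation warp, looping voxel by voxel over the corner-weight
# formula output(u) = sum_{v in N(u+phi(u))} I(v) prod_d (1 - |u_d+phi_d-v_d|)
oracle_warp <- function(img, phi) {
  shp <- dim(img)
  nd <- length(shp)
  out <- array(0, dim = shp)
  grid <- as.matrix(expand.grid(lapply(shp, seq_len)))
  nvox <- nrow(grid)
  for (r in seq_len(nvox)) {
    u <- grid[r, ]
    x <- numeric(nd)
    for (d in seq_len(nd)) {
      comp <- if (nd == 2) phi[u[1], u[2], d] else phi[u[1], u[2], u[3], d]
      x[d] <- min(max(u[d] + comp, 1), shp[d])
    }
    f <- pmin(floor(x), shp - 1)
    val <- 0
    for (corner in seq_len(2^nd)) {
      b <- as.integer(intToBits(corner - 1))[seq_len(nd)]
      v <- f + b
      wt <- prod(1 - abs(x - v))
      iv <- if (nd == 2) img[v[1], v[2]] else img[v[1], v[2], v[3]]
      val <- val + iv * wt
    }
    if (nd == 2) out[u[1], u[2]] <- val else out[u[1], u[2], u[3]] <- val
  }
  out
}

# Per-voxel Jacobian determinant via explicit index arithmetic and base det()
oracle_jacobian <- function(phi) {
  shp <- dim(phi)[-length(dim(phi))]
  nd <- length(shp)
  getc <- function(u, a) {
    if (nd == 2) phi[u[1], u[2], a] else phi[u[1], u[2], u[3], a]
  }
  dcomp <- function(u, a, b) {
    up <- u; dn <- u
    if (u[b] == 1) {
      up[b] <- 2
      getc(up, a) - getc(u, a)
    } else if (u[b] == shp[b]) {
      dn[b] <- shp[b] - 1
      getc(u, a) - getc(dn, a)
    } else {
      up[b] <- u[b] + 1; dn[b] <- u[b] - 1
      (getc(up, a) - getc(dn, a)) / 2
    }
  }
  out <- array(0, dim = shp)
  grid <- as.matrix(expand.grid(lapply(shp, seq_len)))
  for (r in seq_len(nrow(grid))) {
    u <- grid[r, ]
    J <- diag(nd)
    for (a in seq_len(nd)) for (b in seq_len(nd)) {
      J[a, b] <- J[a, b] + dcomp(u, a, b)
    }
    if (nd == 2) out[u[1], u[2]] <- det(J) else out[u[1], u[2], u[3]] <- det(J)
  }
  out
}

# Forward-difference gradient of component `a` along axis `b`, index form
oracle_forward_diff <- function(comp, axis) {
  shp <- dim(comp)
  out <- array(0, dim = shp)
  grid <- as.matrix(expand.grid(lapply(shp, seq_len)))
  for (r in seq_len(nrow(grid))) {
    u <- grid[r, ]
    if (u[axis] < shp[axis]) {
      up <- u; up[axis] <- u[axis] + 1
      v <- if (length(shp) == 2) comp[up[1], up[2]] - comp[u[1], u[2]] else
        comp[up[1], up[2], up[3]] - comp[u[1], u[2], u[3]]
      if (length(shp) == 2) out[u[1], u[2]] <- v else out[u[1], u[2], u[3]] <- v
    }
  }
  out
}

# Loop implementation of the interior-mean squared-Laplacian loss
oracle_laplace <- function(phi) {
  shp <- dim(phi)[-length(dim(phi))]
  nd <- length(shp)
  grid <- as.matrix(expand.grid(lapply(shp, function(n) 2:(n - 1))))
  acc <- 0
  getc <- function(u, a) if (nd == 2) phi[u[1], u[2], a] else phi[u[1], u[2], u[3], a]
  for (r in seq_len(nrow(grid))) {
    u <- grid[r, ]
    for (a in seq_len(nd)) {
      lap <- 0
      for (b in seq_len(nd)) {
        up <- u; up[b] <- u[b] + 1
        dn <- u; dn[b] <- u[b] - 1
        lap <- lap + getc(up, a) + getc(dn, a) - 2 * getc(u, a)
      }
      acc <- acc + lap^2
    }
  }
  acc / nrow(grid)
}

# Smooth random test fields/images with a fixed seed, used as shared inputs
fixture_field <- function(shape, amplitude, sigma, seed) {
  symmreg:::with_seed(seed, random_smooth_field(shape, amplitude, sigma))
}

fixture_image <- function(shape, seed, sigma = 1.5) {
  symmreg:::with_seed(seed,
    gaussian_smooth(array(stats::runif(prod(shape)), dim = shape), sigma))
}

max_interior <- function(field, margin) {
  shp <- dim(field)[-length(dim(field))]
  mask <- symmreg:::interior_mask(shp, margin)
  m <- 0
  for (comp in symmreg:::field_components(field)) {
    m <- max(m, max(abs(comp[mask])))
  }
  m
}
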