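# The halfway-field regression network: a light VoxelMorph-style
# encoder-decoder, fully convolutional in 2D or 3D. Input is the
# (template, subject, difference) stack; output is the halfway displacement
# field, one channel per spatial axis, in voxel units.
#
# No deep-learning framework is used: convolutions are shift-and-multiply
# BLAS products and the backward pass is written out layer by layer. At the
# problem sizes this package targets (2D 64x64, 3D 32^3) that is fast enough
# for CPU training.

leaky_relu <- function(x, slope = 0.2) pmax(x, 0) + slope * pmin(x, 0)
leaky_relu_grad <- function(x, slope = 0.2) (x > 0) + slope * (x <= 0)

#' Kernel offset table for a 3^D convolution, row order fixed so weights are
#' reproducible across sessions.
#' @noRd
conv_offsets <- function(nd) {
  as.matrix(expand.grid(rep(list(-1:1), nd)))
}

#' Zero-pad the spatial axes of a feature array [spatial..., C] by 1 voxel
#' @noRd
pad_spatial <- function(x) {
  d <- dim(x)
  nd <- length(d) - 1L
  dp <- c(d[seq_len(nd)] + 2L, d[length(d)])
  xp <- array(0, dim = dp)
  idx <- c(lapply(d[seq_len(nd)], function(n) seq_len(n) + 1L),
           list(seq_len(d[length(d)])))
  arr_slab_assign(xp, idx, x)
}

#' Same-padding 3^D convolution, optional stride-2 subsampling
#' @noRd
conv_forward <- function(x, W, b, stride = 1L) {
  d <- dim(x)
  nd <- length(d) - 1L
  sp <- d[seq_len(nd)]
  cin <- d[length(d)]
  cout <- length(b)
  offs <- conv_offsets(nd)
  xp <- pad_spatial(x)
  n <- prod(sp)
  Y <- matrix(rep(b, each = n), n, cout)
  for (k in seq_len(nrow(offs))) {
    idx <- c(lapply(seq_len(nd), function(a) seq_len(sp[a]) + 1L + offs[k, a]),
             list(seq_len(cin)))
    Y <- Y + matrix(arr_slab(xp, idx), n, cin) %*% matrix(W[k, , ], cin, cout)
  }
  y <- array(Y, dim = c(sp, cout))
  if (stride > 1L) {
    idx <- c(lapply(sp, function(nn) seq(1L, nn, by = stride)), list(seq_len(cout)))
    y <- arr_slab(y, idx)
  }
  y
}

#' Backward pass of conv_forward: gradients w.r.t. input, weights and bias
#' @noRd
conv_backward <- function(x, W, dY, stride = 1L) {
  d <- dim(x)
  nd <- length(d) - 1L
  sp <- d[seq_len(nd)]
  cin <- d[length(d)]
  cout <- dim(W)[3]
  offs <- conv_offsets(nd)
  n <- prod(sp)
  if (stride > 1L) {
    full <- array(0, dim = c(sp, cout))
    idx <- c(lapply(sp, function(nn) seq(1L, nn, by = stride)), list(seq_len(cout)))
    full <- arr_slab_assign(full, idx, dY)
    dY <- full
  }
  dYm <- matrix(dY, n, cout)
  db <- colSums(dYm)
  dW <- array(0, dim = dim(W))
  xp <- pad_spatial(x)
  dXp <- array(0, dim = dim(xp))
  for (k in seq_len(nrow(offs))) {
    idx <- c(lapply(seq_len(nd), function(a) seq_len(sp[a]) + 1L + offs[k, a]),
             list(seq_len(cin)))
    Xm <- matrix(arr_slab(xp, idx), n, cin)
    dW[k, , ] <- crossprod(Xm, dYm)
    dSlab <- dYm %*% t(matrix(W[k, , ], cin, cout))
    dXp <- arr_slab_assign(dXp, idx,
                           arr_slab(dXp, idx) + array(dSlab, c(sp, cin)))
  }
  idx_in <- c(lapply(sp, function(nn) seq_len(nn) + 1L), list(seq_len(cin)))
  list(dX = arr_slab(dXp, idx_in), dW = dW, db = db)
}

#' Nearest-neighbour x2 upsampling of the spatial axes
#' @noRd
upsample2 <- function(x) {
  d <- dim(x)
  nd <- length(d) - 1L
  idx <- c(lapply(d[seq_len(nd)], function(n) rep(seq_len(n), each = 2L)),
           list(seq_len(d[length(d)])))
  arr_slab(x, idx)
}

#' Adjoint of upsample2: sum each 2^D block of the gradient
#' @noRd
upsample2_backward <- function(dY) {
  nd <- length(dim(dY)) - 1L
  for (a in seq_len(nd)) {
    d <- dim(dY)
    idx_o <- lapply(d, seq_len)
    idx_e <- idx_o
    idx_o[[a]] <- seq(1L, d[a], by = 2L)
    idx_e[[a]] <- seq(2L, d[a], by = 2L)
    dY <- arr_slab(dY, idx_o) + arr_slab(dY, idx_e)
  }
  dY
}

#' Network configuration
#'
#' @param spatial_dims 2 or 3.
#' @param enc_channels encoder feature counts, one stride-2 convolution per
#'   entry. Defaults to the VoxelMorph-style widths (16, 32, 32, 32); halve
#'   them for small (<= 48-voxel) grids to keep CPU training quick.
#' @param dec_channels decoder feature counts. The first
#'   `length(enc_channels)` entries are the convolutions interleaved with x2
#'   upsampling and skip concatenation; any further entries are full-
#'   resolution refinement convolutions.
#' @param field_scale multiplier applied to the raw output channels to give
#'   voxel-unit displacements (default 1).
#' @param in_channels input channels; 3 for (template, subject, difference).
#' @return Object of class `snet_config`.
#' @export
snet_config <- function(spatial_dims = 2L,
                        enc_channels = c(16L, 32L, 32L, 32L),
                        dec_channels = c(32L, 32L, 32L, 32L, 16L),
                        field_scale = 1,
                        in_channels = 3L) {
  stopifnot(spatial_dims %in% c(2L, 3L),
            length(enc_channels) >= 1, length(dec_channels) >= length(enc_channels),
            all(enc_channels >= 1), all(dec_channels >= 1),
            field_scale > 0, in_channels >= 1)
  structure(list(spatial_dims = as.integer(spatial_dims),
                 enc_channels = as.integer(enc_channels),
                 dec_channels = as.integer(dec_channels),
                 field_scale = field_scale,
                 in_channels = as.integer(in_channels)),
            class = "snet_config")
}

#' Channel bookkeeping for the builder and the forward/backward passes
#' @noRd
snet_plan <- function(cfg) {
  L <- length(cfg$enc_channels)
  enc_in <- c(cfg$in_channels, cfg$enc_channels[-L])
  skips <- c(rev(c(cfg$in_channels, cfg$enc_channels[-L])))
  dec_in <- integer(0)
  ch <- cfg$enc_channels[L]
  for (i in seq_len(L)) {
    dec_in <- c(dec_in, ch)
    ch <- cfg$dec_channels[i] + skips[i]
  }
  extra <- seq_len(length(cfg$dec_channels) - L) + L
  for (j in extra) {
    dec_in <- c(dec_in, ch)
    ch <- cfg$dec_channels[j]
  }
  list(L = L, enc_in = enc_in, dec_in = dec_in, skips = skips, final_in = ch)
}

init_conv <- function(k, cin, cout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (k * cin))
  list(W = array(stats::rnorm(k * cin * cout, sd = sd), dim = c(k, cin, cout)),
       b = numeric(cout))
}

#' Build the halfway-field regression network
#'
#' Strided-convolution encoder with skip connections into an upsampling
#' decoder, ending in a linear convolution with one output channel per
#' spatial axis. The final convolution is initialized near zero (weight sd
#' 1e-5, zero bias) so a freshly built model predicts an essentially-identity
#' transform — the stable starting point for unsupervised registration
#' training.
#'
#' @param cfg an [snet_config()].
#' @param seed integer seed for weight initialization.
#' @return Object of class `snet`.
#' @export
build_snet <- function(cfg = snet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "snet_config"))
  plan <- snet_plan(cfg)
  k <- 3L^cfg$spatial_dims
  params <- with_seed(seed, {
    enc <- lapply(seq_len(plan$L), function(i) {
      init_conv(k, plan$enc_in[i], cfg$enc_channels[i])
    })
    dec <- lapply(seq_along(cfg$dec_channels), function(j) {
      init_conv(k, plan$dec_in[j], cfg$dec_channels[j])
    })
    final <- init_conv(k, plan$final_in, cfg$spatial_dims, sd = 1e-5)
    list(enc = enc, dec = dec, final = final)
  })
  structure(list(cfg = cfg, params = params, seed = seed), class = "snet")
}

#' @export
print.snet <- function(x, ...) {
  cat(sprintf("Halfway-field registration network (%dD)\n", x$cfg$spatial_dims))
  cat("  encoder:", paste(x$cfg$enc_channels, collapse = ", "), "\n")
  cat("  decoder:", paste(x$cfg$dec_channels, collapse = ", "), "\n")
  cat(sprintf("  parameters: %d\n", sum(vapply(
    rapply(x$params, identity, how = "unlist"), length, 1L))))
  invisible(x)
}

#' Forward pass; optionally keep the cache needed by the backward pass
#' @noRd
snet_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$cfg
  p <- model$params
  L <- length(cfg$enc_channels)
  feats <- vector("list", L + 1L)
  pre <- list(enc = vector("list", L), dec = vector("list", length(cfg$dec_channels)))
  xin <- list(enc = vector("list", L), dec = vector("list", length(cfg$dec_channels)))
  feats[[1]] <- x
  for (i in seq_len(L)) {
    xin$enc[[i]] <- feats[[i]]
    z <- conv_forward(feats[[i]], p$enc[[i]]$W, p$enc[[i]]$b, stride = 2L)
    pre$enc[[i]] <- z
    feats[[i + 1L]] <- leaky_relu(z)
  }
  y <- feats[[L + 1L]]
  concat_ch <- integer(L)
  for (i in seq_len(L)) {
    xin$dec[[i]] <- y
    z <- conv_forward(y, p$dec[[i]]$W, p$dec[[i]]$b, stride = 1L)
    pre$dec[[i]] <- z
    y <- upsample2(leaky_relu(z))
    skip <- feats[[L + 1L - i]]
    concat_ch[i] <- dim(y)[length(dim(y))]
    y <- array(c(y, skip), dim = c(dim(y)[-length(dim(y))],
                                   dim(y)[length(dim(y))] + dim(skip)[length(dim(skip))]))
  }
  for (j in seq_along(cfg$dec_channels)[-seq_len(L)]) {
    xin$dec[[j]] <- y
    z <- conv_forward(y, p$dec[[j]]$W, p$dec[[j]]$b, stride = 1L)
    pre$dec[[j]] <- z
    y <- leaky_relu(z)
  }
  xin$final <- y
  field <- conv_forward(y, p$final$W, p$final$b, stride = 1L) * cfg$field_scale
  if (!keep_cache) return(field)
  list(field = field, cache = list(xin = xin, pre = pre, concat_ch = concat_ch))
}

#' Backward pass: gradient of a scalar loss w.r.t. all parameters, given
#' d(loss)/d(field)
#' @noRd
snet_backward <- function(model, cache, dfield) {
  cfg <- model$cfg
  p <- model$params
  L <- length(cfg$enc_channels)
  nd <- cfg$spatial_dims
  grads <- list(enc = vector("list", L),
                dec = vector("list", length(cfg$dec_channels)),
                final = NULL)
  dfield <- dfield * cfg$field_scale
  bw <- conv_backward(cache$xin$final, p$final$W, dfield, stride = 1L)
  grads$final <- list(W = bw$dW, b = bw$db)
  dY <- bw$dX
  dskip <- vector("list", L + 1L)  # gradients flowing into encoder features
  for (j in rev(seq_along(cfg$dec_channels)[-seq_len(L)])) {
    dZ <- dY * leaky_relu_grad(cache$pre$dec[[j]])
    bw <- conv_backward(cache$xin$dec[[j]], p$dec[[j]]$W, dZ, stride = 1L)
    grads$dec[[j]] <- list(W = bw$dW, b = bw$db)
    dY <- bw$dX
  }
  for (i in rev(seq_len(L))) {
    d <- dim(dY)
    cch <- cache$concat_ch[i]
    tot <- d[length(d)]
    idx_main <- c(lapply(d[-length(d)], seq_len), list(seq_len(cch)))
    idx_skip <- c(lapply(d[-length(d)], seq_len), list(seq(cch + 1L, tot)))
    dskip[[L + 1L - i]] <- arr_slab(dY, idx_skip)
    dUp <- arr_slab(dY, idx_main)
    dAct <- upsample2_backward(dUp)
    dZ <- dAct * leaky_relu_grad(cache$pre$dec[[i]])
    bw <- conv_backward(cache$xin$dec[[i]], p$dec[[i]]$W, dZ, stride = 1L)
    grads$dec[[i]] <- list(W = bw$dW, b = bw$db)
    dY <- bw$dX
  }
  # dY is now the gradient w.r.t. feats[[L+1]]; add skip gradients and walk
  # back down the encoder
  dfeat <- dY
  for (i in rev(seq_len(L))) {
    if (!is.null(dskip[[i + 1L]]) && i < L) dfeat <- dfeat + dskip[[i + 1L]]
    dZ <- dfeat * leaky_relu_grad(cache$pre$enc[[i]])
    bw <- conv_backward(cache$xin$enc[[i]], p$enc[[i]]$W, dZ, stride = 2L)
    grads$enc[[i]] <- list(W = bw$dW, b = bw$db)
    dfeat <- bw$dX
  }
  grads
}

#' Pair input stack for the network
#'
#' Min-max normalizes both images to [0, 1], forms the signed difference map
#' (template - subject), and stacks the three as input channels in the fixed
#' order (template, subject, difference). Swapping template and subject is a
#' different input; no output symmetry under the swap is assumed.
#'
#' @param template,subject intensity arrays of identical shape.
#' @return Object of class `pair_input` with elements `template`, `subject`,
#'   `difference` (all normalized) and `x` (the stacked input array).
#' @export
make_pair_input <- function(template, subject) {
  check_volume(template, "template")
  check_volume(subject, "subject")
  check_same_shape(template, subject, "images")
  tn <- normalize_intensity(template)
  sn <- normalize_intensity(subject)
  df <- tn - sn
  x <- array(c(tn, sn, df), dim = c(dim(tn), 3L))
  structure(list(template = tn, subject = sn, difference = df, x = x),
            class = "pair_input")
}

#' Predict the halfway displacement field for an image pair
#'
#' Runs the network on the (template, subject, difference) stack and returns
#' the halfway field that moves the template toward the pseudomean; the
#' subject-side field is always its negation, obtained via [negate_field()],
#' never predicted separately. Inference is deterministic given fixed
#' weights.
#'
#' @param model an [build_snet()] model.
#' @param pair a [make_pair_input()] object.
#' @return Displacement field array `c(spatial, spatial_dims)`.
#' @export
predict_halfway <- function(model, pair) {
  stopifnot(inherits(model, "snet"), inherits(pair, "pair_input"))
  shp <- dim(pair$template)
  if (length(shp) != model$cfg$spatial_dims) {
    stop(sprintf("model is %dD but the pair is %dD", model$cfg$spatial_dims, length(shp)))
  }
  fac <- 2L^length(model$cfg$enc_channels)
  if (any(shp %% fac != 0L)) {
    stop(sprintf("every spatial extent must be divisible by %d (total downsampling factor)", fac))
  }
  snet_forward(model, pair$x)
}

#' Compose the full forward and backward deformations from the halfway field
#'
#' The two half pathways are completed into end-to-end deformations:
#' `forward  = phi_t o (phi_s)^-1` (with `phi_s = -phi_t`), the field that
#' resamples the template onto the subject grid, and
#' `backward = phi_s o (phi_t)^-1`, the field that resamples the subject
#' onto the template grid. The two are mutual inverses up to interpolation
#' and inversion error, which is how the construction guarantees inverse
#' consistency.
#'
#' @param phi_t halfway displacement field.
#' @param invert_iter,invert_tol fixed-point inversion settings.
#' @return list with `forward` and `backward` fields (each carrying the
#'   inversion convergence attributes).
#' @export
compose_full_deformations <- function(phi_t, invert_iter = 30L, invert_tol = 1e-3) {
  check_field(phi_t, "phi_t")
  inv_s <- invert_field(-phi_t, max_iter = invert_iter, tol = invert_tol)
  inv_t <- invert_field(phi_t, max_iter = invert_iter, tol = invert_tol)
  fw <- compose_fields(phi_t, inv_s)
  bw <- compose_fields(-phi_t, inv_t)
  attr(fw, "converged") <- attr(inv_s, "converged")
  attr(bw, "converged") <- attr(inv_t, "converged")
  list(forward = fw, backward = bw)
}
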