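# Synthetic brain-like phantoms with known ground-truth deformations: the
# test substrate that lets every other module (and end-to-end training) be
# exercised without external imaging data.
#
# A phantom template is a smooth "head": an outer ellipse/ellipsoid, a bright
# rim (skull/CSF analog), a darker interior with a low-intensity ventricle
# analog, and a handful of smooth intensity blobs that double as labeled
# ROIs. Tissue boundaries are Gaussian-smoothed, mimicking the smooth
# gradients of preprocessed MR images (and giving intensity losses a usable
# capture range). The ground-truth deformation is a Gaussian-smoothed random
# displacement field rescaled to a prescribed amplitude and guaranteed
# fold-free by rejection.

#' Separable Gaussian smoothing of an N-D array
#'
#' Truncated (3 sigma) Gaussian kernel applied along each axis in turn, with
#' renormalized (clamped) weights at the boundaries so edge values are not
#' pulled toward zero.
#'
#' @param x 2D or 3D array.
#' @param sigma kernel standard deviation in voxels.
#' @return Smoothed array.
#' @export
gaussian_smooth <- function(x, sigma) {
  stopifnot(sigma > 0)
  d <- dim(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  for (a in seq_along(d)) {
    n <- d[a]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmax(1L, pmin(n, i + seq(-r, r)))
      w <- k / sum(k)
      for (t in seq_along(j)) K[i, j[t]] <- K[i, j[t]] + w[t]
    }
    perm <- c(a, seq_along(d)[-a])
    xp <- aperm(x, perm)
    dp <- dim(xp)
    xp <- K %*% matrix(xp, n)
    dim(xp) <- dp
    x <- aperm(xp, order(perm))
  }
  x
}

#' Random smooth fold-free displacement field
#'
#' Per-component white noise, Gaussian-smoothed at `sigma`, rescaled so the
#' maximum displacement magnitude equals `amplitude`, and redrawn (up to
#' `max_tries`) until the field is fold-free. Smooth low-amplitude fields of
#' this family are what the Laplacian/antifolding regularizers assume.
#'
#' @param shape spatial extents.
#' @param amplitude maximum displacement magnitude, voxels.
#' @param sigma Gaussian smoothing width, voxels.
#' @param max_tries rejection-sampling budget (default 10).
#' @param support optional array of weights in `[0, 1]` multiplied into the
#'   smoothed noise before rescaling. The phantom generator passes a smooth
#'   head mask here so the deformation peak lands on anatomy rather than on
#'   empty background — affinely pre-aligned brains deform inside the head,
#'   not in air.
#' @return Displacement field array; errors if no fold-free draw is found
#'   (amplitude too large for the requested smoothness).
#' @export
random_smooth_field <- function(shape, amplitude, sigma, max_tries = 10L,
                                support = NULL) {
  shape <- as.integer(shape)
  nd <- length(shape)
  if (amplitude == 0) return(zero_field(shape))
  if (!is.null(support)) stopifnot(identical(dim(support), shape))
  for (try in seq_len(max_tries)) {
    comps <- lapply(seq_len(nd), function(a) {
      z <- gaussian_smooth(array(stats::rnorm(prod(shape)), dim = shape), sigma)
      if (is.null(support)) z else z * support
    })
    mag <- sqrt(Reduce(`+`, lapply(comps, function(z) z^2)))
    s <- amplitude / max(mag)
    phi <- components_to_field(lapply(comps, function(z) z * s))
    if (count_folds(phi) == 0L) return(phi)
  }
  stop("could not draw a fold-free field: amplitude too large for sigma")
}

#' Draw one phantom head image + ROI labels (no deformation applied)
#' @noRd
phantom_template <- function(shape, n_rois, rng_jitter = 0) {
  nd <- length(shape)
  coords <- grid_coords(shape)
  ctr <- shape / 2 + 0.5
  semi <- shape * 0.42 * (1 + rng_jitter * stats::runif(nd, -1, 1))
  # normalized elliptic radius
  rho <- sqrt(Reduce(`+`, lapply(seq_len(nd), function(a) {
    ((coords[[a]] - ctr[a]) / semi[a])^2
  })))
  img <- array(0, dim = shape)
  img[rho <= 1] <- 0.45                 # brain tissue
  img[rho <= 1 & rho > 0.88] <- 0.95    # rim (skull/CSF analog)
  img[rho <= 0.22] <- 0.12              # ventricle analog
  labels <- array(0L, dim = shape)
  # ROI blobs on a ring at ~0.55 of the head radius, angularly spread with
  # jittered centres and radii
  for (i in seq_len(n_rois)) {
    ang <- 2 * pi * (i - 1) / n_rois + rng_jitter * stats::runif(1, -0.4, 0.4)
    off <- c(cos(ang), sin(ang), if (nd == 3L) sin(2 * ang) * 0.3)[seq_len(nd)]
    cc <- ctr + 0.55 * semi * off
    rad <- max(2.2, min(shape) / 11) * (1 + rng_jitter * stats::runif(1, -0.25, 0.25))
    dist2 <- Reduce(`+`, lapply(seq_len(nd), function(a) (coords[[a]] - cc[a])^2))
    inside <- dist2 <= rad^2
    img[inside] <- 0.55 + 0.35 * (i %% 2)   # alternating blob intensities
    labels[inside] <- i
  }
  img <- gaussian_smooth(img, 1.2)
  img <- pmin(pmax(img, 0), 1)
  # smooth head-interior weight used as deformation support
  mask <- gaussian_smooth((rho <= 0.95) * 1.0, 2.5)
  list(image = img, labels = labels, head = mask)
}

#' Generate a synthetic template/subject phantom pair
#'
#' Builds a head-like template with `n_rois` labeled blobs, draws a random
#' smooth fold-free ground-truth field, and produces the subject as the
#' warped template plus Gaussian intensity noise; the subject labels are the
#' template labels carried through the same field with nearest-neighbour
#' resampling. Fully reproducible from `seed`.
#'
#' @param shape spatial extents (default 2D 64x64).
#' @param n_rois number of labeled blobs (default 4).
#' @param deformation_amplitude max ground-truth displacement, voxels
#'   (default 3).
#' @param smoothness_sigma Gaussian width of the random field, voxels
#'   (default 6).
#' @param noise_sd additive intensity noise sd (default 0.02).
#' @param seed RNG seed.
#' @return Object of class `phantom_pair`: `template`, `subject`,
#'   `labels_template`, `labels_subject`, `true_field`.
#' @export
make_phantom <- function(shape = c(64L, 64L), n_rois = 4L,
                         deformation_amplitude = 3, smoothness_sigma = 6,
                         noise_sd = 0.02, seed = 1L) {
  stopifnot(deformation_amplitude >= 0, smoothness_sigma > 0, noise_sd >= 0,
            n_rois >= 1, length(shape) %in% c(2L, 3L), all(shape >= 4))
  with_seed(seed, {
    tpl <- phantom_template(as.integer(shape), n_rois)
    phi <- random_smooth_field(shape, deformation_amplitude, smoothness_sigma,
                               support = tpl$head)
    subject <- warp_image(tpl$image, phi)
    if (noise_sd > 0) {
      # clip back into the tissue intensity window so template and subject
      # stay intensity-comparable, as preprocessed MR pairs are
      subject <- pmin(pmax(
        subject + array(stats::rnorm(prod(shape), sd = noise_sd), dim = shape),
        0), 1)
    }
    structure(
      list(template = tpl$image,
           subject = subject,
           labels_template = tpl$labels,
           labels_subject = warp_labels(tpl$labels, phi),
           true_field = phi,
           spec = list(shape = as.integer(shape), n_rois = n_rois,
                       deformation_amplitude = deformation_amplitude,
                       smoothness_sigma = smoothness_sigma,
                       noise_sd = noise_sd, seed = seed)),
      class = "phantom_pair"
    )
  })
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("Phantom pair %s, %d ROIs, amplitude %.3g voxels (seed %d)\n",
              paste(x$spec$shape, collapse = "x"), x$spec$n_rois,
              x$spec$deformation_amplitude, x$spec$seed))
  invisible(x)
}

#' Generate a cohort of anatomically varied phantoms
#'
#' Each member starts from the same labeled base head (so ROI identities
#' correspond across the cohort), is shaped by per-subject jittered ellipse
#' and blob parameters plus an independent smooth random deformation, and
#' carries its own consistent label map. All members share one grid — the
#' substrate for pairing plans and cohort training.
#'
#' @param n cohort size (>= 2).
#' @param shape,n_rois,deformation_amplitude,smoothness_sigma,noise_sd,seed
#'   as in [make_phantom()].
#' @return list of length `n`; each element has `image` and `labels`.
#' @export
make_cohort <- function(n, shape = c(64L, 64L), n_rois = 4L,
                        deformation_amplitude = 3, smoothness_sigma = 6,
                        noise_sd = 0.02, seed = 1L) {
  stopifnot(n >= 2)
  lapply(seq_len(n), function(i) {
    with_seed(seed + 1000L * i, {
      tpl <- phantom_template(as.integer(shape), n_rois, rng_jitter = 0.15)
      phi <- random_smooth_field(shape, deformation_amplitude, smoothness_sigma,
                                 support = tpl$head)
      img <- warp_image(tpl$image, phi)
      if (noise_sd > 0) {
        img <- pmin(pmax(
          img + array(stats::rnorm(prod(shape), sd = noise_sd), dim = shape),
          0), 1)
      }
      list(image = img, labels = warp_labels(tpl$labels, phi))
    })
  })
}
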