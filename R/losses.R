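# The six-term training loss: intensity similarity in the pseudomean space
# and in the two end spaces (all SSD), plus three regularizers on the halfway
# field (Laplacian smoothness, displacement magnitude, antifolding).
#
# Normalization convention: every sum over voxels is divided by the voxel
# count (per-voxel mean), so loss magnitudes — and thus the balance weights —
# are resolution independent. Squared norms over vector components are
# summed, not averaged. Intensity volumes are expected on a common scale;
# pair construction (see make_pair_input) min-max normalizes images to [0,1]
# before any SSD is computed.

#' Loss balance weights
#'
#' The three coefficients weighting the regularizers against the (unweighted)
#' similarity terms in the total loss: `alpha` scales the Laplacian
#' smoothness term, `beta` the displacement-magnitude (zero) term, `gamma`
#' the antifolding term. Defaults (1, 0.01, 100) are the configuration the
#' model is trained with: smoothness on equal footing with similarity, a
#' deliberately small magnitude penalty so genuine large deformations are not
#' suppressed, and a heavy fold penalty that is inactive on fold-free fields.
#'
#' @param alpha,beta,gamma non-negative weights.
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 1, beta = 0.01, gamma = 100) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "loss_weights")
}

#' Pseudomean-space symmetric similarity
#'
#' Mean squared difference between the subject warped by the negated halfway
#' field and the template warped by the halfway field:
#' `mean((warp(I_S, -phi) - warp(I_T, +phi))^2)`. Driving this to zero pulls
#' both images symmetrically onto their pseudomean.
#'
#' @param subject,template intensity arrays (same shape).
#' @param phi_t halfway displacement field (template side).
#' @return Scalar loss.
#' @export
loss_sim_sym <- function(subject, template, phi_t) {
  check_same_shape(subject, template, "images")
  a <- warp_image(subject, -phi_t)
  b <- warp_image(template, phi_t)
  mean((a - b)^2)
}

#' End-space similarities via composed full deformations
#'
#' Completes the half pathways into full deformations and scores alignment in
#' the two end spaces: `s_to_t` compares the subject warped all the way onto
#' the template grid (field `(-phi) o phi^-1`) against the template, and
#' `t_to_s` compares the template warped onto the subject grid (field
#' `phi o (-phi)^-1`) against the subject. The inverses come from
#' [invert_field()]; at training time a small fixed iteration count bounds
#' cost, at evaluation time full-tolerance inversion is used.
#'
#' @param subject,template intensity arrays.
#' @param phi_t halfway displacement field.
#' @param invert_iter,invert_tol fixed-point inversion settings.
#' @return Named numeric vector `c(s_to_t =, t_to_s =)` with attribute
#'   `converged` (logical, both inversions). Non-convergence is a warning,
#'   not an error.
#' @export
loss_sim_endspaces <- function(subject, template, phi_t,
                               invert_iter = 30L, invert_tol = 1e-3) {
  check_same_shape(subject, template, "images")
  phi_s <- -phi_t
  inv_t <- invert_field(phi_t, max_iter = invert_iter, tol = invert_tol)
  inv_s <- invert_field(phi_s, max_iter = invert_iter, tol = invert_tol)
  ok <- isTRUE(attr(inv_t, "converged")) && isTRUE(attr(inv_s, "converged"))
  if (!ok) warning("field inversion did not reach tolerance; end-space losses are approximate")
  to_template <- compose_fields(phi_s, inv_t)   # subject -> template grid
  to_subject <- compose_fields(phi_t, inv_s)    # template -> subject grid
  out <- c(
    s_to_t = mean((warp_image(subject, to_template) - template)^2),
    t_to_s = mean((warp_image(template, to_subject) - subject)^2)
  )
  attr(out, "converged") <- ok
  out
}

#' Discrete Laplacian of one component, valid on the all-axes interior
#' @noRd
laplacian_comp <- function(v) {
  out <- 0
  for (a in seq_along(dim(v))) {
    out <- out + shift_zero(v, a, +1L) + shift_zero(v, a, -1L) - 2 * v
  }
  out
}

#' Laplacian smoothness loss
#'
#' Mean over interior voxels of the squared norm (summed over components) of
#' the discrete vector Laplacian — second central differences summed over
#' axes. Vanishes exactly on affine fields; penalizes curvature of the
#' halfway field.
#'
#' @param phi_t halfway displacement field.
#' @return Scalar loss.
#' @export
loss_laplace <- function(phi_t) {
  check_field(phi_t, "phi_t")
  shp <- spatial_shape(phi_t)
  mask <- interior_mask(shp, 1L)
  acc <- 0
  for (cc in field_components(phi_t)) {
    lap <- laplacian_comp(cc)
    acc <- acc + sum((lap * mask)^2)
  }
  acc / sum(mask)
}

#' Displacement-magnitude ("zero") loss
#'
#' Mean over voxels of the squared displacement norm. A small weight on this
#' term discourages unreasonably large deformations without preventing the
#' genuine ones.
#'
#' @param phi_t halfway displacement field.
#' @return Scalar loss.
#' @export
loss_zero <- function(phi_t) {
  check_field(phi_t, "phi_t")
  sum(phi_t^2) / prod(spatial_shape(phi_t))
}

#' Antifolding loss
#'
#' For each axis `d`, the same-axis forward-difference derivative
#' `d phi_d / d u_d` approximates the corresponding Jacobian diagonal entry
#' minus one; a fold along that axis requires `d phi_d / d u_d + 1 <= 0`.
#' The loss is the per-voxel mean of `R(d phi_d/d u_d + 1)` summed over axes,
#' with `R(Q) = |Q|` for `Q <= 0` and `0` otherwise — exactly zero whenever
#' every same-axis derivative exceeds -1, i.e. for any field nowhere near
#' folding.
#'
#' @param phi_t halfway displacement field.
#' @return Scalar loss.
#' @export
loss_antifold <- function(phi_t) {
  check_field(phi_t, "phi_t")
  shp <- spatial_shape(phi_t)
  comps <- field_components(phi_t)
  acc <- 0
  for (d in seq_along(comps)) {
    q <- (shift_replicate(comps[[d]], d, +1L) - comps[[d]]) + 1
    acc <- acc + sum(pmax(0, -q))
  }
  acc / prod(shp)
}

#' Total training loss
#'
#' Assembles all six terms:
#' `total = sim_sym + sim_s_to_t + sim_t_to_s + alpha*laplace + beta*zero +
#' gamma*antifold`.
#'
#' @param subject,template intensity arrays (normalize intensities first for
#'   comparable similarity scales; see [make_pair_input()]).
#' @param phi_t halfway displacement field.
#' @param weights a [loss_weights()] object.
#' @param invert_iter,invert_tol settings passed to the end-space inversions.
#' @return Object of class `loss_breakdown`: the six terms, the weights, and
#'   the weighted `total`.
#' @export
total_loss <- function(subject, template, phi_t, weights = loss_weights(),
                       invert_iter = 30L, invert_tol = 1e-3) {
  stopifnot(inherits(weights, "loss_weights"))
  ends <- loss_sim_endspaces(subject, template, phi_t,
                             invert_iter = invert_iter, invert_tol = invert_tol)
  terms <- list(
    sim_sym = loss_sim_sym(subject, template, phi_t),
    sim_s_to_t = unname(ends["s_to_t"]),
    sim_t_to_s = unname(ends["t_to_s"]),
    laplace = loss_laplace(phi_t),
    zero = loss_zero(phi_t),
    antifold = loss_antifold(phi_t)
  )
  terms$total <- terms$sim_sym + terms$sim_s_to_t + terms$sim_t_to_s +
    weights$alpha * terms$laplace + weights$beta * terms$zero +
    weights$gamma * terms$antifold
  terms$weights <- weights
  structure(terms, class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat("Loss breakdown (alpha =", x$weights$alpha,
      ", beta =", x$weights$beta, ", gamma =", x$weights$gamma, ")\n")
  for (nm in c("sim_sym", "sim_s_to_t", "sim_t_to_s", "laplace", "zero", "antifold", "total")) {
    cat(sprintf("  %-10s %.6g\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' @export
as.data.frame.loss_breakdown <- function(x, ...) {
  data.frame(sim_sym = x$sim_sym, sim_s_to_t = x$sim_s_to_t,
             sim_t_to_s = x$sim_t_to_s, laplace = x$laplace, zero = x$zero,
             antifold = x$antifold, total = x$total)
}

#' Min-max normalize intensities to [0, 1]
#'
#' Applied to both images before any SSD loss so similarity magnitudes are
#' comparable across inputs; a constant image maps to all zeros.
#'
#' @param image intensity array.
#' @return Normalized array.
#' @export
normalize_intensity <- function(image) {
  check_volume(image)
  r <- range(image)
  if (r[2] - r[1] <= 0) return(array(0, dim = dim(image)))
  (image - r[1]) / (r[2] - r[1])
}
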