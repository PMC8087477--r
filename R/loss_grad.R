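# Analytic gradient of the total loss with respect to the halfway field.
# This is the glue between the loss definitions and the network optimizer:
# the network's backward pass consumes d(total)/d(phi).
#
# The inverse fields inside the end-space terms are treated as
# stopped-gradient inputs (the fixed-point inversion is not differentiated
# through); gradients flow through the direct appearance of phi in the
# composed field and through the warp resampling. The `stop_grad_invert`
# switch exists to make that choice explicit at call sites.

#' Total loss and its gradient with respect to the halfway field
#'
#' @param subject,template intensity arrays on a common [0,1] scale.
#' @param phi_t halfway displacement field.
#' @param weights [loss_weights()].
#' @param invert_iter fixed-point iterations used by the end-space inversions
#'   (a small fixed count bounds training cost; full-tolerance inversion is
#'   for inference).
#' @param stop_grad_invert must currently be TRUE: the inverse fields are
#'   constants of the backward pass.
#' @return list with `breakdown` (class `loss_breakdown`) and `grad`, an
#'   array shaped like `phi_t`.
#' @export
total_loss_grad <- function(subject, template, phi_t, weights = loss_weights(),
                            invert_iter = 5L, stop_grad_invert = TRUE) {
  if (!stop_grad_invert) {
    stop("differentiating through the fixed-point inversion is not implemented")
  }
  check_same_shape(subject, template, "images")
  check_field(phi_t, "phi_t")
  shp <- spatial_shape(phi_t)
  nd <- length(shp)
  nvox <- prod(shp)
  base <- grid_coords(shp)
  comps <- field_components(phi_t)
  gcomps <- rep(list(array(0, dim = shp)), nd)

  ## --- pseudomean symmetric similarity -------------------------------------
  coords_s <- lapply(seq_len(nd), function(a) base[[a]] - comps[[a]])
  coords_t <- lapply(seq_len(nd), function(a) base[[a]] + comps[[a]])
  ws <- grid_sample(subject, coords_s)
  wt <- grid_sample(template, coords_t)
  diff_sym <- ws - wt
  l_sym <- mean(diff_sym^2)
  gs <- grid_sample_grad(subject, coords_s)
  gt <- grid_sample_grad(template, coords_t)
  for (a in seq_len(nd)) {
    gcomps[[a]] <- gcomps[[a]] + (2 / nvox) * diff_sym * (-gs[[a]] - gt[[a]])
  }

  ## --- end-space similarities (stop-grad inverses) -------------------------
  inv_t <- invert_field(phi_t, max_iter = invert_iter, tol = 1e-6)
  inv_s <- invert_field(-phi_t, max_iter = invert_iter, tol = 1e-6)

  # subject -> template grid: c1(u) = inv_t(u) - phi(u + inv_t(u))
  at_t <- lapply(seq_len(nd), function(a) base[[a]] + field_components(inv_t)[[a]])
  c1 <- lapply(seq_len(nd), function(a) {
    field_components(inv_t)[[a]] - grid_sample(comps[[a]], at_t)
  })
  coords_c1 <- lapply(seq_len(nd), function(a) base[[a]] + c1[[a]])
  w_s2t <- grid_sample(subject, coords_c1)
  diff_st <- w_s2t - template
  l_st <- mean(diff_st^2)
  g_s2t <- grid_sample_grad(subject, coords_c1)
  for (a in seq_len(nd)) {
    dc <- (2 / nvox) * diff_st * g_s2t[[a]]
    gcomps[[a]] <- gcomps[[a]] - grid_scatter(dc, at_t, shp)
  }

  # template -> subject grid: c2(u) = inv_s(u) + phi(u + inv_s(u))
  at_s <- lapply(seq_len(nd), function(a) base[[a]] + field_components(inv_s)[[a]])
  c2 <- lapply(seq_len(nd), function(a) {
    field_components(inv_s)[[a]] + grid_sample(comps[[a]], at_s)
  })
  coords_c2 <- lapply(seq_len(nd), function(a) base[[a]] + c2[[a]])
  w_t2s <- grid_sample(template, coords_c2)
  diff_ts <- w_t2s - subject
  l_ts <- mean(diff_ts^2)
  g_t2s <- grid_sample_grad(template, coords_c2)
  for (a in seq_len(nd)) {
    dc <- (2 / nvox) * diff_ts * g_t2s[[a]]
    gcomps[[a]] <- gcomps[[a]] + grid_scatter(dc, at_s, shp)
  }

  ## --- Laplacian smoothness ------------------------------------------------
  mask <- interior_mask(shp, 1L)
  nint <- sum(mask)
  l_lap <- 0
  for (a in seq_len(nd)) {
    lap <- laplacian_comp(comps[[a]]) * mask
    l_lap <- l_lap + sum(lap^2)
    # the zero-padded Laplacian stencil is self-adjoint
    gcomps[[a]] <- gcomps[[a]] +
      weights$alpha * (2 / nint) * laplacian_comp(lap)
  }
  l_lap <- l_lap / nint

  ## --- displacement magnitude ----------------------------------------------
  l_zero <- sum(phi_t^2) / nvox
  for (a in seq_len(nd)) {
    gcomps[[a]] <- gcomps[[a]] + weights$beta * (2 / nvox) * comps[[a]]
  }

  ## --- antifolding ----------------------------------------------------------
  l_anti <- 0
  for (a in seq_len(nd)) {
    q <- (shift_replicate(comps[[a]], a, +1L) - comps[[a]]) + 1
    active <- (q <= 0) * 1.0
    # last slice has zero derivative by construction, never active
    l_anti <- l_anti + sum(pmax(0, -q))
    y <- -active / nvox
    valid <- 1 - (axis_coord(shp, a) == shp[a])
    dAdj <- shift_zero(y, a, -1L) - y * valid
    gcomps[[a]] <- gcomps[[a]] + weights$gamma * dAdj
  }
  l_anti <- l_anti / nvox

  terms <- list(
    sim_sym = l_sym, sim_s_to_t = l_st, sim_t_to_s = l_ts,
    laplace = l_lap, zero = l_zero, antifold = l_anti
  )
  terms$total <- l_sym + l_st + l_ts + weights$alpha * l_lap +
    weights$beta * l_zero + weights$gamma * l_anti
  terms$weights <- weights
  list(
    breakdown = structure(terms, class = "loss_breakdown"),
    grad = components_to_field(gcomps)
  )
}
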