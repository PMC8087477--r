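# Two-stage unsupervised training: a pretraining stage on one-template-vs-all
# pairs, then (optionally) a stage over all ordered pairs of the cohort, both
# optimized with Adam on the six-term loss.

#' Pairing plans for the two training stages
#'
#' Stage 1 pairs a single fixed template with every cohort member (n pairs
#' for n ids, the self pair included). Stage 2 enumerates all ordered
#' (template, subject) pairs: n^2 with self pairs (the default — self pairs
#' act as identity-regularizing examples), or n*(n-1) with
#' `include_self = FALSE`, the counting used for held-out test pairs.
#'
#' @param ids vector of cohort identifiers.
#' @param stage 1 or 2.
#' @param template_id the fixed template for stage 1 (default: first id).
#' @param include_self keep (i, i) pairs (default TRUE).
#' @return data.frame with columns `template` and `subject`.
#' @export
make_pairing_plan <- function(ids, stage, template_id = ids[[1]],
                              include_self = TRUE) {
  stopifnot(length(ids) >= 1, stage %in% c(1L, 2L))
  if (stage == 1L) {
    if (!template_id %in% ids) stop("`template_id` is not among `ids`")
    subj <- if (include_self) ids else ids[ids != template_id]
    return(data.frame(template = rep(template_id, length(subj)), subject = subj))
  }
  plan <- expand.grid(subject = ids, template = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, c(2, 1)]
  if (!include_self) plan <- plan[plan$template != plan$subject, ]
  rownames(plan) <- NULL
  plan
}

#' Training configuration
#'
#' Defaults follow the published schedule: stage 1 runs 200 Adam steps per
#' pair at learning rate 1e-4; stage 2 (disabled by default at desk scale —
#' set `epochs` > 0 to enable) makes one step per ordered pair per epoch at
#' learning rate 1e-5, halving the rate every 2 epochs. Pair order in stage 2
#' is reshuffled each epoch from the run seed.
#'
#' @param stage1 list: `iterations_per_pair` (default 200; 0 skips the
#'   stage), `lr` (default 1e-4), `template_id` (default NULL = first id),
#'   `include_self` (default TRUE).
#' @param stage2 list: `epochs` (default 0; the published schedule uses 20),
#'   `lr` (default 1e-5), `lr_decay` (default 0.5), `decay_every` (epochs,
#'   default 2), `include_self` (default TRUE).
#' @param seed run seed for pair shuffling.
#' @param weights [loss_weights()].
#' @param invert_iter fixed-point inversion sweeps inside the training-time
#'   end-space losses (default 5; full-tolerance inversion is for inference).
#' @param adam list of optimizer constants `beta1`, `beta2`, `eps`.
#' @return Object of class `training_config`.
#' @export
training_config <- function(stage1 = list(), stage2 = list(), seed = 1L,
                            weights = loss_weights(), invert_iter = 5L,
                            adam = list(beta1 = 0.9, beta2 = 0.999, eps = 1e-8)) {
  s1 <- utils::modifyList(list(iterations_per_pair = 200L, lr = 1e-4,
                               template_id = NULL, include_self = TRUE), stage1)
  s2 <- utils::modifyList(list(epochs = 0L, lr = 1e-5, lr_decay = 0.5,
                               decay_every = 2L, include_self = TRUE), stage2)
  stopifnot(s1$iterations_per_pair >= 0, s1$lr > 0,
            s2$epochs >= 0, s2$lr > 0,
            s2$lr_decay > 0, s2$lr_decay <= 1, s2$decay_every >= 1,
            inherits(weights, "loss_weights"), invert_iter >= 1)
  structure(list(stage1 = s1, stage2 = s2, seed = as.integer(seed),
                 weights = weights, invert_iter = as.integer(invert_iter),
                 adam = adam),
            class = "training_config")
}

#' Effective stage-2 learning rate at a given (1-based) epoch
#'
#' `lr * lr_decay^(epoch %/% decay_every)`: e.g. with the defaults the rate
#' at epoch 4 is `1e-5 * 0.5^2`.
#' @param epoch 1-based epoch number.
#' @param lr,lr_decay,decay_every schedule constants.
#' @export
stage2_lr <- function(epoch, lr = 1e-5, lr_decay = 0.5, decay_every = 2L) {
  lr * lr_decay^(epoch %/% decay_every)
}

## --- parameter-tree helpers and Adam ----------------------------------------

tree_pmap <- function(trees, f) {
  if (is.list(trees[[1]])) {
    out <- vector("list", length(trees[[1]]))
    names(out) <- names(trees[[1]])
    for (i in seq_along(out)) out[[i]] <- tree_pmap(lapply(trees, `[[`, i), f)
    out
  } else {
    do.call(f, trees)
  }
}

adam_init <- function(params) {
  list(m = tree_pmap(list(params), function(x) x * 0),
       v = tree_pmap(list(params), function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_pmap(list(state$m, grads), function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_pmap(list(state$v, grads), function(v, g) beta2 * v + (1 - beta2) * g^2)
  corr <- sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  params <- tree_pmap(list(params, state$m, state$v), function(p, m, v) {
    p - lr * corr * m / (sqrt(v) + eps)
  })
  list(params = params, state = state)
}

#' Train the registration network on a cohort
#'
#' Runs stage 1 (one template vs all) then, if configured, stage 2 (all
#' ordered pairs, shuffled per epoch). Each step predicts the halfway field
#' for one pair, evaluates the six-term loss and its analytic field gradient,
#' backpropagates through the network and applies one Adam update. A
#' non-finite loss aborts with the offending step identified. With a fixed
#' seed and single-threaded BLAS the loss history is reproducible.
#'
#' @param model an [build_snet()] model.
#' @param images list of intensity arrays, all on the same grid.
#' @param config a [training_config()].
#' @param quiet suppress per-pair progress messages.
#' @return Object of class `snet_fit`: `model` (trained), `history` (one row
#'   per step with the loss breakdown), `config`.
#' @export
train_snet <- function(model, images, config = training_config(), quiet = TRUE) {
  stopifnot(inherits(model, "snet"), inherits(config, "training_config"),
            is.list(images), length(images) >= 1)
  shp <- dim(images[[1]])
  for (im in images) check_same_shape(images[[1]], im, "cohort volumes")
  ids <- names(images) %||% as.character(seq_along(images))
  names(images) <- ids

  params <- model$params
  state <- adam_init(params)
  rows <- vector("list", 0L)
  step <- 0L

  run_step <- function(tid, sid, lr, stage, epoch) {
    pair <- make_pair_input(images[[tid]], images[[sid]])
    fwd <- snet_forward(list(cfg = model$cfg, params = params), pair$x,
                        keep_cache = TRUE)
    lg <- total_loss_grad(pair$subject, pair$template, fwd$field,
                          weights = config$weights,
                          invert_iter = config$invert_iter)
    if (!is.finite(lg$breakdown$total)) {
      stop(sprintf("non-finite loss at step %d (stage %d, template %s, subject %s)",
                   step + 1L, stage, tid, sid))
    }
    grads <- snet_backward(list(cfg = model$cfg, params = params), fwd$cache,
                           lg$grad)
    upd <- adam_step(params, grads, state, lr,
                     beta1 = config$adam$beta1, beta2 = config$adam$beta2,
                     eps = config$adam$eps)
    params <<- upd$params
    state <<- upd$state
    step <<- step + 1L
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(step = step, stage = stage, epoch = epoch,
                 template = tid, subject = sid, lr = lr),
      as.data.frame(lg$breakdown)
    )
    invisible(NULL)
  }

  with_seed(config$seed, {
    s1 <- config$stage1
    if (s1$iterations_per_pair > 0) {
      tid <- s1$template_id %||% ids[[1]]
      plan <- make_pairing_plan(ids, 1L, template_id = tid,
                                include_self = s1$include_self)
      for (r in seq_len(nrow(plan))) {
        if (!quiet) message(sprintf("stage 1: pair %d/%d", r, nrow(plan)))
        for (it in seq_len(s1$iterations_per_pair)) {
          run_step(plan$template[r], plan$subject[r], s1$lr, 1L, NA_integer_)
        }
      }
    }
    s2 <- config$stage2
    if (s2$epochs > 0) {
      plan <- make_pairing_plan(ids, 2L, include_self = s2$include_self)
      for (ep in seq_len(s2$epochs)) {
        lr <- stage2_lr(ep, s2$lr, s2$lr_decay, s2$decay_every)
        ord <- sample.int(nrow(plan))
        if (!quiet) message(sprintf("stage 2: epoch %d/%d (lr %.3g)", ep, s2$epochs, lr))
        for (r in ord) {
          run_step(plan$template[r], plan$subject[r], lr, 2L, ep)
        }
      }
    }
  })

  model$params <- params
  structure(
    list(model = model,
         history = if (length(rows)) do.call(rbind, rows) else
           data.frame(step = integer(), stage = integer(), epoch = integer(),
                      template = character(), subject = character(),
                      lr = numeric(), sim_sym = numeric(), sim_s_to_t = numeric(),
                      sim_t_to_s = numeric(), laplace = numeric(),
                      zero = numeric(), antifold = numeric(), total = numeric()),
         config = config),
    class = "snet_fit"
  )
}

#' @export
print.snet_fit <- function(x, ...) {
  cat(sprintf("Trained registration model: %d steps\n", nrow(x$history)))
  if (nrow(x$history)) {
    cat(sprintf("  total loss: %.5g (first) -> %.5g (last)\n",
                x$history$total[1], x$history$total[nrow(x$history)]))
  }
  invisible(x)
}

#' Register one image pair
#'
#' Predicts the halfway field, completes the full deformations, and returns
#' every product of a symmetric registration: the halfway fields (the
#' subject-side field is the exact negation of the template-side field), the
#' composed forward/backward deformations, the two pseudomean-space (middle)
#' warps, the two end-space warps (template resampled onto the subject grid
#' by the forward field, subject resampled onto the template grid by the
#' backward field), smoothness diagnostics of the composed forward field, and
#' the template-space SSD before/after registration (computed on normalized
#' intensities).
#'
#' @param model a trained (or fresh) [build_snet()] model.
#' @param template,subject intensity arrays on the model's grid.
#' @param invert_iter,invert_tol inversion settings for the composed fields.
#' @return Object of class `registration_result`.
#' @export
register_pair <- function(model, template, subject,
                          invert_iter = 30L, invert_tol = 1e-3) {
  pair <- make_pair_input(template, subject)
  phi_t <- predict_halfway(model, pair)
  phi_s <- negate_field(phi_t)
  comp <- compose_full_deformations(phi_t, invert_iter = invert_iter,
                                    invert_tol = invert_tol)
  ssd_pre <- mean((pair$subject - pair$template)^2)
  ssd_post <- mean((warp_image(pair$subject, comp$backward) - pair$template)^2)
  structure(
    list(
      phi_t = phi_t,
      phi_s = phi_s,
      forward = comp$forward,
      backward = comp$backward,
      middle_subject = warp_image(subject, phi_s),
      middle_template = warp_image(template, phi_t),
      warped_template = warp_image(template, comp$forward),
      warped_subject = warp_image(subject, comp$backward),
      diagnostics = field_diagnostics(comp$forward),
      diagnostics_halfway = field_diagnostics(phi_t),
      ssd_pre = ssd_pre,
      ssd_post = ssd_post
    ),
    class = "registration_result"
  )
}

#' @export
print.registration_result <- function(x, ...) {
  cat("Symmetric registration result\n")
  cat(sprintf("  max |halfway displacement|: %.3f voxels\n", max(abs(x$phi_t))))
  cat(sprintf("  template-space SSD: %.5g -> %.5g\n", x$ssd_pre, x$ssd_post))
  cat(sprintf("  folds of composed forward field: %d\n", x$diagnostics$fold_count))
  invisible(x)
}
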