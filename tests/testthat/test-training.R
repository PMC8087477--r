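test_that("pairing plans reproduce the cohort-size arithmetic", {
  ids30 <- sprintf("s%02d", 1:30)
  expect_equal(nrow(make_pairing_plan(ids30, 1L)), 30)
  expect_equal(nrow(make_pairing_plan(ids30, 2L)), 900)
  ids10 <- sprintf("s%02d", 1:10)
  expect_equal(nrow(make_pairing_plan(ids10, 2L, include_self = FALSE)), 90)
  expect_equal(nrow(make_pairing_plan(letters[1:5], 2L)), 25)

  p1 <- make_pairing_plan(ids10, 1L, template_id = "s03")
  expect_true(all(p1$template == "s03"))
  expect_error(make_pairing_plan(ids10, 1L, template_id = "zzz"), "template_id")
})

test_that("the stage-2 learning-rate schedule follows its closed form", {
  expect_equal(stage2_lr(1), 1e-5)
  expect_equal(stage2_lr(2), 5e-6)
  expect_equal(stage2_lr(4), 1e-5 * 0.5^2)
  expect_equal(stage2_lr(4, lr = 2e-5, lr_decay = 0.1, decay_every = 4L), 2e-6)
})

test_that("zero configured steps leave the model untouched with empty history", {
  model <- build_snet(snet_config(enc_channels = c(4L, 8L),
                                  dec_channels = c(8L, 8L, 4L)), seed = 2)
  imgs <- list(a = fixture_image(c(32, 32), seed = 1),
               b = fixture_image(c(32, 32), seed = 2))
  fit <- train_snet(model, imgs,
                    config = training_config(stage1 = list(iterations_per_pair = 0L)))
  expect_identical(fit$model$params, model$params)
  expect_equal(nrow(fit$history), 0)
})

test_that("a short training run lowers the loss and is seed-reproducible", {
  ph <- make_phantom(shape = c(32L, 32L), n_rois = 3L, seed = 6)
  model <- build_snet(snet_config(enc_channels = c(4L, 8L),
                                  dec_channels = c(8L, 8L, 4L)), seed = 6)
  cfgt <- training_config(stage1 = list(iterations_per_pair = 25L,
                                        template_id = "t", include_self = FALSE),
                          seed = 6)
  fit <- train_snet(model, list(t = ph$template, s = ph$subject), config = cfgt)
  expect_equal(nrow(fit$history), 25)
  expect_lt(fit$history$total[25], fit$history$total[1])

  fit2 <- train_snet(model, list(t = ph$template, s = ph$subject), config = cfgt)
  expect_identical(fit$history, fit2$history)
})

test_that("stage 2 visits every ordered pair per epoch with decayed rates", {
  co <- make_cohort(3, shape = c(32L, 32L), n_rois = 3L, seed = 7)
  model <- build_snet(snet_config(enc_channels = c(4L, 8L),
                                  dec_channels = c(8L, 8L, 4L)), seed = 7)
  fit <- train_snet(model, lapply(co, `[[`, "image"),
                    config = training_config(stage1 = list(iterations_per_pair = 0L),
                                             stage2 = list(epochs = 2L), seed = 7))
  expect_equal(nrow(fit$history), 2 * 9)
  expect_equal(unique(fit$history$lr), c(1e-5, 5e-6))
  ep1 <- fit$history[fit$history$epoch == 1, c("template", "subject")]
  expect_equal(nrow(unique(ep1)), 9)
})

test_that("registering an identical pair does not increase the SSD", {
  img <- make_phantom(shape = c(32L, 32L), n_rois = 3L, seed = 8,
                      deformation_amplitude = 0, noise_sd = 0)$template
  model <- build_snet(snet_config(enc_channels = c(4L, 8L),
                                  dec_channels = c(8L, 8L, 4L)), seed = 8)
  res <- register_pair(model, img, img)
  expect_lte(res$ssd_post, res$ssd_pre + 1e-8)
  expect_identical(res$phi_s, -res$phi_t)
})

test_that("training recovers alignment better than the affine-only baseline", {
  # known-deformation recovery at reduced scale: the mean endpoint error of
  # the composed subject-to-template map must beat the zero-field baseline
  ph <- make_phantom(shape = c(32L, 32L), n_rois = 3L, seed = 9)
  model <- build_snet(snet_config(enc_channels = c(8L, 16L),
                                  dec_channels = c(16L, 16L, 8L)), seed = 9)
  fit <- train_snet(model, list(t = ph$template, s = ph$subject),
                    config = training_config(stage1 = list(iterations_per_pair = 60L,
                                                           template_id = "t",
                                                           include_self = FALSE),
                                             seed = 9))
  res <- register_pair(fit$model, ph$template, ph$subject)
  m <- symmreg:::interior_mask(c(32, 32), 2L)
  epe <- function(f) {
    d <- f - ph$true_field
    mean(sqrt(d[, , 1]^2 + d[, , 2]^2)[m])
  }
  base <- epe(zero_field(c(32L, 32L)))
  expect_lt(epe(res$forward), base)
  expect_lt(res$ssd_post, res$ssd_pre)
})
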