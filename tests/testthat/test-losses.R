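test_that("similarity losses obey their closed forms at the identity", {
  img <- fixture_image(c(8, 8), seed = 1)
  z <- zero_field(c(8, 8))
  expect_equal(loss_sim_sym(img, img, z), 0)
  expect_equal(loss_sim_sym(img, img + 0.3, z), 0.09, tolerance = 1e-12)
  ends0 <- loss_sim_endspaces(img, img, z)
  expect_equal(as.vector(ends0), c(0, 0))
  ends <- loss_sim_endspaces(img, img + 0.25, z)
  expect_equal(as.vector(ends), c(0.0625, 0.0625), tolerance = 1e-12)
})

test_that("pseudomean similarity matches a warp-subtract-average oracle", {
  for (seed in 1:3) {
    is_ <- fixture_image(c(8, 8, 8), seed = seed)
    it_ <- fixture_image(c(8, 8, 8), seed = seed + 30)
    phi <- fixture_field(c(8, 8, 8), amplitude = 2, sigma = 2, seed = seed + 60)
    expected <- mean((oracle_warp(is_, -phi) - oracle_warp(it_, phi))^2)
    expect_equal(loss_sim_sym(is_, it_, phi), expected, tolerance = 1e-6)
  }
})

test_that("end-space similarities match the explicit invert-compose-warp chain", {
  is_ <- fixture_image(c(12, 12), seed = 4)
  it_ <- fixture_image(c(12, 12), seed = 5)
  phi <- fixture_field(c(12, 12), amplitude = 2, sigma = 3, seed = 6)
  inv_t <- invert_field(phi, max_iter = 30L, tol = 1e-3)
  inv_s <- invert_field(-phi, max_iter = 30L, tol = 1e-3)
  manual <- c(
    mean((oracle_warp(is_, compose_fields(-phi, inv_t)) - it_)^2),
    mean((oracle_warp(it_, compose_fields(phi, inv_s)) - is_)^2)
  )
  got <- loss_sim_endspaces(is_, it_, phi)
  expect_equal(as.vector(got), manual, tolerance = 1e-5)
  expect_true(attr(got, "converged"))
})

test_that("Laplacian loss vanishes on affine fields and matches hand/oracle values", {
  aff <- zero_field(c(8, 8, 8))
  for (a in 1:3) {
    aff[, , , a] <- 0.2 * symmreg:::axis_coord(c(8, 8, 8), a) - 0.7 +
      0.1 * symmreg:::axis_coord(c(8, 8, 8), (a %% 3) + 1)
  }
  expect_equal(loss_laplace(aff), 0, tolerance = 1e-20)

  quad <- zero_field(c(8, 8))
  quad[, , 1] <- symmreg:::axis_coord(c(8, 8), 1)^2
  expect_equal(loss_laplace(quad), 4, tolerance = 1e-12)

  rnd <- fixture_field(c(8, 8, 8), amplitude = 2, sigma = 2, seed = 7)
  expect_equal(loss_laplace(rnd), oracle_laplace(rnd), tolerance = 1e-10)
})

test_that("magnitude loss follows the squared-norm-per-voxel convention", {
  expect_equal(loss_zero(zero_field(c(8, 8))), 0)
  c122 <- zero_field(c(8, 8, 8))
  c122[, , , 1] <- 1; c122[, , , 2] <- 2; c122[, , , 3] <- 2
  expect_equal(loss_zero(c122), 9, tolerance = 1e-12)
  rnd <- fixture_field(c(8, 8), amplitude = 2, sigma = 2, seed = 8)
  expect_equal(loss_zero(rnd), sum(rnd^2) / 64, tolerance = 1e-10)
})

test_that("antifold loss triggers exactly when same-axis derivatives reach -1", {
  expect_equal(loss_antifold(zero_field(c(8, 8, 8))), 0)

  fold <- zero_field(c(8, 8, 8))
  fold[, , , 1] <- -1.5 * symmreg:::axis_coord(c(8, 8, 8), 1)
  # penalty |-1.5 + 1| = 0.5 wherever the forward difference exists
  expect_equal(loss_antifold(fold), 0.5 * 7 * 64 / 512, tolerance = 1e-12)

  gentle <- fixture_field(c(12, 12), amplitude = 1, sigma = 4, seed = 9)
  g <- spatial_gradient(gentle)
  stopifnot(max(abs(g[[1]][[1]]), abs(g[[2]][[2]])) < 0.5)
  expect_identical(loss_antifold(gentle), 0)
})

test_that("total loss recomposes from its terms with the published weights", {
  is_ <- fixture_image(c(8, 8), seed = 10)
  it_ <- fixture_image(c(8, 8), seed = 11)
  z <- zero_field(c(8, 8))
  lb0 <- total_loss(is_, is_, z)
  expect_equal(lb0$total, 0)

  w <- loss_weights()
  expect_equal(c(w$alpha, w$beta, w$gamma), c(1, 0.01, 100))

  phi <- fixture_field(c(8, 8), amplitude = 2, sigma = 2, seed = 12)
  lb <- total_loss(is_, it_, phi, w)
  manual <- lb$sim_sym + lb$sim_s_to_t + lb$sim_t_to_s +
    w$alpha * lb$laplace + w$beta * lb$zero + w$gamma * lb$antifold
  expect_equal(lb$total, manual, tolerance = 1e-10)
  for (nm in c("sim_sym", "sim_s_to_t", "sim_t_to_s", "laplace", "zero", "antifold")) {
    expect_gte(lb[[nm]], 0)
  }
})

test_that("total loss is linear in each balance weight", {
  is_ <- fixture_image(c(12, 12), seed = 13)
  it_ <- fixture_image(c(12, 12), seed = 14)
  phi <- fixture_field(c(12, 12), amplitude = 1.5, sigma = 3, seed = 15)
  base <- total_loss(is_, it_, phi, loss_weights(alpha = 0, beta = 0, gamma = 0))
  for (wname in c("alpha", "beta", "gamma")) {
    args <- list(alpha = 0, beta = 0, gamma = 0)
    args[[wname]] <- 2
    lb2 <- do.call(total_loss, c(list(is_, it_, phi), list(weights = do.call(loss_weights, args))))
    term <- switch(wname, alpha = base$laplace, beta = base$zero, gamma = base$antifold)
    expect_equal(lb2$total, base$total + 2 * term, tolerance = 1e-12)
  }
})

test_that("the analytic field gradient matches central finite differences", {
  set.seed(31)
  shp <- c(12, 12)
  is_ <- fixture_image(shp, seed = 16)
  it_ <- fixture_image(shp, seed = 17)
  phi <- fixture_field(shp, amplitude = 1.5, sigma = 3, seed = 18)
  w <- loss_weights()
  lg <- total_loss_grad(is_, it_, phi, w, invert_iter = 5L)
  # numeric differentiation under the same stop-gradient convention: the
  # inverse fields are held fixed while phi is perturbed
  inv_t0 <- invert_field(phi, max_iter = 5L, tol = 1e-6)
  inv_s0 <- invert_field(-phi, max_iter = 5L, tol = 1e-6)
  lossf <- function(p) {
    loss_sim_sym(is_, it_, p) +
      mean((warp_image(is_, compose_fields(-p, inv_t0)) - it_)^2) +
      mean((warp_image(it_, compose_fields(p, inv_s0)) - is_)^2) +
      w$alpha * loss_laplace(p) + w$beta * loss_zero(p) +
      w$gamma * loss_antifold(p)
  }
  eps <- 1e-5
  worst <- 0
  for (i in sample(length(phi), 20)) {
    p1 <- phi; p1[i] <- p1[i] + eps
    p2 <- phi; p2[i] <- p2[i] - eps
    worst <- max(worst, abs(lg$grad[i] - (lossf(p1) - lossf(p2)) / (2 * eps)))
  }
  expect_lt(worst, 1e-7)
})
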