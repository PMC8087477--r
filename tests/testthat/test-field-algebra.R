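test_that("negation is a bit-exact involution with the expected fixed points", {
  expect_identical(negate_field(zero_field(c(8, 8))), zero_field(c(8, 8)))

  phi <- zero_field(c(6, 6, 6))
  phi[, , , 1] <- 2
  neg <- negate_field(phi)
  expect_equal(unique(as.vector(neg[, , , 1])), -2)
  expect_true(all(neg[, , , 2:3] == 0))

  rnd <- fixture_field(c(8, 8, 8), amplitude = 2, sigma = 2, seed = 4)
  expect_identical(negate_field(negate_field(rnd)), rnd)
})

test_that("composition obeys identity and translation-group laws", {
  phi <- fixture_field(c(10, 10), amplitude = 2, sigma = 3, seed = 7)
  expect_equal(compose_fields(zero_field(c(10, 10)), phi), phi)

  t1 <- zero_field(c(12, 12, 12)); t1[, , , 1] <- 1.25; t1[, , , 2] <- -0.5
  t2 <- zero_field(c(12, 12, 12)); t2[, , , 1] <- 0.75; t2[, , , 3] <- 1
  c12 <- compose_fields(t1, t2)
  c21 <- compose_fields(t2, t1)
  # away from the clamped boundary the translations simply add and commute
  m <- symmreg:::interior_mask(c(12, 12, 12), 3L)
  for (a in 1:3) {
    expected <- t1[2, 2, 2, a] + t2[2, 2, 2, a]
    expect_equal(max(abs(c12[, , , a][m] - expected)), 0, tolerance = 1e-12)
    expect_equal(max(abs(c21[, , , a][m] - expected)), 0, tolerance = 1e-12)
  }
})

test_that("warping by a composed field equals warping twice", {
  img <- fixture_image(c(16, 16), seed = 21)
  outer <- fixture_field(c(16, 16), amplitude = 1.5, sigma = 3, seed = 22)
  inner <- fixture_field(c(16, 16), amplitude = 1.5, sigma = 3, seed = 23)
  two_step <- warp_image(warp_image(img, outer), inner)
  one_step <- warp_image(img, compose_fields(outer, inner))
  m <- symmreg:::interior_mask(c(16, 16), 3L)
  expect_lt(max(abs((two_step - one_step)[m])), 0.02)
})

test_that("fixed-point inversion recovers exact inverses where they are known", {
  z <- invert_field(zero_field(c(8, 8, 8)))
  expect_true(all(z == 0))
  expect_true(attr(z, "converged"))

  tr <- zero_field(c(12, 12, 12))
  tr[, , , 1] <- 1.5; tr[, , , 2] <- -1
  inv <- invert_field(tr)
  m <- symmreg:::interior_mask(c(12, 12, 12), 3L)
  expect_lt(max(abs((inv[, , , 1])[m] + 1.5)), 1e-6)
  expect_lt(max(abs((inv[, , , 2])[m] - 1)), 1e-6)
  expect_lt(max(abs((inv[, , , 3])[m])), 1e-6)
})

test_that("inversion residual of smooth fields is below 0.1 voxel in the interior", {
  for (seed in 1:3) {
    phi <- fixture_field(c(16, 16, 16), amplitude = 3, sigma = 4, seed = seed)
    psi <- invert_field(phi, max_iter = 30L, tol = 1e-3)
    expect_true(attr(psi, "converged"))
    resid <- compose_fields(phi, psi)
    expect_lt(max_interior(resid, 4L), 0.1)
  }
})

test_that("non-convergence is reported via the flag, not an error", {
  phi <- zero_field(c(8, 8))
  phi[, , 1] <- 2.5 * sin(symmreg:::axis_coord(c(8, 8), 1))
  expect_silent(psi <- invert_field(phi, max_iter = 1L, tol = 1e-12))
  expect_false(attr(psi, "converged"))
})

test_that("forward-difference gradient matches closed forms and the index oracle", {
  const <- zero_field(c(6, 6)); const[, , 1] <- 3; const[, , 2] <- -1
  g <- spatial_gradient(const)
  expect_true(all(vapply(g, function(ax) all(vapply(ax, function(cc) all(cc == 0), TRUE)), TRUE)))

  lin <- zero_field(c(8, 8))
  lin[, , 1] <- 0.3 * symmreg:::axis_coord(c(8, 8), 1)
  gl <- spatial_gradient(lin)
  expect_equal(max(abs(gl[[1]][[1]][1:7, ] - 0.3)), 0, tolerance = 1e-12)
  expect_true(all(gl[[1]][[1]][8, ] == 0))  # replicated edge

  rnd <- fixture_field(c(8, 8, 8), amplitude = 2, sigma = 2, seed = 11)
  gr <- spatial_gradient(rnd)
  comps <- symmreg:::field_components(rnd)
  for (a in 1:3) for (cc in 1:3) {
    expect_identical(gr[[a]][[cc]], oracle_forward_diff(comps[[cc]], a))
  }
})

test_that("Jacobian determinants match closed forms and the per-voxel oracle", {
  expect_equal(jacobian_determinant(zero_field(c(8, 8, 8))),
               array(1, c(8, 8, 8)))

  lin <- zero_field(c(8, 8, 8))
  lin[, , , 1] <- 0.25 * symmreg:::axis_coord(c(8, 8, 8), 1)
  det_lin <- jacobian_determinant(lin)
  expect_equal(max(abs(det_lin[2:7, , ] - 1.25)), 0, tolerance = 1e-12)

  for (seed in 1:3) {
    phi2 <- fixture_field(c(8, 8), amplitude = 1.5, sigma = 2, seed = seed)
    expect_equal(jacobian_determinant(phi2), oracle_jacobian(phi2), tolerance = 1e-10)
    phi3 <- fixture_field(c(8, 8, 8), amplitude = 1.5, sigma = 2, seed = seed + 10)
    expect_equal(jacobian_determinant(phi3), oracle_jacobian(phi3), tolerance = 1e-10)
  }
})

test_that("anisotropic spacing rescales the determinant of a linear field", {
  lin <- zero_field(c(8, 8))
  lin[, , 1] <- 0.2 * symmreg:::axis_coord(c(8, 8), 2)  # shear dphi_x/dy
  iso <- jacobian_determinant(lin)
  aniso <- jacobian_determinant(lin, spacing = c(1, 2))
  expect_equal(iso, array(1, c(8, 8)))  # pure shear: det 1
  expect_equal(aniso, array(1, c(8, 8)))
  stretch <- zero_field(c(8, 8))
  stretch[, , 1] <- 0.2 * symmreg:::axis_coord(c(8, 8), 1)
  expect_equal(jacobian_determinant(stretch, spacing = c(1, 2))[3, 3],
               jacobian_determinant(stretch)[3, 3])
})

test_that("fold counting matches the derived interior count and zero cases", {
  expect_identical(count_folds(zero_field(c(8, 8, 8))), 0L)

  fold <- zero_field(c(8, 8, 8))
  fold[, , , 1] <- -1.5 * symmreg:::axis_coord(c(8, 8, 8), 1)
  # interior determinant 1 - 1.5 = -0.5 < 0 at every interior voxel
  expect_identical(count_folds(fold), 216L)

  small <- fixture_field(c(12, 12, 12), amplitude = 0.3, sigma = 3, seed = 9)
  expect_identical(count_folds(small), 0L)

  d <- field_diagnostics(fold)
  expect_identical(d$fold_count, 216L)
  expect_lt(d$min_det, 0)
  expect_output(print(d), "folds")
})
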