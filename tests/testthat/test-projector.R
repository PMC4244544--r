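test_that("forward projection reproduces analytic chord integrals", {
  # fine grid so the pixelised disc is within 1% of the analytic chord
  n <- 128L; sp <- 1.71875
  geom <- spect_geometry(60L, n, sp)
  idx <- (seq_len(n) - (n + 1) / 2) * sp
  xx <- outer(idx, rep(1, n)); yy <- outer(rep(1, n), idx)
  disc <- (xx^2 + yy^2 <= 80^2) * 50
  p <- forward_project(spect_image(disc, sp, "Bq/mL"), geom)
  central <- max(p[, 1, 1])
  expect_rel(central, 160 * 50, 0.01)

  # zero image -> zero sinogram
  expect_equal(max(abs(forward_project(matrix(0, 64, 64) |> array(c(64, 64, 1)),
                                       fix_geometry()))), 0)
})

test_that("attenuation applies the closed-form exponential along the chord", {
  geom <- fix_geometry()
  n <- 64L; sp <- geom$bin_mm
  idx <- (seq_len(n) - (n + 1) / 2) * sp
  xx <- outer(idx, rep(1, n)); yy <- outer(rep(1, n), idx)
  mu <- array((xx^2 + yy^2 <= 80^2) * 0.160, c(n, n, 1))
  # source voxel at the far (-y) edge of the disc, central column
  src <- array(0, c(n, n, 1))
  j <- min(which(mu[33, , 1] > 0))
  src[33, j, 1] <- 1
  p0 <- forward_project(src, geom)
  pa <- forward_project(src, geom, mu_map = mu)
  trans <- pa[33, 1, 1] / p0[33, 1, 1]
  # oracle: discrete optical depth from the voxel centre to the +y exit
  path <- sum(mu[33, j:n, 1]) - 0.5 * mu[33, j, 1]
  expect_equal(trans, exp(-0.1 * sp * path), tolerance = 1e-12)
  # magnitude matches the nominal 16-cm water chord factor exp(-2.56)
  expect_equal(trans, exp(-2.56), tolerance = 0.1)
})

test_that("back-projection is the exact adjoint of forward projection", {
  geom <- spect_geometry(30L, 32L, 4)
  set.seed(42)
  for (rep in 1:3) {
    x <- array(stats::runif(32 * 32), c(32, 32, 1))
    y <- array(stats::runif(32 * 30), c(32, 30, 1))
    lhs <- sum(forward_project(x, geom) * y)
    rhs <- sum(x * back_project(y, geom))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
  }
})

test_that("back-projection basics: delta ridge and zero input", {
  geom <- fix_geometry()
  z <- back_project(array(0, c(64, 60, 1)), geom)
  expect_equal(max(abs(z)), 0)
  # single-view back-projection of a delta bin is a straight ridge
  p <- array(0, c(64, 60, 1)); p[32, 1, 1] <- 1
  g1 <- geom; img <- back_project(p, g1)[, , 1]
  expect_true(all(img[32, ] > 0))          # the ridge column
  expect_equal(sum(img[-c(31, 32, 33), ]), 0, tolerance = 1e-12)
})

test_that("projection is equivariant under 90-degree rotations", {
  geom <- fix_geometry()   # 60 views over 360: 90 deg = 15 views
  set.seed(7)
  img <- matrix(0, 64, 64)
  img[20:40, 15:30] <- stats::runif(21 * 16)
  rot90 <- t(img)[64:1, ]  # quarter turn: img'[i, j] = img[j, n + 1 - i]
  p0 <- forward_project(array(img, c(64, 64, 1)), geom)
  p90 <- forward_project(array(rot90, c(64, 64, 1)), geom)
  for (v in 1:45) {
    expect_equal(p90[, v, 1], p0[, v + 15, 1], tolerance = 1e-9)
  }
})

test_that("count bookkeeping: noiseless projections equal sensitivity-weighted line integrals", {
  prof <- fix_profile_c()
  ph <- fix_phantom()
  sim <- simulate_dual_injection_study(ph, prof, fix_schedule(), seed = 1L,
                                       noise = FALSE, scatter = FALSE,
                                       offset = FALSE,
                                       precomp = fix_precomp("C")$factors)
  # oracle: project the collimator-blurred total activity of frame 1 directly
  act <- sim$truth$frame_activity[1, ]
  amap <- cbfspect:::label_image(ph, act)
  blur <- gaussian_smooth(spect_image(amap, ph$spacing_mm, "Bq/mL"),
                          cbfspect:::collimator_fwhm(prof))
  expected <- pmax(forward_project(blur, sim$geometry,
                                   mu_map = phantom_mu(ph)) *
                     cbfspect:::profile_sensitivity(prof) * 4, 0)
  got <- sim$rest$counts[, , , 1]
  expect_lt(max(abs(got - expected)) / max(expected), 1e-6)
})
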