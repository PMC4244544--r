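cyl_static <- function(noise = FALSE, seed = 1L, scatter = TRUE, offset = TRUE,
                       activity = NULL) {
  cyl <- make_cylinder_phantom(160, 50000, "disc")
  sim <- simulate_static_study(cyl, fix_profile_c(), duration_min = 28,
                               seed = seed, noise = noise, scatter = scatter,
                               offset = offset, activity = activity)
  list(cyl = cyl, sim = sim, sino = ps_sum(sim$proj))
}

test_that("FBP support detection: disc Dice, point location, zero input", {
  cs <- fixture("cyl_clean", cyl_static(noise = FALSE, scatter = FALSE,
                                        offset = FALSE))
  geom <- cs$sim$geometry
  fbp <- reconstruct_uncorrected(cs$sino, geom)
  truth <- phantom_mask(cs$cyl, "source")
  est <- as.array(fbp) > 0.5 * cbfspect:::robust_max(as.array(fbp))
  dice <- 2 * sum(est & truth) / (sum(est) + sum(truth))
  expect_gt(dice, 0.9)

  z <- reconstruct_uncorrected(array(0, c(64, 60, 1)), geom)
  expect_equal(max(abs(as.array(z))), 0)

  pt <- make_cylinder_phantom(shape = "point", activity_bqml = 1e5)
  ps <- simulate_static_study(pt, fix_profile_c(), duration_min = 28, seed = 1L,
                              noise = FALSE, scatter = FALSE, offset = FALSE)
  pf <- reconstruct_uncorrected(ps_sum(ps$proj), geom)
  pk <- which(as.array(pf)[, , 1] == max(as.array(pf)), arr.ind = TRUE)
  ctr <- which(as.array(phantom_activity(pt))[, , 1] > 0, arr.ind = TRUE)
  expect_lte(max(abs(pk - ctr)), 1)
})

test_that("threshold-based mu-map: area, uniform value, failure on empty input", {
  cs <- fixture("cyl_clean", cyl_static(noise = FALSE, scatter = FALSE,
                                        offset = FALSE))
  fbp <- reconstruct_uncorrected(cs$sino, cs$sim$geometry)
  mm <- estimate_mu_map(fbp)          # default half-maximum threshold
  true_area <- sum(phantom_mask(cs$cyl, "source"))
  expect_lt(abs(sum(mm$mask) / true_area - 1), 0.05)
  expect_true(all(as.array(mm$mu)[mm$mask] == 0.160))
  expect_true(all(as.array(mm$mu)[!mm$mask] == 0))
  zero <- spect_image(array(0, c(64, 64, 1)), 3.4375)
  expect_error(estimate_mu_map(zero), "empty")
})

test_that("TDCS reduces to identities in its degenerate configurations", {
  cs <- fixture("cyl_clean", cyl_static(noise = FALSE, scatter = FALSE,
                                        offset = FALSE))
  geom <- cs$sim$geometry
  mm <- estimate_mu_map(reconstruct_uncorrected(cs$sino, geom))
  # A = 1, B = 0, no offset: scatter fraction is identically 0
  p1 <- tdcs_scatter_correct(cs$sino, mm, geom,
                             scatter_params(A = 1, B = 0, offset_fraction = 0))
  expect_equal(as.numeric(p1), as.numeric(cs$sino), tolerance = 1e-12)
  # offset only: output = input - offset, clipped at zero
  p2 <- tdcs_scatter_correct(cs$sino, mm, geom,
                             scatter_params(A = 1, B = 0, offset_fraction = 0.1))
  off <- 0.1 * mean(cs$sino)
  expect_equal(as.numeric(p2), as.numeric(pmax(cs$sino - off, 0)),
               tolerance = 1e-9)
  expect_error(scatter_params(A = 1.5, B = 1, beta = 0.5), "scatter fraction")
})

test_that("TDCS removes the simulator's known scatter to within 3%", {
  clean <- fixture("cyl_clean", cyl_static(noise = FALSE, scatter = FALSE,
                                           offset = FALSE))
  dirty <- cyl_static(noise = FALSE, scatter = TRUE, offset = TRUE)
  geom <- dirty$sim$geometry
  mm <- estimate_mu_map(reconstruct_uncorrected(dirty$sino, geom))
  corr <- tdcs_scatter_correct(dirty$sino, mm, geom, fix_profile_c()$scatter)
  expect_lt(abs(sum(corr) / sum(clean$sino) - 1), 0.03)
})

test_that("OSEM recovers a noiseless uniform disc and stays non-negative", {
  cs <- fixture("cyl_clean", cyl_static(noise = FALSE, scatter = FALSE,
                                        offset = FALSE))
  geom <- cs$sim$geometry
  mm <- estimate_mu_map(reconstruct_uncorrected(cs$sino, geom))
  rec <- osem_reconstruct(cs$sino, mm, geom)
  expect_true(all(as.array(rec) >= 0))
  truth <- 50000 * cbfspect:::profile_sensitivity(fix_profile_c()) * 28
  roi <- erode_mask(phantom_mask(cs$cyl, "source"), cs$cyl$spacing_mm, 20)
  expect_rel(mask_mean(rec, roi), truth, 0.03)
  # zero projections give a zero image
  z <- osem_reconstruct(array(0, c(64, 60, 1)), mm, geom)
  expect_lt(max(as.array(z)), 1e-10)
})

test_that("EM fixed point: reprojecting the noiseless reconstruction preserves totals", {
  cs <- fixture("cyl_clean", cyl_static(noise = FALSE, scatter = FALSE,
                                        offset = FALSE))
  geom <- cs$sim$geometry
  mm <- estimate_mu_map(reconstruct_uncorrected(cs$sino, geom))
  rec <- osem_reconstruct(cs$sino, mm, geom, post_fwhm_mm = 0)
  half <- spect_geometry(30L, 64L, geom$bin_mm, span_deg = 180)
  reproj <- forward_project(rec, half)
  # corrected geometric-mean data the EM actually fitted
  gm <- cbfspect:::combine_opposed(cs$sino[, , 1], geom)
  corr <- cbfspect:::gm_attenuation_correction(
    matrix(as.numeric(mm$mask[, , 1]), 64, 64), as.array(mm$mu)[, , 1], geom)
  expect_lt(abs(sum(reproj) / sum(gm * corr$factor) - 1), 0.02)
})

test_that("scatter correction improves cold-spot contrast", {
  cyl <- make_cylinder_phantom(160, 50000, "disc")
  idx <- (seq_len(64) - 32.5) * 3.4375
  xx <- outer(idx, rep(1, 64)); yy <- outer(rep(1, 64), idx)
  cold <- (xx + 25)^2 + yy^2 <= 25^2
  act <- array(50000 * (xx^2 + yy^2 <= 80^2), c(64, 64, 1))
  act[cold] <- 10000
  sim <- simulate_static_study(cyl, fix_profile_c(), duration_min = 28,
                               seed = 4L, noise = FALSE,
                               activity = spect_image(act, 3.4375, "Bq/mL"))
  geom <- sim$geometry
  sino <- ps_sum(sim$proj)
  mm <- estimate_mu_map(reconstruct_uncorrected(sino, geom))
  contrast <- function(img) {
    hot <- array((xx - 30)^2 + yy^2 <= 20^2, c(64, 64, 1))
    coldroi <- array((xx + 25)^2 + yy^2 <= 12^2, c(64, 64, 1))
    1 - mask_mean(img, coldroi) / mask_mean(img, hot)
  }
  before <- contrast(osem_reconstruct(sino, mm, geom))
  after <- contrast(osem_reconstruct(
    tdcs_scatter_correct(sino, mm, geom, fix_profile_c()$scatter), mm, geom))
  expect_gte(after, before)
})

test_that("BCF and CCF calibrations: identities and linearity", {
  # image already in Bq/mL over exactly the source mask -> BCF = 1
  mask <- array(FALSE, c(16, 16, 1)); mask[5:12, 5:12, 1] <- TRUE
  img <- spect_image(array(mask * 700, c(16, 16, 1)), 4, "Bq/mL")
  expect_equal(calibrate_bcf(img, 700, mask), 1, tolerance = 1e-12)
  expect_error(calibrate_bcf(spect_image(array(0, c(16, 16, 1)), 4), 700, mask),
               "zero mean")
  expect_equal(calibrate_ccf(img, 700, mask), 1, tolerance = 1e-12)
  expect_equal(calibrate_ccf(img, 1400, mask), 2, tolerance = 1e-12)
  expect_error(calibrate_ccf(spect_image(array(0, c(16, 16, 1)), 4), 1, mask),
               "zero mean")

  # halving the simulated sensitivity doubles the measured BCF
  prof <- fix_profile_c()
  prof_half <- prof; prof_half$sensitivity_scale <- prof$sensitivity_scale / 2
  syr <- make_cylinder_phantom(30, 80000, "disc")
  bcf_of <- function(p) {
    s <- simulate_static_study(syr, p, duration_min = 10, seed = 3L,
                               noise = FALSE)
    sino <- ps_sum(s$proj)
    mm <- estimate_mu_map(reconstruct_uncorrected(sino, s$geometry))
    rec <- reconstruct_quantitative(sino, mm, s$geometry, 1, p$scatter)
    calibrate_bcf(rec, 80000, phantom_mask(syr, "source"))
  }
  expect_rel(bcf_of(prof_half) / bcf_of(prof), 2, 1e-6)
})
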