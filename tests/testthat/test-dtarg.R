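test_that("input-function calibration: identity, linearity, simulator round trip", {
  std <- standard_input_function(150)
  # well sample consistent with the standard curve -> identity
  w <- 0.9 * input_value(std, 10)
  cal <- calibrate_input_function(std, w, ccf = 0.9)
  expect_equal(cal$value_bqml, std$value_bqml, tolerance = 1e-12)
  # doubling the sample doubles the curve
  cal2 <- calibrate_input_function(std, 2 * w, ccf = 0.9)
  expect_equal(cal2$value_bqml, 2 * std$value_bqml, tolerance = 1e-12)
  expect_error(calibrate_input_function(const_input(0), 1, 1), "zero")
  # end to end with the scanner's true CCF: the simulated blood sample
  # reproduces the simulator's input exactly (noise off)
  nx <- fix_noiseless_study()
  truth <- nx$sim$inputs$first
  cal_true <- calibrate_input_function(
    standard_input_function(fix_profile_c()$dose_mbq),
    nx$sim$blood_sample, fix_profile_c()$ccf)
  at <- c(1, 5, 10, 20, 28)
  expect_lt(max(abs(input_value(cal_true, at) / input_value(truth, at) - 1)),
            0.01)
  # with the CCF measured from the cylinder experiment, the residual is the
  # cylinder reconstruction bias (a few percent)
  fit <- fix_noiseless_fit()
  expect_lt(max(abs(input_value(fit$input1, at) / input_value(truth, at) - 1)),
            0.03)
})

test_that("look-up table: zero flow, monotone, constant-input closed form", {
  tab <- fixture("table_c_028", build_lookup_table(
    standard_input_function(155.9), window = c(0, 28)))
  expect_equal(tab$activity[tab$flow == 0], 0)
  expect_true(all(diff(tab$activity) > 0))
  # constant input c: window mean over [0, T] of Vd c (1 - e^(-f t / Vd))
  cc <- 120; Tn <- 28; f <- 0.35; vd <- 35; k <- f / vd
  tabc <- build_lookup_table(const_input(cc), window = c(0, Tn),
                             flow_grid = c(0, 0.35, 0.7))
  analytic <- vd * cc * (1 - (1 - exp(-k * Tn)) / (k * Tn))
  expect_rel(tabc$activity[tabc$flow == 0.35], analytic, 1e-3)
  # non-monotone input (all-zero) is rejected
  expect_error(build_lookup_table(const_input(0), window = c(0, 28)),
               "increasing")
})

test_that("look-up inversion: round trip, clamping, zero", {
  tab <- fixture("table_c_028", build_lookup_table(
    standard_input_function(155.9), window = c(0, 28)))
  const <- kinetic_constants()
  cbf_in <- c(10, 25.8, 35.7, 51.7, 80)
  act <- cbfspect:::lookup_forward(tab, cbfspect:::cbf_to_flow(cbf_in, const))
  back <- invert_lookup(tab, act)
  expect_lt(max(abs(back - cbf_in)), 0.1)
  expect_equal(as.numeric(invert_lookup(tab, 0)), 0)
  over <- suppressWarnings(invert_lookup(tab, max(tab$activity) * 1.5))
  expect_equal(as.numeric(over), cbfspect:::flow_to_cbf(max(tab$flow), const))
  expect_equal(attr(over, "n_clamped"), 1L)
  expect_error(invert_lookup(tab, -1), "negative")
})

test_that("global CBF estimate honours the mask and recovers simulated truth", {
  nx <- fix_noiseless_study()
  tab <- rescale_lookup_table(nx$pre$base_tables$t2428,
                              attr(fix_noiseless_fit()$input1,
                                   "calibration_scale"))
  gmc <- fix_noiseless_fit()$gm_core
  g <- estimate_global_cbf(nx$img_frame7, gmc, tab)
  expect_rel(g, 35.7, 0.05)
  # zero image -> zero estimate; WM voxels cannot influence the value
  zero <- spect_image(array(0, dim(as.array(nx$img_frame7))), 3.4375)
  expect_equal(estimate_global_cbf(zero, gmc, tab), 0)
  img2 <- nx$img_frame7
  wm <- phantom_mask(fix_phantom(), "white_matter")
  img2$data[wm] <- 99999
  expect_equal(estimate_global_cbf(img2, gmc, tab),
               estimate_global_cbf(nx$img_frame7, gmc, tab))
  expect_error(estimate_global_cbf(nx$img_frame7, array(FALSE, dim(wm)), tab),
               "empty")
})

test_that("consistency scaling: fixed point, monotonicity, brute-force oracle", {
  tab <- fixture("table_c_028", build_lookup_table(
    standard_input_function(155.9), window = c(0, 28)))
  const <- kinetic_constants()
  ph <- fix_phantom()
  gm <- phantom_mask(ph, "gm", tissue = TRUE)
  # image consistent with the table: s = 1
  act <- cbfspect:::lookup_forward(tab, cbfspect:::cbf_to_flow(35.7, const))
  img <- spect_image(array(act * gm, dim(gm)), ph$spacing_mm, "Bq/mL")
  s1 <- scale_lookup_table(tab, img, gm, 35.7)
  expect_lt(abs(attr(s1, "scale_s") - 1), 1e-3)
  # monotone: a larger target needs a smaller axis scale
  s_small <- attr(scale_lookup_table(tab, img, gm, 30), "scale_s")
  s_large <- attr(scale_lookup_table(tab, img, gm, 42), "scale_s")
  expect_gt(s_small, s_large)
  # brute-force grid search over s agrees with the bisection
  target <- 31.4
  vox <- act
  gsearch <- seq(0.5, 2, by = 5e-4)
  err <- vapply(gsearch, function(s) {
    abs(mean(invert_lookup(rescale_lookup_table(tab, s), vox)) - target)
  }, numeric(1))
  s_brute <- gsearch[which.min(err)]
  s_bis <- attr(scale_lookup_table(tab, img, gm, target), "scale_s")
  expect_lt(abs(s_bis - s_brute), 2e-3)
  expect_error(scale_lookup_table(tab, img, gm, 1e6), "no consistency scale")
})

test_that("rest CBF orchestration recovers a noiseless brain within 5%", {
  fit <- fix_noiseless_fit()
  gmc <- fit$gm_core
  expect_rel(mask_mean(fit$rest, gmc), 35.7, 0.05)
  wm_core <- erode_mask(phantom_mask(fix_phantom(), "white_matter"),
                        3.4375, 8)
  expect_rel(mask_mean(fit$rest, wm_core), 25.8, 0.10)
  # all-zero frames give an all-zero CBF map
  zero <- spect_image(array(0, dim(as.array(fit$rest))), 3.4375, "Bq/mL")
  out <- compute_rest_cbf(list(zero, zero),
                          frame_start_min = c(0, 24), frame_dur_min = c(24, 4),
                          input = fit$input1, gm_mask = gmc)
  expect_equal(max(as.array(out)), 0)
})

test_that("extra-cranial accumulation outside the head mask cannot bias GM CBF", {
  fit <- fix_noiseless_fit()
  nx <- fix_noiseless_study()
  img <- nx$img_mean_rest
  outside <- !nx$mu$mask
  # plant a parotid-like hot source outside the head mask
  hot <- img
  w <- which(outside[, , 1], arr.ind = TRUE)
  pick <- w[w[, 1] <= 5, , drop = FALSE][1:8, ]
  hot$data[cbind(pick, 1)] <- max(img$data) * 3
  rest_hot <- compute_rest_cbf(hot, input = fit$input1, gm_mask = fit$gm_core,
                               head_mask = nx$mu$mask,
                               frame_24_28 = nx$img_frame7)
  expect_equal(mask_mean(rest_hot, fit$gm_core),
               mask_mean(fit$rest, fit$gm_core), tolerance = 1e-10)
  expect_equal(sum(as.array(rest_hot)[outside]), 0)
})

test_that("background prediction: zero flow, monotonicity, simulator round trip", {
  fit <- fix_noiseless_fit()
  zero <- spect_image(array(0, dim(as.array(fit$rest))), 3.4375, "mL/min/100g")
  expect_equal(max(as.array(predict_background(zero, fit$input1))), 0)
  # monotone in rest CBF on a value grid
  tabbg <- build_lookup_table(fit$input1, window = c(30, 58))
  grid_cbf <- seq(5, 90, by = 5)
  vals <- cbfspect:::lookup_forward(
    tabbg, cbfspect:::cbf_to_flow(grid_cbf, kinetic_constants()))
  expect_true(all(diff(vals) > 0))
  # round trip: predicted background from true rest CBF matches the
  # simulator's first-injection residue (noise off) to < 2%
  ph <- fix_phantom()
  truth_cbf <- phantom_cbf(ph, "rest")
  bg_pred <- predict_background(truth_cbf, fix_noiseless_study()$sim$inputs$first)
  comp <- ph$compartments
  f_rest <- cbfspect:::cbf_to_flow(comp$cbf_rest, kinetic_constants())
  resid <- cbfspect:::tissue_window_mean(f_rest, 35,
                                         fix_noiseless_study()$sim$inputs$first,
                                         c(30, 58))
  for (lab in c(4L, 3L)) {   # cortex, white matter
    m <- ph$labels == lab
    expect_rel(mean(as.array(bg_pred)[m]), resid[comp$label == lab], 0.02)
  }
})

test_that("acetazolamide CBF: recovery, degenerate cases, CVR identities", {
  fit <- fix_noiseless_fit()
  gmc <- fit$gm_core
  expect_rel(mask_mean(fit$acz, gmc), 51.7, 0.07)
  expect_lt(abs(mask_mean(fit$cvr, gmc) - 100 * (51.7 - 35.7) / 35.7), 5)
  # second scan identical to the predicted background -> zero CBF
  z <- compute_acz_cbf(fit$bg, fit$bg, fit$input2,
                       scale_s = attr(fit$rest, "scale_s"))
  expect_equal(max(as.array(z)), 0)
  # CVR identities
  r <- fit$rest
  expect_equal(max(abs(as.array(compute_cvr(r, r)))), 0)
  r2 <- r; r2$data <- 2 * r$data
  cvr2 <- compute_cvr(r, r2)
  expect_equal(max(abs(as.array(cvr2)[as.array(r) > 0] - 100)), 0,
               tolerance = 1e-9)
  # invariant to a common multiplicative calibration error
  ra <- fit$rest; rb <- fit$acz
  ra2 <- ra; ra2$data <- 1.17 * ra$data
  rb2 <- rb; rb2$data <- 1.17 * rb$data
  expect_equal(as.array(compute_cvr(ra2, rb2)), as.array(compute_cvr(ra, rb)),
               tolerance = 1e-12)
})

test_that("without acetazolamide response the two scans give matching CBF", {
  ph0 <- make_brain_phantom(gm_cbf_acz = 35.7, wm_cbf_acz = 25.8)
  prof <- fix_profile_c()
  sim <- simulate_dual_injection_study(ph0, prof, fix_schedule(), seed = 6L,
                                       noise = FALSE)
  geom <- sim$geometry
  mu <- estimate_mu_map(reconstruct_uncorrected(ps_sum(sim$rest), geom), 0.10)
  pre <- fix_precomp("C")
  recq <- function(s) reconstruct_quantitative(s, mu, geom, bcf = pre$bcf,
                                               scatter = prof$scatter)
  std <- standard_input_function(prof$dose_mbq)
  calib <- calibrate_input_function(std, sim$blood_sample, pre$ccf)
  gmc <- gm_core_mask(ph0)
  rest <- compute_rest_cbf(recq(ps_sum(sim$rest)), input = calib,
                           gm_mask = gmc, head_mask = mu$mask,
                           frame_24_28 = recq(ps_sum(sim$rest, 7)))
  bg <- predict_background(rest, calib)
  acz <- compute_acz_cbf(recq(ps_sum(sim$acz)), bg,
                         scale_input(standard_input_function(prof$dose_mbq,
                                                             t_inject_min = 30),
                                     attr(calib, "calibration_scale")),
                         head_mask = mu$mask, scale_s = attr(rest, "scale_s"))
  expect_lt(abs(mask_mean(acz, gmc) / mask_mean(rest, gmc) - 1), 0.05)
})
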