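# Shared fixtures, computed lazily once per test run and cached across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

fix_geometry <- function() fixture("geom", spect_geometry(60L, 64L, 3.4375))

fix_phantom <- function() fixture("phantom", make_brain_phantom())

fix_schedule <- function() fixture("schedule", acquisition_schedule())

fix_profile_c <- function() default_institutions()$C

# per-institution calibration + precomputation bundles
fix_precomp <- function(inst = "C") {
  fixture(paste0("precomp_", inst), prepare_institution(
    default_institutions()[[inst]], fix_phantom(), fix_schedule(),
    seed = 5L, noise = TRUE
  ))
}

# noise-free calibration bundles (used by the noiseless-recovery contracts)
fix_precomp_clean <- function(inst = "C") {
  fixture(paste0("precomp_clean_", inst), prepare_institution(
    default_institutions()[[inst]], fix_phantom(), fix_schedule(),
    seed = 5L, noise = FALSE
  ))
}

# noiseless dual-injection study at institution C plus its reconstructions
fix_noiseless_study <- function() {
  fixture("noiseless_c", {
    prof <- fix_profile_c()
    ph <- fix_phantom()
    sim <- simulate_dual_injection_study(ph, prof, fix_schedule(), seed = 3L,
                                         noise = FALSE, scatter = TRUE,
                                         offset = TRUE,
                                         precomp = fix_precomp_clean("C")$factors)
    geom <- sim$geometry
    mu <- estimate_mu_map(reconstruct_uncorrected(ps_sum(sim$rest), geom), 0.10)
    pre <- fix_precomp_clean("C")
    recq <- function(s) reconstruct_quantitative(s, mu, geom, bcf = pre$bcf,
                                                 scatter = prof$scatter)
    list(
      sim = sim, mu = mu, geom = geom, pre = pre,
      img_mean_rest = recq(ps_sum(sim$rest)),
      img_frame7 = recq(ps_sum(sim$rest, 7)),
      img_mean_second = recq(ps_sum(sim$acz))
    )
  })
}

# the DTARG fit of the noiseless study
fix_noiseless_fit <- function() {
  fixture("noiseless_fit", {
    nx <- fix_noiseless_study()
    ph <- fix_phantom()
    std <- standard_input_function(fix_profile_c()$dose_mbq)
    calib <- calibrate_input_function(std, nx$sim$blood_sample, nx$pre$ccf)
    gmc <- gm_core_mask(ph)
    rest <- compute_rest_cbf(nx$img_mean_rest, input = calib, gm_mask = gmc,
                             head_mask = nx$mu$mask,
                             frame_24_28 = nx$img_frame7)
    input2 <- scale_input(standard_input_function(fix_profile_c()$dose_mbq,
                                                  t_inject_min = 30),
                          attr(calib, "calibration_scale"))
    bg <- predict_background(rest, calib)
    acz <- compute_acz_cbf(nx$img_mean_second, bg, input2,
                           head_mask = nx$mu$mask,
                           scale_s = attr(rest, "scale_s"))
    list(rest = rest, acz = acz, cvr = compute_cvr(rest, acz),
         input1 = calib, input2 = input2, bg = bg, gm_core = gmc)
  })
}

# small two-institution noisy study used by pipeline / io / tidier tests
fix_small_report <- function() {
  fixture("small_report", {
    cfg <- study_config(n_subjects = 2L,
                        institutions = default_institutions()[c("B", "C")],
                        seed = 11L)
    run_multicenter_comparison(cfg, precomps = list(B = fix_precomp("B"),
                                                    C = fix_precomp("C")))
  })
}

# constant-valued input function on a fine grid (analytic oracles)
const_input <- function(value, t_end = 70) {
  tg <- seq(0, t_end, by = 0.05)
  cbfspect:::new_input_function(tg, rep(value, length(tg)), 1, 0)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
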