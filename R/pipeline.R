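#' Multicentre study configuration
#'
#' Bundles everything a full simulated multicentre run needs: the institution
#' profiles, subjects per institution, the phantom and schedule, seeds and
#' process toggles. Inter-subject variability is a multiplicative log-normal
#' factor on global CBF (both conditions jointly, so true CVR is preserved)
#' with a default coefficient of variation of 16%, the inter-subject spread
#' reported for healthy cohorts with this technique.
#'
#' @param institutions named list of [institution_profile()]s.
#' @param n_subjects subjects per institution; `NULL` uses each profile's
#'   enrolment.
#' @param phantom a brain `phantom_spec` shared by all subjects.
#' @param schedule an [acquisition_schedule()].
#' @param seed master seed; every random draw derives from it.
#' @param noise Poisson noise toggle.
#' @param subject_cv coefficient of variation of the per-subject global CBF
#'   factor (0 disables inter-subject variability).
#' @param equalize run the resolution-equalized analysis.
#' @param gm_margin_mm erosion margin of the cortical-core gray-matter mask.
#' @param head_threshold mu-map threshold fraction for head outlines.
#' @return A `study_config`.
#' @export
study_config <- function(institutions = default_institutions(),
                         n_subjects = NULL,
                         phantom = make_brain_phantom(),
                         schedule = acquisition_schedule(),
                         seed = 1L, noise = TRUE, subject_cv = 0.16,
                         equalize = TRUE, gm_margin_mm = 8,
                         head_threshold = 0.10) {
  stopifnot(length(institutions) >= 1L)
  if (is.null(n_subjects)) {
    n_subjects <- unname(vapply(institutions, `[[`, integer(1), "n_subjects"))
  } else if (length(n_subjects) == 1L) {
    n_subjects <- rep(as.integer(n_subjects), length(institutions))
  }
  stopifnot(length(n_subjects) == length(institutions), all(n_subjects >= 1L))
  structure(
    list(institutions = institutions, n_subjects = n_subjects,
         phantom = phantom, schedule = schedule, seed = as.integer(seed),
         noise = noise, subject_cv = subject_cv, equalize = equalize,
         gm_margin_mm = gm_margin_mm, head_threshold = head_threshold),
    class = "study_config"
  )
}

#' Prepare the per-institution calibration and precomputations
#'
#' Runs the phantom experiments a site performs once before the clinical
#' study: the Becquerel calibration (syringe of known activity), the
#' well-counter cross calibration (uniform 16-cm cylinder), and the
#' resolution measurement (gray-matter-filled brain phantom, estimated
#' against the digital design). Also precomputes the subject-independent
#' projection factors and the base look-up tables for the institution's dose.
#'
#' @param profile an [institution_profile()].
#' @param phantom the brain `phantom_spec` of the study.
#' @param schedule the [acquisition_schedule()].
#' @param seed seed for the calibration acquisitions.
#' @param noise Poisson noise toggle.
#' @param constants [kinetic_constants()].
#' @return An `institution_precomp` list.
#' @export
prepare_institution <- function(profile, phantom, schedule, seed = 1L,
                                noise = TRUE, constants = kinetic_constants()) {
  grid <- dim(phantom$labels)[1]
  sp <- phantom$spacing_mm
  geometry <- spect_geometry(nview = 60L, nbin = grid, bin_mm = sp)

  # Becquerel calibration: syringe-like source of known concentration
  syr <- make_cylinder_phantom(30, 80000, "disc", grid = grid, spacing_mm = sp)
  ss <- simulate_static_study(syr, profile, duration_min = 10, seed = seed,
                              noise = noise)
  ssino <- ps_sum(ss$proj)
  smu <- estimate_mu_map(reconstruct_uncorrected(ssino, geometry))
  srec <- reconstruct_quantitative(ssino, smu, geometry, bcf = 1,
                                   scatter = profile$scatter)
  bcf <- calibrate_bcf(srec, 80000, phantom_mask(syr, "source"))

  # cross calibration: uniform cylinder counted in the well counter
  cyl <- make_cylinder_phantom(160, 50000, "disc", grid = grid, spacing_mm = sp)
  cs <- simulate_static_study(cyl, profile, duration_min = 28, seed = seed + 1L,
                              noise = noise)
  csino <- ps_sum(cs$proj)
  cmu <- estimate_mu_map(reconstruct_uncorrected(csino, geometry))
  crec <- reconstruct_quantitative(csino, cmu, geometry, bcf = bcf,
                                   scatter = profile$scatter)
  well <- profile$ccf * 50000
  ccf <- calibrate_ccf(crec, well,
                       erode_mask(phantom_mask(cyl, "source"), sp, 20))

  # resolution: gray-matter-filled brain phantom vs its digital design
  gm_act <- phantom_mask(phantom, "gm", tissue = TRUE) * 30000
  digital <- spect_image(gm_act, sp, "Bq/mL")
  bs <- simulate_static_study(phantom, profile, duration_min = 28,
                              seed = seed + 2L, noise = noise,
                              activity = digital)
  bsino <- ps_sum(bs$proj)
  bmu <- estimate_mu_map(reconstruct_uncorrected(bsino, geometry), 0.10)
  brec <- reconstruct_quantitative(bsino, bmu, geometry, bcf = bcf,
                                   scatter = profile$scatter)
  res <- estimate_fwhm(brec, digital)

  dose_input1 <- standard_input_function(profile$dose_mbq,
                                         t_inject_min = schedule$inject_min[1])
  dose_input2 <- standard_input_function(profile$dose_mbq,
                                         t_inject_min = schedule$inject_min[2])
  second_window <- c(schedule$inject_min[2],
                     max(schedule$frame_start_min + schedule$frame_dur_min))
  structure(
    list(
      profile = profile, geometry = geometry,
      bcf = bcf, ccf = ccf, resolution = res,
      factors = precompute_projection_factors(phantom, profile, geometry),
      base_inputs = list(first = dose_input1, second = dose_input2),
      base_tables = list(
        t028 = build_lookup_table(dose_input1, constants, c(0, 28)),
        t2428 = build_lookup_table(dose_input1, constants, c(24, 28)),
        bg = build_lookup_table(dose_input1, constants, second_window),
        t2 = build_lookup_table(dose_input2, constants, second_window)
      ),
      second_window = second_window
    ),
    class = "institution_precomp"
  )
}

scale_subject_phantom <- function(phantom, factor) {
  ph <- phantom
  perf <- ph$compartments$tissue %in% c("gm", "wm", "soft")
  ph$compartments$cbf_rest[perf] <- ph$compartments$cbf_rest[perf] * factor
  ph$compartments$cbf_acz[perf] <- ph$compartments$cbf_acz[perf] * factor
  ph
}

dtarg_one_subject <- function(imgs, pre, calib_scale, gm_mask, head_mask,
                              constants) {
  t028 <- rescale_lookup_table(pre$base_tables$t028, calib_scale)
  t2428 <- rescale_lookup_table(pre$base_tables$t2428, calib_scale)
  bg_tab <- rescale_lookup_table(pre$base_tables$bg, calib_scale)
  t2 <- rescale_lookup_table(pre$base_tables$t2, calib_scale)
  input1 <- scale_input(pre$base_inputs$first, calib_scale)
  rest <- compute_rest_cbf(imgs$mean_rest, input = input1, constants = constants,
                           gm_mask = gm_mask, head_mask = head_mask,
                           frame_24_28 = imgs$frame_24_28,
                           tables = list(t028 = t028, t2428 = t2428))
  bg <- predict_background(rest, input1, constants,
                           window = pre$second_window, bg_table = bg_tab)
  acz <- compute_acz_cbf(imgs$mean_second, bg,
                         scale_input(pre$base_inputs$second, calib_scale),
                         constants, head_mask = head_mask,
                         scale_s = attr(rest, "scale_s"),
                         window = pre$second_window, table = t2)
  list(rest = rest, acz = acz, cvr = compute_cvr(rest, acz),
       global_cbf = attr(rest, "global_cbf"), scale_s = attr(rest, "scale_s"))
}

#' Simulate and analyse one institution's cohort
#'
#' For each subject: draw the inter-subject global-CBF factor, simulate the
#' dual-injection study, reconstruct (mu-map from the summed rest scan; the
#' 24-28 min frame and the two scan-duration sums through the quantitative
#' chain with the institution's measured BCF), calibrate the input function
#' with the blood sample and measured CCF, run the dual-table estimation, and
#' extract regional CBF. Fully reproducible given the seed.
#'
#' @param profile an [institution_profile()].
#' @param n_subjects number of simulated subjects.
#' @param seed integer seed for this cohort.
#' @param config a [study_config()] (phantom, schedule, toggles).
#' @param precomp optional [prepare_institution()] result to reuse.
#' @return An `institution_study`: list with `cohort` (tibble: institution,
#'   subject, region, condition, cbf), `subjects` (per-subject images and
#'   provenance), `precomp`, `rois`.
#' @export
run_institution_study <- function(profile, n_subjects = profile$n_subjects,
                                  seed = 1L, config = study_config(),
                                  precomp = NULL) {
  phantom <- config$phantom
  schedule <- config$schedule
  constants <- kinetic_constants()
  if (is.null(precomp)) {
    precomp <- prepare_institution(profile, phantom, schedule,
                                   seed = seed + 900000L, noise = config$noise)
  }
  geometry <- precomp$geometry
  gm_mask <- gm_core_mask(phantom, config$gm_margin_mm)
  rois <- make_roi_template(phantom)
  sdlog <- sqrt(log(1 + config$subject_cv^2))
  sf <- schedule_scan_frames(schedule)
  i24 <- which(abs(schedule$frame_start_min - 24) < 1e-6)
  if (!length(i24)) stop("schedule has no frame starting at 24 min", call. = FALSE)

  subjects <- vector("list", n_subjects)
  rows <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sseed <- seed + 1000L * s
    factor_s <- if (config$subject_cv > 0) {
      withr::with_seed(sseed + 1L, stats::rlnorm(1, -sdlog^2 / 2, sdlog))
    } else 1
    ph_s <- scale_subject_phantom(phantom, factor_s)
    sim <- tryCatch(
      simulate_dual_injection_study(ph_s, profile, schedule, seed = sseed,
                                    geometry = geometry, noise = config$noise,
                                    constants = constants,
                                    precomp = precomp$factors),
      error = function(e) stop("subject ", s, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    mu <- estimate_mu_map(
      reconstruct_uncorrected(ps_sum(sim$rest), geometry),
      config$head_threshold
    )
    recq <- function(sino) reconstruct_quantitative(
      sino, mu, geometry, bcf = precomp$bcf, scatter = profile$scatter
    )
    imgs <- list(
      mean_rest = recq(ps_sum(sim$rest)),
      frame_24_28 = recq(ps_sum(sim$rest, which(sf$rest == i24))),
      mean_second = recq(ps_sum(sim$acz))
    )
    input_std <- standard_input_function(profile$dose_mbq,
                                         t_inject_min = schedule$inject_min[1])
    calib <- calibrate_input_function(input_std, sim$blood_sample, precomp$ccf,
                                      t_sample_min = schedule$sample_min)
    fit <- dtarg_one_subject(imgs, precomp, attr(calib, "calibration_scale"),
                             gm_mask, mu$mask, constants)
    rows[[s]] <- subject_roi_rows(profile$name, s, fit, rois)
    subjects[[s]] <- list(images = imgs, mu_mask = mu$mask, fit = fit,
                          calib_scale = attr(calib, "calibration_scale"),
                          truth_factor = factor_s, seed = sseed)
  }
  structure(
    list(cohort = dplyr::bind_rows(rows), subjects = subjects,
         precomp = precomp, rois = rois, profile = profile,
         gm_mask = gm_mask, config = config),
    class = "institution_study"
  )
}

subject_roi_rows <- function(inst, subject, fit, rois) {
  one <- function(img, condition) {
    roi_means(img, rois) |>
      dplyr::filter(.data$side == "both") |>
      dplyr::transmute(institution = inst, subject = subject,
                       region = .data$region, condition = condition,
                       cbf = .data$mean)
  }
  dplyr::bind_rows(one(fit$rest, "rest"), one(fit$acz, "acz"))
}

#' Run the full multicentre comparison
#'
#' Simulates every institution's cohort, measures each scanner's resolution
#' on the digital brain phantom, equalizes all reconstructed images to the
#' worst resolution with the quadrature-complement Gaussian filter, re-runs
#' the CBF estimation on the equalized images, and compares regional CBF
#' across institutions (Steel-Dwass over all institution pairs per region and
#' condition; optionally pairwise t / Mann-Whitney) with and without
#' equalization.
#'
#' @param config a [study_config()].
#' @param precomps optional named list of [prepare_institution()] results
#'   (reused across replicates of a simulation experiment).
#' @param pairwise also run pairwise t and Mann-Whitney tests.
#' @return A `multicenter_report`: list with `cohorts` (raw and equalized),
#'   `summaries`, `tests`, `resolution` (measured and target FWHM), `studies`.
#' @export
run_multicenter_comparison <- function(config, precomps = NULL, pairwise = FALSE) {
  k <- length(config$institutions)
  if (k < 2L) {
    message("single institution in config: comparison skipped")
    return(structure(list(cohorts = NULL, tests = NULL, skipped = TRUE),
                     class = "multicenter_report"))
  }
  constants <- kinetic_constants()
  studies <- vector("list", k)
  names(studies) <- names(config$institutions)
  for (i in seq_len(k)) {
    prof <- config$institutions[[i]]
    pre <- if (!is.null(precomps)) precomps[[names(config$institutions)[i]]] else NULL
    studies[[i]] <- run_institution_study(
      prof, config$n_subjects[i],
      seed = config$seed + 10000000L * (i - 1L), config = config, precomp = pre
    )
  }
  fwhm_est <- vapply(studies, function(s) s$precomp$resolution$fwhm_mm, numeric(1))
  target <- max(fwhm_est)
  resolution <- tibble::tibble(
    institution = names(studies),
    fwhm_measured_mm = unname(fwhm_est),
    fwhm_nominal_mm = vapply(studies, function(s) s$profile$fwhm_mm, numeric(1)),
    additional_fwhm_mm = vapply(fwhm_est, function(f) additional_fwhm(target, f),
                                numeric(1))
  )
  raw_cohort <- dplyr::bind_rows(lapply(studies, `[[`, "cohort"))
  cohorts <- list(raw = raw_cohort)
  if (config$equalize) {
    eq_rows <- list()
    for (i in seq_len(k)) {
      st <- studies[[i]]
      addf <- resolution$additional_fwhm_mm[i]
      for (s in seq_along(st$subjects)) {
        sub <- st$subjects[[s]]
        imgs_eq <- lapply(sub$images, equalize_resolution,
                          additional_fwhm_mm = addf)
        fit_eq <- dtarg_one_subject(imgs_eq, st$precomp, sub$calib_scale,
                                    st$gm_mask, sub$mu_mask, constants)
        eq_rows[[length(eq_rows) + 1L]] <-
          subject_roi_rows(st$profile$name, s, fit_eq, st$rois)
      }
    }
    cohorts$equalized <- dplyr::bind_rows(eq_rows)
  }
  tests <- lapply(cohorts, cohort_tests, pairwise = pairwise)
  summaries <- lapply(cohorts, summary_table)
  structure(
    list(cohorts = cohorts, summaries = summaries, tests = tests,
         resolution = resolution, studies = studies, config = config,
         skipped = FALSE),
    class = "multicenter_report"
  )
}

# Steel-Dwass (and optional pairwise) comparisons per region x condition
cohort_tests <- function(cohort, pairwise = FALSE) {
  combos <- dplyr::distinct(cohort, .data$region, .data$condition)
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sub <- cohort[cohort$region == combos$region[i] &
                    cohort$condition == combos$condition[i], ]
    groups <- split(sub$cbf, sub$institution)
    res <- list()
    if (length(groups) >= 3L) {
      res[[1L]] <- steel_dwass(groups) |>
        dplyr::mutate(region = combos$region[i], condition = combos$condition[i],
                      test = "steel_dwass")
    } else {
      pairwise <- TRUE   # all-pairs test needs >= 3 groups; fall back
    }
    if (pairwise) {
      prs <- utils::combn(names(groups), 2)
      for (q in seq_len(ncol(prs))) {
        for (m in c("unpaired_t", "mann_whitney")) {
          gc <- group_compare(groups[[prs[1, q]]], groups[[prs[2, q]]], m)
          res[[length(res) + 1L]] <- tibble::tibble(
            group1 = prs[1, q], group2 = prs[2, q],
            n1 = length(groups[[prs[1, q]]]), n2 = length(groups[[prs[2, q]]]),
            statistic = gc$statistic, p_adjusted = gc$p_value,
            region = combos$region[i], condition = combos$condition[i],
            test = m)
        }
      }
    }
    out[[i]] <- dplyr::bind_rows(res)
  }
  dplyr::bind_rows(out)
}

#' @export
print.multicenter_report <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat("<multicenter_report> skipped (single institution)\n")
    return(invisible(x))
  }
  cat("<multicenter_report>", length(x$studies), "institutions,",
      sum(vapply(x$studies, function(s) length(s$subjects), integer(1))),
      "subjects\n")
  print(x$resolution)
  for (nm in names(x$tests)) {
    sig <- x$tests[[nm]] |>
      dplyr::filter(.data$test == "steel_dwass", .data$p_adjusted < 0.05)
    cat(sprintf("  %s analysis: %d significant region pair(s) at alpha = 0.05\n",
                nm, nrow(sig)))
  }
  invisible(x)
}
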