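#' Scatter and septal-penetration model parameters
#'
#' Transmission-dependent convolution subtraction (TDCS) describes the local
#' scatter fraction of each projection bin as `SF(x) = 1 - 1/(A - B * t(x)^beta)`
#' where `t(x)` is the photon transmission factor of the bin's chord. The
#' scatter estimate is the observed projection convolved with a unit-area
#' symmetric mono-exponential kernel of the given decay length, weighted by
#' `SF`. High-energy photons of I-123 that penetrate the collimator septa add
#' an essentially uniform background, modelled as a fixed fraction of the mean
#' observed counts.
#'
#' @param A,B,beta TDCS scatter-fraction constants; `A - B * t^beta` must stay
#'   >= 1 on `t` in `[0, 1]` so that `SF` lies in `[0, 1)`.
#' @param kernel_mm decay length of the mono-exponential scatter kernel (mm).
#' @param offset_fraction septal-penetration offset as a fraction of the mean
#'   observed projection count.
#' @return A `scatter_params` object.
#' @export
scatter_params <- function(A = 2.0, B = 1.0, beta = 0.5,
                           kernel_mm = 40, offset_fraction = 0.03) {
  tgrid <- seq(0, 1, by = 0.01)
  denom <- A - B * tgrid^beta
  if (any(denom < 1 - 1e-9)) {
    stop("invalid TDCS constants: scatter fraction leaves [0, 1)", call. = FALSE)
  }
  stopifnot(kernel_mm > 0, offset_fraction >= 0, offset_fraction < 1)
  structure(list(A = A, B = B, beta = beta, kernel_mm = kernel_mm,
                 offset_fraction = offset_fraction),
            class = "scatter_params")
}

scatter_fraction <- function(params, t) {
  1 - 1 / (pmax(params$A - params$B * pmax(t, 0)^params$beta, 1))
}

#' Institution (scanner) profiles
#'
#' Bundles the per-institution acquisition constants of a multicentre study:
#' nominal spatial resolution of the reconstructed images (FWHM, mm), the
#' Becquerel calibration factor BCF (Bq/mL per reconstructed intensity;
#' smaller BCF = more sensitive system), the well-counter cross-calibration
#' factor CCF, the tracer dose, the acetazolamide dose, and the scatter model.
#'
#' `default_institutions()` returns the three study profiles: A (LMEGP
#' parallel-hole, 17.13 mm, the worst resolution), B (LMEHR, 11.22 mm) and
#' C (LESHR, 10.26 mm), with their calibration factors, doses and enrolment.
#'
#' @param name institution label.
#' @param fwhm_mm nominal FWHM of reconstructed images, mm.
#' @param bcf Becquerel calibration factor (> 0).
#' @param ccf well-counter cross-calibration factor (> 0).
#' @param dose_mbq administered I-123 IMP dose per injection, MBq.
#' @param acz_dose_mg_kg acetazolamide dose, mg/kg.
#' @param n_subjects enrolled subjects (used by the study driver).
#' @param scatter a [scatter_params()].
#' @param sensitivity_scale dimensionless constant relating detector
#'   sensitivity to `1/bcf`; fixes the absolute count level of the simulation.
#' @return An `institution_profile`.
#' @export
institution_profile <- function(name, fwhm_mm, bcf, ccf,
                                dose_mbq, acz_dose_mg_kg = 16,
                                n_subjects = 10L,
                                scatter = scatter_params(),
                                sensitivity_scale = 2.0) {
  stopifnot(fwhm_mm > 0, bcf > 0, ccf > 0, dose_mbq > 0, sensitivity_scale > 0)
  structure(
    list(name = name, fwhm_mm = fwhm_mm, bcf = bcf, ccf = ccf,
         dose_mbq = dose_mbq, acz_dose_mg_kg = acz_dose_mg_kg,
         n_subjects = as.integer(n_subjects), scatter = scatter,
         sensitivity_scale = sensitivity_scale),
    class = "institution_profile"
  )
}

#' @export
print.institution_profile <- function(x, ...) {
  cat(sprintf(
    "<institution_profile %s> FWHM %.2f mm, BCF %g, CCF %.3f, dose %.1f MBq\n",
    x$name, x$fwhm_mm, x$bcf, x$ccf, x$dose_mbq))
  invisible(x)
}

#' @rdname institution_profile
#' @export
default_institutions <- function() {
  list(
    A = institution_profile("A", fwhm_mm = 17.13, bcf = 87956, ccf = 0.799,
                            dose_mbq = 122.1, acz_dose_mg_kg = 17.8,
                            n_subjects = 9L),
    B = institution_profile("B", fwhm_mm = 11.22, bcf = 72281, ccf = 0.619,
                            dose_mbq = 142.2, acz_dose_mg_kg = 15.0,
                            n_subjects = 13L),
    C = institution_profile("C", fwhm_mm = 10.26, bcf = 112419, ccf = 0.948,
                            dose_mbq = 155.9, acz_dose_mg_kg = 16.8,
                            n_subjects = 10L)
  )
}

# Collimator/system blur applied to the activity before projection. The
# nominal profile FWHM characterises the final reconstructed image, which
# already contains the 7-mm post-reconstruction filter, so the simulator
# applies the quadrature complement.
collimator_fwhm <- function(profile, post_fwhm_mm = 7) {
  sqrt(max(profile$fwhm_mm^2 - post_fwhm_mm^2, 0))
}

# detector sensitivity: mean counts per (Bq/mL * mm line integral * min)
profile_sensitivity <- function(profile) profile$sensitivity_scale / profile$bcf

#' Dual-injection acquisition schedule
#'
#' The scanning timeline of the dual-administration protocol: two tracer
#' injections (default 0 and 30 min), acetazolamide given between them
#' (default 20 min), a single arterial blood sample (default 10 min), and two
#' dynamic scans of 7 contiguous 4-min frames each (0-28 and 30-58 min).
#'
#' @param inject_min injection times of the first/second tracer dose (min).
#' @param acz_min acetazolamide administration time (min).
#' @param sample_min arterial blood-sample time (min).
#' @param frame_start_min,frame_dur_min frame start times and durations (min);
#'   frames must be non-overlapping and contiguous within each scan.
#' @return An `acquisition_schedule`.
#' @export
acquisition_schedule <- function(inject_min = c(0, 30), acz_min = 20,
                                 sample_min = 10,
                                 frame_start_min = c(seq(0, 24, 4), seq(30, 54, 4)),
                                 frame_dur_min = rep(4, 14)) {
  stopifnot(length(inject_min) == 2L, length(frame_start_min) == length(frame_dur_min),
            all(frame_dur_min > 0))
  ends <- frame_start_min + frame_dur_min
  if (any(frame_start_min[-1] < ends[-length(ends)] - 1e-9)) {
    stop("frames overlap", call. = FALSE)
  }
  structure(
    list(inject_min = inject_min, acz_min = acz_min, sample_min = sample_min,
         frame_start_min = frame_start_min, frame_dur_min = frame_dur_min),
    class = "acquisition_schedule"
  )
}

schedule_scan_frames <- function(schedule) {
  # indices of frames belonging to the first (rest) and second scans
  second <- schedule$frame_start_min >= schedule$inject_min[2]
  list(rest = which(!second), second = which(second))
}
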