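#' Dynamic projection sets
#'
#' A `projection_set` holds the sinogram frames of one dynamic scan:
#' an array `nbin x nview x nslice x nframe` of (usually Poisson) counts,
#' the acquisition geometry and per-frame start times and durations.
#'
#' @param counts 4-D count array.
#' @param geometry a [spect_geometry()].
#' @param frame_start_min,frame_dur_min frame timing (min).
#' @param unit count unit label.
#' @export
projection_set <- function(counts, geometry, frame_start_min, frame_dur_min,
                           unit = "counts") {
  stopifnot(length(dim(counts)) == 4L,
            dim(counts)[4] == length(frame_start_min),
            length(frame_start_min) == length(frame_dur_min))
  structure(list(counts = counts, geometry = geometry,
                 frame_start_min = frame_start_min,
                 frame_dur_min = frame_dur_min, unit = unit),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<projection_set> %d bins x %d views x %d slices x %d frames (%s)\n",
              d[1], d[2], d[3], d[4], x$unit))
  cat(sprintf("  frames: %s min\n",
              paste(sprintf("%g-%g", x$frame_start_min,
                            x$frame_start_min + x$frame_dur_min), collapse = ", ")))
  invisible(x)
}

#' Sum frames of a projection set
#'
#' @param ps a `projection_set`.
#' @param frames frame indices (default all).
#' @return sinogram array `nbin x nview x nslice` with attribute
#'   `"duration_min"` (total summed duration).
#' @export
ps_sum <- function(ps, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(dim(ps$counts)[4])
  out <- apply(ps$counts[, , , frames, drop = FALSE], 1:3, sum)
  attr(out, "duration_min") <- sum(ps$frame_dur_min[frames])
  attr(out, "geometry") <- ps$geometry
  out
}

# mono-exponential unit-area scatter kernel as a bin x bin convolution matrix;
# normalisation fixed by the full kernel mass so edge bins lose out-of-field
# scatter
scatter_kernel_matrix <- function(nbin, bin_mm, kernel_mm) {
  d <- abs(outer(seq_len(nbin), seq_len(nbin), `-`)) * bin_mm
  k <- exp(-d / kernel_mm)
  k / (2 * sum(exp(-(seq_len(nbin) - 1) * bin_mm / kernel_mm)) - 1)
}

# scatter consistent with the TDCS model: s solves s = SF o K(clean + s),
# i.e. scatter is a transmission-weighted blur of the total (primary +
# scattered) field; solved by fixed-point iteration (contraction since
# SF < 1 and K has unit mass)
add_scatter_offset <- function(clean, sf, kmat, offset_fraction) {
  s <- matrix(0, nrow(clean), ncol(clean))
  for (i in 1:30) {
    s_new <- sf * (kmat %*% (clean + s))
    if (max(abs(s_new - s)) <= 1e-10 * (max(clean) + 1e-12)) { s <- s_new; break }
    s <- s_new
  }
  base <- clean + as.matrix(s)
  off <- if (offset_fraction > 0) offset_fraction * mean(base) / (1 - offset_fraction) else 0
  base + off
}

# per-slice true transmission factors of the phantom (full chord)
true_transmission <- function(phantom, geometry) {
  mu <- as_image_data(phantom_mu(phantom))
  tt <- array(0, dim = c(geometry$nbin, geometry$nview, dim(mu)[3]))
  for (k in seq_len(dim(mu)[3])) {
    tt[, , k] <- exp(-0.1 * fp_slice(mu[, , k], geometry))
  }
  tt
}

#' Precompute the subject-independent projection factors of a scanner
#'
#' The attenuated forward projections of every (collimator-blurred)
#' compartment indicator and the true transmission sinogram depend only on
#' the phantom's label geometry and the scanner, not on the flows, so one
#' precomputation serves every simulated subject of an institution.
#'
#' @inheritParams simulate_dual_injection_study
#' @return list with `cp` (per-compartment projections) and `tt`
#'   (transmission factors), for the `precomp` argument of the simulators.
#' @export
precompute_projection_factors <- function(phantom, profile, geometry = NULL) {
  if (is.null(geometry)) {
    geometry <- spect_geometry(nview = 60L, nbin = dim(phantom$labels)[1],
                               bin_mm = phantom$spacing_mm)
  }
  cp <- compartment_projections(phantom, geometry, collimator_fwhm(profile))
  attr(cp, "bin_mm") <- geometry$bin_mm
  list(cp = cp, tt = true_transmission(phantom, geometry), geometry = geometry)
}

# spatial projection factors: for every compartment, the attenuated forward
# projection of its (collimator-blurred) indicator; a frame sinogram is then
# a linear combination with the per-frame compartment activities
compartment_projections <- function(phantom, geometry, fwhm_mm) {
  mu <- as_image_data(phantom_mu(phantom))
  labs <- sort(unique(as.integer(phantom$labels)))
  labs <- setdiff(labs, phantom$compartments$label[phantom$compartments$tissue == "air"])
  out <- list()
  for (l in labs) {
    m <- array(as.numeric(phantom$labels == l), dim = dim(phantom$labels))
    if (fwhm_mm > 0) {
      m <- map_slices(m, gaussian_blur_matrix, fwhm_mm = fwhm_mm,
                      spacing_mm = phantom$spacing_mm)
    }
    s <- array(0, dim = c(geometry$nbin, geometry$nview, dim(m)[3]))
    for (k in seq_len(dim(m)[3])) {
      s[, , k] <- fp_slice(m[, , k], geometry, mu = mu[, , k])
    }
    out[[as.character(l)]] <- s
  }
  out
}

assemble_noisy_frames <- function(comp_proj, act, sens, frame_dur, tt, scatter_p,
                                  use_scatter, use_offset, noise) {
  # act: nframe x ncomp matrix of mean activities (Bq/mL), columns named by label
  nframe <- nrow(act)
  dims <- dim(comp_proj[[1]])
  counts <- array(0, dim = c(dims[1], dims[2], dims[3], nframe))
  kmat <- scatter_kernel_matrix(dims[1], attr(comp_proj, "bin_mm"),
                                scatter_p$kernel_mm)
  off_frac <- if (use_offset) scatter_p$offset_fraction else 0
  for (fr in seq_len(nframe)) {
    for (k in seq_len(dims[3])) {
      clean <- matrix(0, dims[1], dims[2])
      for (l in names(comp_proj)) {
        a <- act[fr, l]
        if (a != 0) clean <- clean + a * comp_proj[[l]][, , k]
      }
      clean <- clean * sens * frame_dur[fr]
      obs <- if (use_scatter || off_frac > 0) {
        sf <- if (use_scatter) scatter_fraction(scatter_p, tt[, , k]) else 0
        add_scatter_offset(clean, sf, kmat, off_frac)
      } else clean
      obs <- pmax(obs, 0)   # mean counts; FFT-blur ringing can dip below zero
      if (noise) obs <- matrix(stats::rpois(length(obs), obs), dims[1])
      counts[, , k, fr] <- obs
    }
  }
  counts
}

#' Simulate a dual-injection dynamic SPECT study
#'
#' Generates the two dynamic scans of the dual-administration protocol for one
#' subject on one scanner. Per-voxel tissue curves follow the one-tissue
#' compartment model: the first injection's kinetics run with the rest-phase
#' flows for the whole study, the second injection's response uses the
#' post-acetazolamide flows. Frame-mean activity maps are blurred by the
#' scanner's collimator resolution, forward-projected with the phantom's true
#' (heterogeneous) attenuation, scattered and offset per the TDCS model, and
#' Poisson noise is drawn with mean counts set by the profile's sensitivity.
#' The arterial blood sample is the true input value at the sample time
#' expressed in well-counter units via the CCF.
#'
#' @param phantom a brain `phantom_spec`.
#' @param profile an [institution_profile()].
#' @param schedule an [acquisition_schedule()].
#' @param seed integer seed for the Poisson draw (required when `noise`).
#' @param geometry optional [spect_geometry()]; defaults to 60 views over
#'   360 degrees matching the phantom grid.
#' @param noise,scatter,offset toggles for Poisson noise, scatter and the
#'   septal-penetration offset.
#' @param constants [kinetic_constants()].
#' @param precomp optional [precompute_projection_factors()] result; the
#'   spatial projection factors depend only on the phantom geometry and the
#'   scanner, so they can be shared across subjects that differ only in flows.
#' @return list with elements `rest` and `acz` ([projection_set()]s),
#'   `blood_sample` (well-counter value), `inputs` (true input functions),
#'   `geometry`, and `truth` (per-frame compartment activities and the
#'   collimator-blurred frame-activity accessor used by tests).
#' @export
simulate_dual_injection_study <- function(phantom, profile, schedule,
                                          seed = 1L, geometry = NULL,
                                          noise = TRUE, scatter = TRUE,
                                          offset = TRUE,
                                          constants = kinetic_constants(),
                                          precomp = NULL) {
  if (is.null(geometry)) {
    geometry <- spect_geometry(nview = 60L, nbin = dim(phantom$labels)[1],
                               bin_mm = phantom$spacing_mm)
  }
  check_study_geometry(phantom, geometry)
  sf <- schedule_scan_frames(schedule)
  if (!length(sf$rest) || !length(sf$second)) {
    stop("schedule must contain frames for both scans", call. = FALSE)
  }
  comp <- phantom$compartments
  input1 <- standard_input_function(profile$dose_mbq,
                                    t_inject_min = schedule$inject_min[1])
  input2 <- standard_input_function(profile$dose_mbq,
                                    t_inject_min = schedule$inject_min[2])
  f_rest <- cbf_to_flow(comp$cbf_rest, constants)
  f_acz <- cbf_to_flow(comp$cbf_acz, constants)
  # nframe x ncomp activities: first injection at rest flow over the full
  # study, second injection at acetazolamide flow
  a1 <- tac_frame_means(f_rest, constants$vd, input1,
                        schedule$frame_start_min, schedule$frame_dur_min)
  a2 <- tac_frame_means(f_acz, constants$vd, input2,
                        schedule$frame_start_min, schedule$frame_dur_min)
  act <- a1 + a2
  colnames(act) <- as.character(comp$label)

  if (is.null(precomp)) {
    precomp <- precompute_projection_factors(phantom, profile, geometry)
  }
  cp <- precomp$cp
  tt <- precomp$tt
  sens <- profile_sensitivity(profile)

  counts <- withr::with_seed(seed, assemble_noisy_frames(
    cp, act, sens, schedule$frame_dur_min, tt, profile$scatter,
    use_scatter = scatter, use_offset = offset, noise = noise
  ))

  mk_ps <- function(idx) projection_set(
    counts[, , , idx, drop = FALSE], geometry,
    schedule$frame_start_min[idx], schedule$frame_dur_min[idx]
  )
  list(
    rest = mk_ps(sf$rest),
    acz = mk_ps(sf$second),
    blood_sample = simulate_blood_sample(input1, schedule$sample_min, profile$ccf),
    inputs = list(first = input1, second = input2),
    geometry = geometry,
    truth = list(frame_activity = act, compartments = comp,
                 sensitivity = sens, schedule = schedule)
  )
}

#' Simulate a static (fixed-activity) phantom scan
#'
#' Single-frame acquisition of a phantom whose compartments carry fixed
#' activity concentrations (uniform cylinder, syringe, line source, or the
#' gray-matter-filled brain phantom used for resolution measurements).
#'
#' @inheritParams simulate_dual_injection_study
#' @param duration_min acquisition duration (min).
#' @param activity optional `spect_image` overriding the phantom's static
#'   activity (Bq/mL).
#' @return list with `proj` (a one-frame [projection_set()]), `activity`
#'   (the true activity image) and `geometry`.
#' @export
simulate_static_study <- function(phantom, profile, duration_min = 28,
                                  seed = 1L, geometry = NULL,
                                  noise = TRUE, scatter = TRUE, offset = TRUE,
                                  activity = NULL) {
  if (is.null(geometry)) {
    geometry <- spect_geometry(nview = 60L, nbin = dim(phantom$labels)[1],
                               bin_mm = phantom$spacing_mm)
  }
  check_study_geometry(phantom, geometry)
  if (is.null(activity)) activity <- phantom_activity(phantom)
  mu <- as_image_data(phantom_mu(phantom))
  a <- as_image_data(activity)
  fw <- collimator_fwhm(profile)
  if (fw > 0) {
    a <- map_slices(a, gaussian_blur_matrix, fwhm_mm = fw,
                    spacing_mm = phantom$spacing_mm)
  }
  tt <- true_transmission(phantom, geometry)
  sens <- profile_sensitivity(profile)
  kmat <- scatter_kernel_matrix(geometry$nbin, geometry$bin_mm,
                                profile$scatter$kernel_mm)
  counts <- array(0, dim = c(geometry$nbin, geometry$nview, dim(a)[3], 1L))
  off_frac <- if (offset) profile$scatter$offset_fraction else 0
  obs_all <- withr::with_seed(seed, {
    for (k in seq_len(dim(a)[3])) {
      clean <- fp_slice(a[, , k], geometry, mu = mu[, , k]) * sens * duration_min
      obs <- if (scatter || off_frac > 0) {
        sfk <- if (scatter) scatter_fraction(profile$scatter, tt[, , k]) else 0
        add_scatter_offset(clean, sfk, kmat, off_frac)
      } else clean
      obs <- pmax(obs, 0)
      if (noise) obs <- matrix(stats::rpois(length(obs), obs), geometry$nbin)
      counts[, , k, 1] <- obs
    }
    counts
  })
  list(proj = projection_set(obs_all, geometry, 0, duration_min),
       activity = activity, geometry = geometry)
}

#' Arterial blood sample in well-counter units
#'
#' The whole-blood concentration at the sample time, converted to well-counter
#' units by the cross-calibration factor.
#'
#' @param input an `input_function`.
#' @param t_min sample time (min).
#' @param ccf cross-calibration factor.
#' @return well-counter value.
#' @export
simulate_blood_sample <- function(input, t_min = 10, ccf = 1) {
  stopifnot(ccf >= 0)
  input_value(input, t_min) * ccf
}

check_study_geometry <- function(phantom, geometry) {
  if (dim(phantom$labels)[1] != geometry$nbin ||
      abs(phantom$spacing_mm - geometry$bin_mm) > 1e-9) {
    stop("phantom grid and acquisition geometry are inconsistent", call. = FALSE)
  }
  invisible(TRUE)
}
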