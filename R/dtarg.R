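#' Calibrate the population input function with the blood sample
#'
#' Scales the standardized input curve so that it matches the measured
#' whole-blood concentration at the sample time:
#' `scale = (well_sample / CCF) / standard(t_sample)`.
#'
#' @param standard the population `input_function`.
#' @param well_sample well-counter reading of the arterial sample.
#' @param ccf cross-calibration factor of the well counter.
#' @param t_sample_min sample time (min).
#' @return calibrated `input_function` (SPECT-consistent Bq/mL), with
#'   attribute `calibration_scale`.
#' @export
calibrate_input_function <- function(standard, well_sample, ccf, t_sample_min = 10) {
  stopifnot(ccf > 0, well_sample >= 0)
  ref <- input_value(standard, t_sample_min)
  if (ref <= 0) stop("standard input is zero at the sample time", call. = FALSE)
  s <- (well_sample / ccf) / ref
  out <- scale_input(standard, s)
  attr(out, "calibration_scale") <- s
  out
}

#' Build an autoradiographic look-up table
#'
#' For each flow on a fine grid (default 0 to 1.2 mL/min/mL in steps of
#' 0.001) the expected window-mean tissue activity under the one-tissue
#' compartment model is tabulated. Window means (not sums) make the table
#' frame-duration invariant. The table must be strictly increasing in flow.
#'
#' @param input calibrated `input_function` (absolute time axis).
#' @param constants [kinetic_constants()].
#' @param window `c(t1, t2)` averaging window (min, absolute time).
#' @param flow_grid flow grid, mL/min/mL.
#' @return a `lookup_table`: tibble with columns `flow` (mL/min/mL) and
#'   `activity` (Bq/mL), attributes `window`, `constants`, `scale_s`.
#' @export
build_lookup_table <- function(input, constants = kinetic_constants(),
                               window = c(0, 28),
                               flow_grid = seq(0, 1.2, by = 0.001)) {
  stopifnot(length(window) == 2L, window[2] > window[1], all(flow_grid >= 0))
  act <- tissue_window_mean(flow_grid, constants$vd, input, window)
  if (any(diff(act) <= 0)) {
    stop("look-up table is not strictly increasing in flow", call. = FALSE)
  }
  new_lookup_table(flow_grid, act, window, constants, scale_s = 1)
}

new_lookup_table <- function(flow, activity, window, constants, scale_s) {
  out <- tibble::tibble(flow = flow, activity = activity)
  class(out) <- c("lookup_table", class(out))
  attr(out, "window") <- window
  attr(out, "constants") <- constants
  attr(out, "scale_s") <- scale_s
  out
}

#' Rescale the activity axis of a look-up table
#'
#' Multiplying the activity axis by `s` is equivalent to scaling the input
#' function by `s` (the model is linear in the input); used both for the
#' global-CBF consistency scaling and to reuse one base table across doses.
#'
#' @param table a `lookup_table`.
#' @param s positive scale factor.
#' @export
rescale_lookup_table <- function(table, s) {
  stopifnot(s > 0)
  new_lookup_table(table$flow, table$activity * s, attr(table, "window"),
                   attr(table, "constants"), attr(table, "scale_s") * s)
}

lookup_forward <- function(table, f) {
  stats::approx(table$flow, table$activity, xout = pmin(pmax(f, 0), max(table$flow)),
                rule = 2)$y
}

#' Invert a look-up table: activity to CBF
#'
#' Linear interpolation on the inverse (strictly monotone) map. Activities
#' above the table maximum are clamped to the maximal flow and counted in the
#' `n_clamped` attribute; negative activities are an error. The result is
#' converted to CBF in mL/min/100 g via the kinetic constants.
#'
#' @param table a `lookup_table`.
#' @param activity non-negative activity values (Bq/mL).
#' @return CBF values (mL/min/100 g) with attribute `n_clamped`.
#' @export
invert_lookup <- function(table, activity) {
  if (any(activity < 0)) stop("negative activity", call. = FALSE)
  n_clamped <- sum(activity > max(table$activity))
  if (n_clamped > 0) {
    warning(sprintf("%d activity value(s) above table maximum clamped to f_max",
                    n_clamped), call. = FALSE)
  }
  f <- stats::approx(table$activity, table$flow, xout = activity, rule = 2)$y
  out <- flow_to_cbf(f, attr(table, "constants"))
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Global gray-matter CBF from the late frame
#'
#' Inverts the gray-matter mean activity of the frame covering 24-28 min
#' (whose timing minimises inter-individual input-shape variation) with a
#' look-up table built for that window.
#'
#' @param frame_24_28 calibrated `spect_image` (Bq/mL) of the late rest frame.
#' @param gm_mask logical array (gray-matter region used for the global value).
#' @param table_24_28 `lookup_table` for the 24-28 min window.
#' @return scalar CBF (mL/min/100 g).
#' @export
estimate_global_cbf <- function(frame_24_28, gm_mask, table_24_28) {
  m <- mask_mean(frame_24_28, gm_mask)
  as.numeric(invert_lookup(table_24_28, max(m, 0)))
}

#' Scale a look-up table for global consistency
#'
#' Finds the scalar `s` (bisection on [0.2, 5], tolerance 1e-4) multiplying
#' the activity axis such that the gray-matter mean of the pixelwise inverted
#' CBF of `image_0_28` equals `target_global`. Scaling the axis up lowers
#' every inverted flow, so the gray-matter mean is strictly decreasing in `s`
#' (and the consistent `s` decreases as the target grows); the bisection
#' relies on that monotonicity.
#'
#' @param table_0_28 `lookup_table` for the full first scan window.
#' @param image_0_28 mean rest image over 0-28 min (Bq/mL).
#' @param gm_mask logical array.
#' @param target_global target global CBF (mL/min/100 g), > 0.
#' @param tol bisection tolerance on `s`.
#' @return rescaled `lookup_table` (attribute `scale_s` carries the factor).
#' @export
scale_lookup_table <- function(table_0_28, image_0_28, gm_mask, target_global,
                               tol = 1e-4) {
  stopifnot(target_global > 0)
  vox <- pmax(as_image_data(image_0_28)[as_image_data(gm_mask) > 0], 0)
  gmean <- function(s) {
    mean(suppressWarnings(invert_lookup(rescale_lookup_table(table_0_28, s), vox)))
  }
  lo <- 0.2; hi <- 5
  flo <- gmean(lo) - target_global   # decreasing in s: flo should be > 0
  fhi <- gmean(hi) - target_global
  if (flo < 0 || fhi > 0) {
    stop(sprintf(
      "no consistency scale in [0.2, 5]: GM CBF %.2f at s=0.2, %.2f at s=5, target %.2f",
      flo + target_global, fhi + target_global, target_global), call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (gmean(mid) - target_global > 0) lo <- mid else hi <- mid
  }
  rescale_lookup_table(table_0_28, (lo + hi) / 2)
}

dtarg_finish_image <- function(cbf_vox, template, head_mask, post_fwhm_mm) {
  img <- spect_image(array(cbf_vox, dim = dim(as_image_data(template))),
                     if (inherits(template, "spect_image")) template$spacing_mm else
                       stop("template must be a spect_image"),
                     unit = "mL/min/100g")
  if (post_fwhm_mm > 0) img <- gaussian_smooth(img, post_fwhm_mm)
  if (!is.null(head_mask)) img$data[!(as_image_data(head_mask) > 0)] <- 0
  img$data <- pmax(img$data, 0)
  img
}

#' Rest CBF by dual-table autoradiography (first scan)
#'
#' Orchestrates the first-scan estimation: global CBF from the 24-28 min
#' frame, consistency scaling of the 0-28 min table, pixelwise table look-up
#' on the 0-28 min mean image, a 7-mm Gaussian smoothing filter, and masking
#' of extra-cranial voxels.
#'
#' @param frames list of calibrated frame images (`spect_image`, Bq/mL) of
#'   the rest scan, or a single pre-averaged 0-28 min image.
#' @param frame_start_min,frame_dur_min frame timing matching `frames`.
#' @param input calibrated `input_function` (first injection).
#' @param constants [kinetic_constants()].
#' @param gm_mask gray-matter region for the global estimate and scaling.
#' @param head_mask voxels outside are set to zero (extra-cranial exclusion);
#'   `NULL` keeps all voxels.
#' @param frame_24_28 the late-frame image; required if `frames` is already
#'   averaged, otherwise located by its start time.
#' @param post_fwhm_mm smoothing filter FWHM (mm), default 7.
#' @param tables optional precomputed base `lookup_table`s
#'   (`list(t028=, t2428=)`) for this input; built on the fly when `NULL`.
#' @return CBF `spect_image` (mL/min/100 g) with attributes `global_cbf`,
#'   `scale_s`, `n_clamped`.
#' @export
compute_rest_cbf <- function(frames, frame_start_min = NULL, frame_dur_min = NULL,
                             input, constants = kinetic_constants(),
                             gm_mask, head_mask = NULL, frame_24_28 = NULL,
                             post_fwhm_mm = 7, tables = NULL) {
  if (inherits(frames, "spect_image")) {
    mean028 <- frames
    if (is.null(frame_24_28)) stop("frame_24_28 required with a pre-averaged image",
                                   call. = FALSE)
  } else {
    stopifnot(length(frames) == length(frame_start_min))
    w <- frame_dur_min / sum(frame_dur_min)
    acc <- as_image_data(frames[[1]]) * w[1]
    for (i in seq_along(frames)[-1]) acc <- acc + as_image_data(frames[[i]]) * w[i]
    mean028 <- spect_image(acc, frames[[1]]$spacing_mm, "Bq/mL")
    if (is.null(frame_24_28)) {
      i24 <- which(abs(frame_start_min - 24) < 1e-6)
      if (!length(i24)) stop("no frame starting at 24 min", call. = FALSE)
      frame_24_28 <- frames[[i24]]
    }
  }
  t2428 <- if (!is.null(tables$t2428)) tables$t2428 else
    build_lookup_table(input, constants, c(24, 28))
  t028 <- if (!is.null(tables$t028)) tables$t028 else
    build_lookup_table(input, constants, c(0, 28))
  g <- estimate_global_cbf(frame_24_28, gm_mask, t2428)
  # a void study (no counts) has zero global CBF: skip the consistency
  # scaling and let the pixelwise look-up return zeros
  scaled <- if (g > 0) scale_lookup_table(t028, mean028, gm_mask, g) else t028
  cbf_vox <- suppressWarnings(invert_lookup(scaled, pmax(as_image_data(mean028), 0)))
  img <- dtarg_finish_image(cbf_vox, mean028, head_mask, post_fwhm_mm)
  attr(img, "global_cbf") <- g
  attr(img, "scale_s") <- attr(scaled, "scale_s")
  attr(img, "n_clamped") <- attr(cbf_vox, "n_clamped")
  img
}

#' Predict the residual background at the second injection
#'
#' Continues the one-tissue model per voxel with the rest-phase flow and the
#' first-injection input, returning the window mean over the second scan —
#' the tissue activity still present from the first injection that must be
#' subtracted before the second look-up.
#'
#' @param rest_cbf rest CBF image (mL/min/100 g).
#' @param input_first calibrated first-injection `input_function`.
#' @param constants [kinetic_constants()].
#' @param window second-scan window (min), default `c(30, 58)`.
#' @param bg_table optional precomputed `lookup_table` for
#'   (first input, second window).
#' @return background `spect_image` (Bq/mL).
#' @export
predict_background <- function(rest_cbf, input_first,
                               constants = kinetic_constants(),
                               window = c(30, 58), bg_table = NULL) {
  if (is.null(bg_table)) {
    bg_table <- build_lookup_table(input_first, constants, window)
  }
  f <- cbf_to_flow(as_image_data(rest_cbf), constants)
  bg <- lookup_forward(bg_table, as.numeric(f))
  spect_image(array(bg, dim = dim(as_image_data(rest_cbf))),
              rest_cbf$spacing_mm, "Bq/mL")
}

#' Acetazolamide CBF from the second scan
#'
#' Subtracts the predicted first-injection background from the second-scan
#' window mean (clipped at zero) and inverts the residual with a table built
#' for the second injection's input and window, scaled by the same
#' consistency factor as the rest table; smoothing and masking as for rest.
#'
#' @param second_mean second-scan window-mean image (Bq/mL).
#' @param background predicted background image from [predict_background()].
#' @param input_second calibrated second-injection `input_function`.
#' @param constants [kinetic_constants()].
#' @param head_mask extra-cranial exclusion mask (`NULL` keeps all voxels).
#' @param scale_s consistency scale carried over from the rest estimation.
#' @param window second-scan window (min).
#' @param post_fwhm_mm smoothing filter FWHM (mm).
#' @param table optional precomputed base `lookup_table` for
#'   (second input, second window).
#' @return CBF `spect_image` (mL/min/100 g) with attribute `n_clamped`.
#' @export
compute_acz_cbf <- function(second_mean, background, input_second,
                            constants = kinetic_constants(),
                            head_mask = NULL, scale_s = 1,
                            window = c(30, 58), post_fwhm_mm = 7,
                            table = NULL) {
  a <- as_image_data(second_mean)
  b <- as_image_data(background)
  stopifnot(all(dim(a) == dim(b)))
  if (is.null(table)) table <- build_lookup_table(input_second, constants, window)
  tab <- rescale_lookup_table(table, scale_s)
  net <- pmax(a - b, 0)
  cbf_vox <- suppressWarnings(invert_lookup(tab, as.numeric(net)))
  img <- dtarg_finish_image(cbf_vox, second_mean, head_mask, post_fwhm_mm)
  attr(img, "n_clamped") <- attr(cbf_vox, "n_clamped")
  img
}

#' Cerebrovascular reactivity
#'
#' Percent CBF increase after acetazolamide: `100 * (acz - rest) / rest`.
#' Voxels with zero rest CBF are undefined and set to 0; their count is
#' returned in the `n_undefined` attribute.
#'
#' @param rest,acz CBF images on the same grid (mL/min/100 g).
#' @return CVR `spect_image` (percent) with attribute `n_undefined`.
#' @export
compute_cvr <- function(rest, acz) {
  r <- as_image_data(rest)
  a <- as_image_data(acz)
  stopifnot(all(dim(r) == dim(a)))
  out <- array(0, dim = dim(r))
  ok <- r > 0
  out[ok] <- 100 * (a[ok] - r[ok]) / r[ok]
  img <- spect_image(out, rest$spacing_mm, unit = "percent")
  attr(img, "n_undefined") <- sum(!ok & (a != 0))
  img
}
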