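#' Becquerel calibration factor from a known-activity source
#'
#' `BCF = true concentration / effective mean reconstructed intensity` over
#' the source region. The effective mean is the image total divided by the
#' source volume, so that activity spilled out of the region by the
#' point-spread function (counts are conserved by reconstruction) is still
#' credited to the source; for an image that already equals the activity
#' inside the mask this reduces to the plain ROI mean and BCF = 1.
#'
#' @param image reconstructed source image (`spect_image`).
#' @param true_activity_bqml known activity concentration of the source.
#' @param source_mask logical array marking the true source support.
#' @return BCF (scalar, same units as `true_activity_bqml` per reconstructed
#'   intensity).
#' @export
calibrate_bcf <- function(image, true_activity_bqml, source_mask) {
  a <- as_image_data(image)
  m <- as_image_data(source_mask) > 0
  stopifnot(all(dim(a) == dim(m)), true_activity_bqml > 0)
  eff_mean <- sum(a) / sum(m)
  if (!is.finite(eff_mean) || eff_mean <= 0) {
    stop("zero mean reconstructed intensity in source region", call. = FALSE)
  }
  true_activity_bqml / eff_mean
}

#' Cross-calibration factor between well counter and SPECT
#'
#' `CCF = well-counter value / mean SPECT concentration` over a uniform
#' region of the calibrated cylinder image; since the SPECT image is already
#' in Bq/mL, CCF is the absolute sensitivity of the well counter relative to
#' SPECT.
#'
#' @param image_bqml calibrated cylinder image (`spect_image`, Bq/mL).
#' @param well_value well-counter reading of the same solution.
#' @param uniform_mask logical array marking a uniform interior region.
#' @return CCF (dimensionless).
#' @export
calibrate_ccf <- function(image_bqml, well_value, uniform_mask) {
  m <- mask_mean(image_bqml, uniform_mask)
  if (!is.finite(m) || m <= 0) stop("zero mean SPECT value in uniform region",
                                    call. = FALSE)
  well_value / m
}

#' Eroded interior of a mask
#'
#' Euclidean erosion by `margin_mm`; used for uniform-region ROIs well away
#' from the partial-volume-affected edge.
#'
#' @param mask logical array.
#' @param spacing_mm voxel size (mm).
#' @param margin_mm erosion depth (mm).
#' @return logical array.
#' @export
erode_mask <- function(mask, spacing_mm, margin_mm) {
  m <- as_image_data(mask) > 0
  out <- array(FALSE, dim = dim(m))
  for (k in seq_len(dim(m)[3])) {
    d <- EBImage::distmap(m[, , k]) * spacing_mm
    out[, , k] <- d > margin_mm
  }
  out
}
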