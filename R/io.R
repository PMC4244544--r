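#' Read and write package objects in standard formats
#'
#' Images travel as NIfTI volumes (voxel spacing in the header, unit in a
#' JSON sidecar when written by this package), dynamic projection sets as
#' NIfTI arrays with a JSON sidecar holding the geometry (view angles in
#' degrees) and frame timing, institution profiles and schedules as YAML,
#' and cohort/summary tables as CSV.
#'
#' @param image a `spect_image`.
#' @param path output file path (`.nii` / `.nii.gz` for images).
#' @return the input, invisibly (writers); the reconstructed object (readers).
#' @name io
NULL

#' @rdname io
#' @export
write_spect_image <- function(image, path) {
  stopifnot(inherits(image, "spect_image"))
  v <- RNifti::asNifti(image$data)
  RNifti::pixdim(v) <- image$spacing_mm
  RNifti::writeNifti(v, path)
  jsonlite::write_json(list(unit = image$unit),
                       paste0(sub("\\.nii(\\.gz)?$", "", path), ".json"),
                       auto_unbox = TRUE)
  invisible(image)
}

#' @rdname io
#' @export
read_spect_image <- function(path) {
  v <- RNifti::readNifti(path)
  side <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  unit <- if (file.exists(side)) jsonlite::read_json(side)$unit else "arbitrary"
  spect_image(array(as.numeric(v), dim = dim(v)),
              RNifti::pixdim(v)[1], unit = unit)
}

#' @rdname io
#' @param ps a `projection_set`.
#' @export
write_projection_set <- function(ps, path) {
  stopifnot(inherits(ps, "projection_set"))
  RNifti::writeNifti(RNifti::asNifti(ps$counts), path)
  side <- list(
    angles_deg = ps$geometry$angles_deg,
    nbin = ps$geometry$nbin, bin_mm = ps$geometry$bin_mm,
    span_deg = ps$geometry$span_deg,
    frame_start_min = ps$frame_start_min,
    frame_dur_min = ps$frame_dur_min, unit = ps$unit
  )
  jsonlite::write_json(side, paste0(sub("\\.nii(\\.gz)?$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(ps)
}

#' @rdname io
#' @export
read_projection_set <- function(path) {
  v <- RNifti::readNifti(path)
  side <- jsonlite::read_json(paste0(sub("\\.nii(\\.gz)?$", "", path), ".json"),
                              simplifyVector = TRUE)
  geom <- spect_geometry(length(side$angles_deg), side$nbin, side$bin_mm,
                         side$span_deg)
  projection_set(array(as.numeric(v), dim = dim(v)), geom,
                 side$frame_start_min, side$frame_dur_min, unit = side$unit)
}

#' @rdname io
#' @param profile an [institution_profile()].
#' @export
write_profile_yaml <- function(profile, path) {
  stopifnot(inherits(profile, "institution_profile"))
  x <- unclass(profile)
  x$scatter <- unclass(x$scatter)
  yaml::write_yaml(x, path)
  invisible(profile)
}

#' @rdname io
#' @export
read_profile_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  institution_profile(
    name = x$name, fwhm_mm = x$fwhm_mm, bcf = x$bcf, ccf = x$ccf,
    dose_mbq = x$dose_mbq, acz_dose_mg_kg = x$acz_dose_mg_kg,
    n_subjects = x$n_subjects,
    scatter = do.call(scatter_params, x$scatter),
    sensitivity_scale = x$sensitivity_scale
  )
}

#' @rdname io
#' @param schedule an [acquisition_schedule()].
#' @export
write_schedule_yaml <- function(schedule, path) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  yaml::write_yaml(unclass(schedule), path)
  invisible(schedule)
}

#' @rdname io
#' @export
read_schedule_yaml <- function(path) {
  do.call(acquisition_schedule, yaml::read_yaml(path))
}

#' Write the report bundle of a multicentre comparison
#'
#' Emits the summary tables (one row per institution x region, mean/SD for
#' both conditions plus per-subject CVR) and the statistical test tables as
#' UTF-8 CSV files, for the raw and (when present) resolution-equalized
#' analyses, plus the measured resolutions and a JSON provenance record.
#'
#' @param report a `multicenter_report`.
#' @param dir output directory (created if needed).
#' @return the written file paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "multicenter_report"), !isTRUE(report$skipped))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(tab, name) {
    p <- file.path(dir, name)
    utils::write.csv(tab, p, row.names = FALSE, fileEncoding = "UTF-8")
    paths <<- c(paths, p)
  }
  for (nm in names(report$summaries)) {
    emit(report$summaries[[nm]], sprintf("summary_%s.csv", nm))
    emit(report$tests[[nm]], sprintf("tests_%s.csv", nm))
    emit(report$cohorts[[nm]], sprintf("cohort_%s.csv", nm))
  }
  emit(report$resolution, "resolution.csv")
  prov <- list(
    seed = report$config$seed,
    n_subjects = report$config$n_subjects,
    institutions = names(report$config$institutions),
    noise = report$config$noise,
    subject_cv = report$config$subject_cv,
    scale_s = lapply(report$studies, function(st)
      vapply(st$subjects, function(s) s$fit$scale_s, numeric(1))),
    global_cbf = lapply(report$studies, function(st)
      vapply(st$subjects, function(s) s$fit$global_cbf, numeric(1)))
  )
  pj <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, pj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pj))
}
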