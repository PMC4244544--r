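#' Tidy and glance methods
#'
#' Broom-style accessors for the package's result objects:
#' `tidy()` returns the tabular content of a result as a tibble, `glance()` a
#' one-row summary.
#'
#' @param x a `multicenter_report`, `institution_study`,
#'   `resolution_estimate` or `lookup_table`.
#' @param analysis for reports, `"equalized"` (default when present) or
#'   `"raw"`.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.multicenter_report <- function(x, analysis = NULL, ...) {
  if (isTRUE(x$skipped)) return(tibble::tibble())
  if (is.null(analysis)) {
    analysis <- if (!is.null(x$tests$equalized)) "equalized" else "raw"
  }
  x$tests[[analysis]]
}

#' @rdname tidiers
#' @export
glance.multicenter_report <- function(x, ...) {
  if (isTRUE(x$skipped)) return(tibble::tibble(skipped = TRUE))
  sig <- function(tab) sum(tab$test == "steel_dwass" & tab$p_adjusted < 0.05)
  tibble::tibble(
    n_institutions = length(x$studies),
    n_subjects = sum(vapply(x$studies, function(s) length(s$subjects), integer(1))),
    target_fwhm_mm = max(x$resolution$fwhm_measured_mm),
    n_significant_raw = sig(x$tests$raw),
    n_significant_equalized = if (!is.null(x$tests$equalized))
      sig(x$tests$equalized) else NA_integer_
  )
}

#' @rdname tidiers
#' @export
tidy.institution_study <- function(x, ...) x$cohort

#' @rdname tidiers
#' @export
glance.institution_study <- function(x, ...) {
  tibble::tibble(
    institution = x$profile$name,
    n_subjects = length(x$subjects),
    bcf = x$precomp$bcf, ccf = x$precomp$ccf,
    fwhm_measured_mm = x$precomp$resolution$fwhm_mm,
    mean_global_cbf = mean(vapply(x$subjects, function(s) s$fit$global_cbf,
                                  numeric(1)))
  )
}

#' @rdname tidiers
#' @export
tidy.resolution_estimate <- function(x, ...) {
  tibble::tibble(fwhm_mm = x$fwhm_mm, sigma_mm = x$sigma_mm,
                 residual = x$residual, n_freq = x$n_freq)
}

#' @rdname tidiers
#' @export
glance.lookup_table <- function(x, ...) {
  tibble::tibble(
    window_start_min = attr(x, "window")[1],
    window_end_min = attr(x, "window")[2],
    scale_s = attr(x, "scale_s"),
    vd = attr(x, "constants")$vd,
    f_max = max(x$flow), activity_max = max(x$activity)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
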