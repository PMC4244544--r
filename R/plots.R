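#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's objects: slice maps of
#' images, input-function curves, look-up tables, and cohort summaries.
#'
#' @param object the object to plot.
#' @param slice slice index (images).
#' @param ... unused.
#' @return a ggplot.
#' @name autoplot-methods
NULL

image_df <- function(image, slice) {
  a <- as_image_data(image)
  sp <- if (inherits(image, "spect_image")) image$spacing_mm[1] else 1
  n1 <- dim(a)[1]; n2 <- dim(a)[2]
  tibble::tibble(
    x = rep((seq_len(n1) - (n1 + 1) / 2) * sp, times = n2),
    y = rep((seq_len(n2) - (n2 + 1) / 2) * sp, each = n1),
    value = as.numeric(a[, , slice])
  )
}

#' @rdname autoplot-methods
#' @export
autoplot.spect_image <- function(object, slice = 1L, ...) {
  df <- image_df(object, slice)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = object$unit) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("slice %d", slice)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.input_function <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_min, .data$value_bqml)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "whole-blood activity (Bq/mL)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.lookup_table <- function(object, ...) {
  w <- attr(object, "window")
  ggplot2::ggplot(object, ggplot2::aes(.data$flow, .data$activity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "flow (mL/min/mL)",
                  y = sprintf("window-mean activity %g-%g min (Bq/mL)",
                              w[1], w[2])) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.multicenter_report <- function(object, ...) {
  if (isTRUE(object$skipped)) stop("nothing to plot: comparison was skipped",
                                   call. = FALSE)
  coh <- dplyr::bind_rows(
    dplyr::mutate(object$cohorts$raw, analysis = "raw"),
    if (!is.null(object$cohorts$equalized))
      dplyr::mutate(object$cohorts$equalized, analysis = "equalized")
  )
  ggplot2::ggplot(coh, ggplot2::aes(.data$region, .data$cbf,
                                    fill = .data$institution)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_grid(.data$analysis ~ .data$condition) +
    ggplot2::labs(x = NULL, y = "CBF (mL/min/100 g)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
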