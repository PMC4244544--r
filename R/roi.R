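#' Deterministic ROI template for the brain phantom
#'
#' Stand-in for an automatic atlas-based ROI tool: partitions the phantom's
#' gray matter into named vascular territories — the cortical mantle split by
#' azimuth into anterior (ACA), middle (MCA) and posterior (PCA) cerebral
#' artery territories per hemisphere, the deep nuclei (basal ganglia,
#' thalamus), and the infratentorial structures (pons, vermis, cerebellum) —
#' plus the centrum semiovale white-matter region on both sides. The
#' territories partition the gray-matter mask exactly and the template is a
#' deterministic function of the phantom.
#'
#' @param phantom a brain `phantom_spec`.
#' @param aca_half_angle_deg half-angle of the anterior sector (default 30).
#' @param pca_half_angle_deg half-angle of the posterior sector (default 50).
#' @return An `roi_set`: list with `labels` (integer array of ROI ids) and
#'   `regions` (tibble: `roi_id`, `region`, `side`).
#' @export
make_roi_template <- function(phantom, aca_half_angle_deg = 30,
                              pca_half_angle_deg = 50) {
  if (phantom$kind != "brain") stop("ROI template requires a brain phantom",
                                    call. = FALSE)
  d <- dim(phantom$labels)
  grid <- d[1]
  idx <- (seq_len(grid) - (grid + 1) / 2) * phantom$spacing_mm
  xx <- outer(idx, rep(1, grid))
  yy <- outer(rep(1, grid), idx)
  az <- abs(atan2(xx, yy)) * 180 / pi    # 0 = anterior (+y), 180 = posterior
  right <- xx > 0

  regions <- tibble::tibble(
    roi_id = 1:18,
    region = c(rep(c("aca", "mca", "pca", "basal_ganglia", "thalamus",
                     "cerebellum", "white_matter"), each = 2),
               "pons", "vermis", "hemisphere", "hemisphere"),
    side = c(rep(c("left", "right"), 7), NA, NA, "left", "right")
  )
  # hemisphere ids 17/18 are composites resolved in roi_means(), not painted
  paint <- array(0L, dim = d)
  lab <- phantom$labels
  ctx <- lab == 4L
  sector <- function(slice_mask, cond) {
    m <- array(FALSE, d); m[, , 1] <- cond; m & slice_mask
  }
  aca <- az <= aca_half_angle_deg
  pca <- az >= 180 - pca_half_angle_deg
  mca <- !aca & !pca
  paint[sector(ctx, aca & !right)] <- 1L
  paint[sector(ctx, aca & right)] <- 2L
  paint[sector(ctx, mca & !right)] <- 3L
  paint[sector(ctx, mca & right)] <- 4L
  paint[sector(ctx, pca & !right)] <- 5L
  paint[sector(ctx, pca & right)] <- 6L
  paint[lab == 5L] <- 7L;  paint[lab == 6L] <- 8L    # basal ganglia
  paint[lab == 7L] <- 9L;  paint[lab == 8L] <- 10L   # thalamus
  paint[lab == 11L] <- 11L; paint[lab == 12L] <- 12L # cerebellum
  wm_l <- array(FALSE, d); wm_l[, , 1] <- lab[, , 1] == 3L & xx < 0  # centrum
  wm_r <- array(FALSE, d); wm_r[, , 1] <- lab[, , 1] == 3L & xx > 0  # semiovale
  paint[wm_l] <- 13L
  paint[wm_r] <- 14L
  paint[lab == 9L] <- 15L                             # pons
  paint[lab == 10L] <- 16L                            # vermis

  counts <- tabulate(paint, nbins = 16L)
  if (any(counts == 0L)) {
    bad <- regions$region[seq_len(16)][counts == 0L]
    stop("empty ROI region(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  structure(list(labels = paint, regions = regions,
                 hemisphere_ids = list(left = c(1L, 3L, 5L, 7L, 9L),
                                       right = c(2L, 4L, 6L, 8L, 10L))),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set>", sum(x$labels > 0), "voxels in",
      length(unique(x$regions$region)), "regions\n")
  invisible(x)
}

#' Regional mean values
#'
#' Mean voxel value per named region and side, with bilateral rows
#' (`side = "both"`) computed as the average of the left and right region
#' means, plus hemisphere rows (ACA + MCA + PCA + basal ganglia + thalamus).
#'
#' @param image a `spect_image` on the ROI grid.
#' @param rois an `roi_set` from [make_roi_template()].
#' @return tibble with columns `region`, `side`, `n_vox`, `mean`.
#' @export
roi_means <- function(image, rois) {
  a <- as_image_data(image)
  stopifnot(all(dim(a) == dim(rois$labels)))
  ids <- seq_len(16)
  base <- rois$regions[rois$regions$roi_id <= 16L, ]
  base$n_vox <- vapply(ids, function(i) sum(rois$labels == i), integer(1))
  base$mean <- vapply(ids, function(i) mean(a[rois$labels == i]), numeric(1))
  hemi <- dplyr::bind_rows(lapply(c("left", "right"), function(s) {
    m <- rois$labels %in% rois$hemisphere_ids[[s]]
    tibble::tibble(region = "hemisphere", side = s,
                   n_vox = sum(m), mean = mean(a[m]))
  }))
  out <- dplyr::bind_rows(
    tibble::tibble(region = base$region, side = base$side,
                   n_vox = base$n_vox, mean = base$mean),
    hemi
  )
  both <- out |>
    dplyr::filter(!is.na(.data$side)) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(side = "both", n_vox = sum(.data$n_vox),
                     mean = mean(.data$mean), .groups = "drop")
  out$side[is.na(out$side)] <- "both"   # midline regions (pons, vermis)
  dplyr::bind_rows(out[!(out$region %in% both$region & out$side == "both"), ],
                   both) |>
    dplyr::arrange(.data$region, .data$side)
}
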