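#' Parallel-beam acquisition geometry
#'
#' Describes the sinogram sampling shared by the simulator and the
#' reconstruction: equally spaced views over 360 degrees (so every ray has an
#' opposed partner, as required by geometric-mean reconstruction) or over 180
#' degrees, and radial bins that coincide with the image columns (bin width =
#' voxel spacing, number of bins = image side).
#'
#' @param nview number of views over `span_deg`.
#' @param nbin number of radial bins (must equal the image side length).
#' @param bin_mm radial bin width in mm (must equal the voxel spacing).
#' @param span_deg angular span, 360 (default) or 180.
#' @return A `spect_geometry` object.
#' @export
spect_geometry <- function(nview = 60L, nbin = 64L, bin_mm = 3.4375, span_deg = 360) {
  stopifnot(nview >= 2, nbin >= 8, bin_mm > 0, span_deg %in% c(180, 360))
  if (span_deg == 360 && nview %% 2L != 0L) {
    stop("360-degree geometry needs an even number of views for opposed pairing",
         call. = FALSE)
  }
  structure(
    list(
      nview = as.integer(nview), nbin = as.integer(nbin),
      bin_mm = bin_mm, span_deg = span_deg,
      angles_deg = seq(0, span_deg, length.out = nview + 1L)[seq_len(nview)]
    ),
    class = "spect_geometry"
  )
}

#' @export
print.spect_geometry <- function(x, ...) {
  cat(sprintf("<spect_geometry> %d views / %d deg, %d bins of %.4g mm\n",
              x$nview, x$span_deg, x$nbin, x$bin_mm))
  invisible(x)
}

# ---- rotation operators ----------------------------------------------------
# The projector is rotate-and-sum: for each view the image is resampled on a
# grid rotated by the view angle (bilinear interpolation) and summed along the
# ray direction. Each rotation is materialised once as a sparse matrix, so its
# exact adjoint is the transpose; matrices are cached per (n, angle).

.rot_cache <- new.env(parent = emptyenv())

rotation_operator <- function(n, theta) {
  key <- sprintf("%d|%.12f", n, theta)
  hit <- .rot_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- seq_len(n) - (n + 1) / 2
  g <- expand.grid(x = idx, y = idx)
  ct <- cos(theta); st <- sin(theta)
  xs <- ct * g$x + st * g$y     # source coordinates sampled by each target pixel
  ys <- -st * g$x + ct * g$y
  i0 <- floor(xs - idx[1]) + 1
  j0 <- floor(ys - idx[1]) + 1
  fx <- (xs - idx[1]) - (i0 - 1)
  fy <- (ys - idx[1]) - (j0 - 1)
  tgt <- seq_len(n * n)
  rows <- vector("list", 4L); cols <- rows; vals <- rows
  q <- 1L
  for (di in 0:1) {
    for (dj in 0:1) {
      ii <- i0 + di; jj <- j0 + dj
      w <- (if (di == 1L) fx else 1 - fx) * (if (dj == 1L) fy else 1 - fy)
      ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n & w > 0
      rows[[q]] <- tgt[ok]; cols[[q]] <- ii[ok] + (jj[ok] - 1) * n; vals[[q]] <- w[ok]
      q <- q + 1L
    }
  }
  m <- Matrix::sparseMatrix(
    i = unlist(rows), j = unlist(cols), x = unlist(vals), dims = c(n * n, n * n)
  )
  .rot_cache[[key]] <- m
  m
}

rotate_gather <- function(img, theta) {
  n <- nrow(img)
  matrix(as.numeric(rotation_operator(n, theta) %*% as.numeric(img)), n, n)
}

rotate_scatter <- function(img, theta) {
  n <- nrow(img)
  key <- sprintf("t|%d|%.12f", n, theta)
  rt <- .rot_cache[[key]]
  if (is.null(rt)) {
    rt <- Matrix::t(rotation_operator(n, theta))
    .rot_cache[[key]] <- rt
  }
  matrix(as.numeric(rt %*% as.numeric(img)), n, n)
}

# cumulative attenuation above each voxel (detector at +y in the rotated frame),
# exclusive of the voxel itself
rev_cumsum_cols <- function(m) {
  n2 <- ncol(m)
  out <- matrix(0, nrow(m), n2)
  acc <- numeric(nrow(m))
  for (j in n2:1) {
    out[, j] <- acc
    acc <- acc + m[, j]
  }
  out
}

fp_slice <- function(img, geom, mu = NULL, attn = NULL) {
  n <- nrow(img)
  dl <- geom$bin_mm
  th <- geom$angles_deg * pi / 180
  out <- matrix(0, geom$nbin, geom$nview)
  for (v in seq_len(geom$nview)) {
    arot <- rotate_gather(img, th[v])
    if (!is.null(attn)) {
      out[, v] <- dl * rowSums(arot * attn[[v]])
    } else if (is.null(mu)) {
      out[, v] <- dl * rowSums(arot)
    } else {
      out[, v] <- dl * rowSums(arot * attenuation_factors(mu, th[v], dl))
    }
  }
  out
}

# per-view attenuation factors from the emitting voxel centre to the detector
attenuation_factors <- function(mu, theta, dl) {
  murot <- rotate_gather(mu, theta)
  exp(-(dl / 10) * (rev_cumsum_cols(murot) + 0.5 * murot))
}

bp_slice <- function(proj, geom) {
  n <- geom$nbin
  dl <- geom$bin_mm
  th <- geom$angles_deg * pi / 180
  img <- matrix(0, n, n)
  for (v in seq_len(geom$nview)) {
    img <- img + rotate_scatter(matrix(proj[, v], n, n), th[v])
  }
  dl * img
}

check_projector_grid <- function(image, geom, mu_map = NULL) {
  a <- as_image_data(image)
  if (dim(a)[1] != dim(a)[2] || dim(a)[1] != geom$nbin) {
    stop("image grid and geometry disagree: need a square image with side = nbin",
         call. = FALSE)
  }
  if (inherits(image, "spect_image") &&
      abs(image$spacing_mm[1] - geom$bin_mm) > 1e-9) {
    stop("voxel spacing and radial bin width disagree", call. = FALSE)
  }
  if (!is.null(mu_map)) {
    b <- as_image_data(mu_map)
    if (!all(dim(a) == dim(b))) stop("image and mu-map grids differ", call. = FALSE)
  }
  invisible(a)
}

#' Attenuated parallel-beam forward projection
#'
#' For each ray the line integral of the activity is accumulated with an
#' exponential attenuation factor from the emitting voxel to the detector
#' (single-photon convention); without a mu-map plain line integrals are
#' returned. Line integrals carry units of (voxel value) x mm.
#'
#' @param image activity image (`spect_image`, matrix, or 3-D array).
#' @param geometry a [spect_geometry()].
#' @param mu_map optional attenuation map in cm^-1 on the same grid.
#' @return sinogram array `nbin x nview x nslice` with attribute `"geometry"`.
#' @export
forward_project <- function(image, geometry, mu_map = NULL) {
  a <- check_projector_grid(image, geometry, mu_map)
  mu <- if (is.null(mu_map)) NULL else as_image_data(mu_map)
  out <- array(0, dim = c(geometry$nbin, geometry$nview, dim(a)[3]))
  for (k in seq_len(dim(a)[3])) {
    out[, , k] <- fp_slice(a[, , k], geometry, mu = if (is.null(mu)) NULL else mu[, , k])
  }
  attr(out, "geometry") <- geometry
  out
}

#' Unweighted back-projection (adjoint of the unattenuated projector)
#'
#' Exact adjoint of [forward_project()] without attenuation:
#' `sum((A x) * y) == sum(x * (A^T y))` to machine precision, by construction
#' (each view is a cached sparse operator and its transpose).
#'
#' @param proj sinogram array `nbin x nview` or `nbin x nview x nslice`.
#' @param geometry a [spect_geometry()].
#' @return image array `nbin x nbin x nslice`.
#' @export
back_project <- function(proj, geometry) {
  if (length(dim(proj)) == 2L) proj <- array(proj, dim = c(dim(proj), 1L))
  stopifnot(dim(proj)[1] == geometry$nbin, dim(proj)[2] == geometry$nview)
  out <- array(0, dim = c(geometry$nbin, geometry$nbin, dim(proj)[3]))
  for (k in seq_len(dim(proj)[3])) out[, , k] <- bp_slice(proj[, , k], geometry)
  out
}
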