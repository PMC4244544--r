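#' Digital phantoms
#'
#' @description
#' A `phantom_spec` holds a labelled voxel grid together with a compartment
#' table assigning each label a tissue class, a true attenuation coefficient
#' (cm^-1), rest and post-acetazolamide perfusion (CBF, mL/min/100 g) and an
#' optional fixed activity concentration (Bq/mL) for static phantoms.
#' Perfusion is converted to flow per mL of tissue internally via
#' `f = CBF * rho / 100` with blood/brain density `rho = 1.06 g/mL`.
#'
#' `make_brain_phantom()` builds a two-slice numerical head: a cerebral slice
#' with scalp, skull, a convoluted cortical gray-matter mantle, a white-matter
#' core and deep gray nuclei (basal ganglia, thalamus), and an infratentorial
#' slice with pons, vermis and cerebellar hemispheres. Compartments are drawn
#' generously large relative to clinical SPECT resolution so that core regions
#' retain their true values after system blurring; the skull (0.230 cm^-1)
#' is denser than brain and scalp (0.146 cm^-1, water at 159 keV), so
#' reconstruction with a uniform coefficient is a genuine approximation,
#' while the head-averaged chord stays close to the conventional
#' 0.160 cm^-1 brain-plus-skull average that the reconstruction assumes.
#'
#' @param grid side length of the square in-plane grid (voxels), >= 32.
#' @param spacing_mm in-plane voxel size in mm.
#' @param seed integer seed fixing the (mild) random phase of the cortical
#'   convolution pattern; identical seeds give identical label maps.
#' @param gm_cbf_rest,gm_cbf_acz gray-matter CBF at rest / after acetazolamide
#'   (mL/min/100 g).
#' @param wm_cbf_rest,wm_cbf_acz white-matter CBF at rest / after acetazolamide.
#' @return A `phantom_spec`.
#' @export
make_brain_phantom <- function(grid = 64L, spacing_mm = 3.4375, seed = 1L,
                               gm_cbf_rest = 35.7, gm_cbf_acz = 51.7,
                               wm_cbf_rest = 25.8, wm_cbf_acz = 34.3) {
  stopifnot(grid >= 32, spacing_mm > 0)
  half <- grid * spacing_mm / 2
  if (half < 95) {
    stop("grid too small to contain head, skull and scalp (need >= 190 mm field)",
         call. = FALSE)
  }
  phase <- withr::with_seed(seed, stats::runif(1, 0, 2 * pi))
  idx <- (seq_len(grid) - (grid + 1) / 2) * spacing_mm
  xx <- outer(idx, rep(1, grid))
  yy <- outer(rep(1, grid), idx)
  inside_ell <- function(cx, cy, a, b) ((xx - cx) / a)^2 + ((yy - cy) / b)^2 <= 1

  lab <- array(0L, dim = c(grid, grid, 2L))

  # --- slice 1: cerebrum ---
  s <- matrix(0L, grid, grid)
  s[inside_ell(0, 0, 75, 85)] <- 1L                      # scalp
  s[inside_ell(0, 0, 70, 80)] <- 2L                      # skull
  brain <- inside_ell(0, 0, 61, 71)
  s[brain] <- 4L                                         # cortex (gray matter)
  phi <- atan2(yy - 3, xx)
  rmod <- 1 + 0.10 * sin(5 * phi + phase)                # convoluted interface
  wm <- ((xx / 40)^2 + ((yy - 3) / 32)^2) <= rmod^2
  s[brain & wm] <- 3L                                    # white-matter core
  s[inside_ell(-19, 11, 7, 9)] <- 5L                     # basal ganglia L/R
  s[inside_ell(19, 11, 7, 9)] <- 6L
  s[inside_ell(-9, -11, 6, 7)] <- 7L                     # thalamus L/R
  s[inside_ell(9, -11, 6, 7)] <- 8L
  lab[, , 1] <- s

  # --- slice 2: posterior fossa ---
  s <- matrix(0L, grid, grid)
  s[inside_ell(0, 0, 65, 75)] <- 1L
  s[inside_ell(0, 0, 60, 70)] <- 2L
  brain2 <- inside_ell(0, 0, 51, 61)
  s[brain2] <- 3L
  cereb <- brain2 & (yy <= 2)
  s[cereb & xx < -9] <- 11L                              # cerebellum L
  s[cereb & xx > 9] <- 12L                               # cerebellum R
  s[cereb & abs(xx) <= 9] <- 10L                         # vermis
  s[inside_ell(0, 18, 13, 11)] <- 9L                     # pons
  lab[, , 2] <- s

  comp <- tibble::tibble(
    label  = c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L),
    name   = c("background", "scalp", "skull", "white_matter", "cortex",
               "basal_ganglia_l", "basal_ganglia_r", "thalamus_l", "thalamus_r",
               "pons", "vermis", "cerebellum_l", "cerebellum_r"),
    tissue = c("air", "soft", "bone", "wm", rep("gm", 9L)),
    mu_cm  = c(0, 0.146, 0.230, 0.146, rep(0.146, 9L)),
    cbf_rest = c(0, 9, 0, wm_cbf_rest, rep(gm_cbf_rest, 9L)),
    cbf_acz  = c(0, 9, 0, wm_cbf_acz,  rep(gm_cbf_acz, 9L)),
    activity_bqml = NA_real_
  )
  new_phantom(lab, spacing_mm, comp, kind = "brain")
}

#' @rdname make_brain_phantom
#' @param diameter_mm inner diameter of the cylinder (disc in-plane), mm.
#' @param activity_bqml uniform activity concentration of the source, Bq/mL
#'   (must be >= 0).
#' @param shape `"disc"` (uniform cylinder section), `"line"` (a single
#'   central hot voxel column, i.e. an axial line source) or `"point"`.
#' @param mu_cm attenuation coefficient of the filled volume; the default
#'   0.160 cm^-1 is the effective water-equivalent value the reconstruction
#'   assumes.
#' @export
make_cylinder_phantom <- function(diameter_mm = 160, activity_bqml = 50000,
                                  shape = c("disc", "line", "point"),
                                  grid = 64L, spacing_mm = 3.4375,
                                  mu_cm = 0.160) {
  shape <- match.arg(shape)
  stopifnot(grid >= 16, spacing_mm > 0)
  if (activity_bqml < 0) stop("activity must be non-negative", call. = FALSE)
  if (diameter_mm > grid * spacing_mm - 4 * spacing_mm) {
    stop("cylinder does not fit the grid", call. = FALSE)
  }
  idx <- (seq_len(grid) - (grid + 1) / 2) * spacing_mm
  xx <- outer(idx, rep(1, grid))
  yy <- outer(rep(1, grid), idx)
  s <- matrix(0L, grid, grid)
  if (shape == "disc") {
    s[xx^2 + yy^2 <= (diameter_mm / 2)^2] <- 1L
  } else {
    ctr <- which.min(abs(idx))
    s[ctr, ctr] <- 1L
  }
  comp <- tibble::tibble(
    label = c(0L, 1L),
    name = c("background", "source"),
    tissue = c("air", "water"),
    mu_cm = c(0, if (shape == "disc") mu_cm else 0),
    cbf_rest = 0, cbf_acz = 0,
    activity_bqml = c(0, activity_bqml)
  )
  new_phantom(array(s, dim = c(grid, grid, 1L)), spacing_mm, comp,
              kind = paste0("cylinder_", shape))
}

new_phantom <- function(labels, spacing_mm, compartments, kind) {
  stopifnot(all(sort(unique(as.integer(labels))) %in% compartments$label))
  structure(
    list(labels = labels, spacing_mm = spacing_mm,
         compartments = compartments, kind = kind),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<phantom_spec: %s> %d x %d x %d voxels at %.4g mm\n",
              x$kind, d[1], d[2], d[3], x$spacing_mm))
  print(x$compartments)
  invisible(x)
}

#' Compartment masks and parametric images of a phantom
#'
#' `phantom_mask()` returns the logical union of the named compartments (or
#' tissue classes); `phantom_mu()` the true attenuation map (cm^-1);
#' `phantom_cbf()` the true perfusion image for one condition;
#' `phantom_activity()` the fixed-activity image of a static phantom.
#'
#' @param phantom a `phantom_spec`.
#' @param names compartment names, or with `tissue = TRUE` tissue classes
#'   (`"gm"`, `"wm"`, `"bone"`, ...).
#' @param tissue interpret `names` as tissue classes.
#' @export
phantom_mask <- function(phantom, names, tissue = FALSE) {
  comp <- phantom$compartments
  labs <- if (tissue) comp$label[comp$tissue %in% names]
          else comp$label[comp$name %in% names]
  if (!length(labs)) stop("no such compartment: ", paste(names, collapse = ", "),
                          call. = FALSE)
  array(phantom$labels %in% labs, dim = dim(phantom$labels))
}

label_image <- function(phantom, values) {
  # values: named by label (character) or vector indexed by label+1
  lut <- values[as.character(phantom$labels)]
  array(lut, dim = dim(phantom$labels))
}

compartment_lut <- function(phantom, column) {
  v <- phantom$compartments[[column]]
  names(v) <- as.character(phantom$compartments$label)
  v
}

#' @rdname phantom_mask
#' @export
phantom_mu <- function(phantom) {
  spect_image(label_image(phantom, compartment_lut(phantom, "mu_cm")),
              phantom$spacing_mm, unit = "cm^-1")
}

#' @rdname phantom_mask
#' @param condition `"rest"` or `"acz"`.
#' @export
phantom_cbf <- function(phantom, condition = c("rest", "acz")) {
  condition <- match.arg(condition)
  col <- if (condition == "rest") "cbf_rest" else "cbf_acz"
  spect_image(label_image(phantom, compartment_lut(phantom, col)),
              phantom$spacing_mm, unit = "mL/min/100g")
}

#' @rdname phantom_mask
#' @export
phantom_activity <- function(phantom) {
  v <- compartment_lut(phantom, "activity_bqml")
  v[is.na(v)] <- 0
  spect_image(label_image(phantom, v), phantom$spacing_mm, unit = "Bq/mL")
}

#' Cortical-core gray-matter mask
#'
#' The gray-matter mask eroded by `margin_mm` (Euclidean distance to the
#' compartment boundary), the package's canonical region for global gray
#' matter CBF: boundary voxels, whose values are diluted by the scanner
#' point-spread function, are excluded so that the global estimate reflects
#' tissue rather than resolution. Deep nuclei and infratentorial structures
#' are kept when their eroded cores are nonempty.
#'
#' @param phantom a brain `phantom_spec`.
#' @param margin_mm erosion margin in mm (default 8).
#' @return logical array.
#' @export
gm_core_mask <- function(phantom, margin_mm = 8) {
  gm <- phantom_mask(phantom, "gm", tissue = TRUE)
  out <- array(FALSE, dim = dim(gm))
  for (k in seq_len(dim(gm)[3])) {
    d <- EBImage::distmap(gm[, , k]) * phantom$spacing_mm
    out[, , k] <- d > margin_mm
  }
  if (!any(out)) stop("erosion margin leaves no gray-matter core", call. = FALSE)
  out
}
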