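#' Kinetic constants of the tracer model
#'
#' The one-tissue-compartment model used throughout:
#' `dCt/dt = f * Ca(t) - (f / Vd) * Ct(t)` with `f` the flow per mL of tissue
#' (mL/min/mL) and `Vd` the distribution volume. Perfusion is reported as
#' `CBF = 100 * f / rho` in mL/min/100 g with blood/brain density `rho`.
#'
#' @param vd distribution volume, mL/mL (default 35.0).
#' @param rho tissue density, g/mL (default 1.06).
#' @return A `kinetic_constants` list.
#' @export
kinetic_constants <- function(vd = 35.0, rho = 1.06) {
  stopifnot(vd > 0, rho > 0)
  structure(list(vd = vd, rho = rho), class = "kinetic_constants")
}

cbf_to_flow <- function(cbf, constants) cbf * constants$rho / 100
flow_to_cbf <- function(f, constants) 100 * f / constants$rho

# Fixed population input shape h(t) (dimensionless, per MBq scaling applied
# by standard_input_function): gamma-variate first pass plus a slow
# biexponential whole-blood tail. Parameters are package constants; the true
# population curve of the clinical protocol is unpublished, so this shape is
# a documented stand-in with realistic peak time and 10-min level.
.input_shape_params <- list(
  tp = 1.2,        # min, gamma-variate peak time
  w_peak = 0.85,
  w_fast = 0.10, tau_fast = 12,   # min
  w_slow = 0.05, tau_slow = 90,   # min
  tau_rise = 1.0,
  c0 = 180                        # Bq/mL per MBq administered
)

input_shape <- function(t) {
  p <- .input_shape_params
  h <- numeric(length(t))
  pos <- t > 0
  tt <- t[pos]
  gv <- (tt / p$tp)^2 * exp(2 * (1 - tt / p$tp))
  rise <- 1 - exp(-tt / p$tau_rise)
  h[pos] <- p$w_peak * gv +
    rise * (p$w_fast * exp(-tt / p$tau_fast) + p$w_slow * exp(-tt / p$tau_slow))
  h
}

#' Population-based standardized arterial input function
#'
#' The fixed analytic population shape (gamma-variate first pass plus a
#' biexponential whole-blood tail) scaled linearly by the administered dose.
#' Zero before the injection; strictly positive at the 10-min calibration
#' sample time.
#'
#' @param dose_mbq administered dose, MBq (> 0).
#' @param t_inject_min injection time (min); the curve is shifted accordingly.
#' @param t_end_min end of the tabulated grid (min).
#' @param dt_min tabulation step (min).
#' @return An `input_function`: tibble with columns `time_min`, `value_bqml`
#'   and attributes `dose_mbq`, `t_inject_min`.
#' @export
standard_input_function <- function(dose_mbq, t_inject_min = 0,
                                    t_end_min = 70, dt_min = 0.05) {
  stopifnot(dose_mbq > 0)
  tg <- seq(0, t_end_min, by = dt_min)
  val <- dose_mbq * .input_shape_params$c0 * input_shape(tg - t_inject_min)
  new_input_function(tg, val, dose_mbq, t_inject_min)
}

new_input_function <- function(time_min, value_bqml, dose_mbq, t_inject_min) {
  stopifnot(all(value_bqml >= 0), all(diff(time_min) > 0))
  out <- tibble::tibble(time_min = time_min, value_bqml = value_bqml)
  class(out) <- c("input_function", class(out))
  attr(out, "dose_mbq") <- dose_mbq
  attr(out, "t_inject_min") <- t_inject_min
  out
}

#' Evaluate an input function at arbitrary times
#'
#' Linear interpolation on the tabulated grid; zero before the grid, constant
#' extrapolation of the last value beyond it.
#'
#' @param input an `input_function`.
#' @param t_min times (min).
#' @return whole-blood activity concentration, Bq/mL.
#' @export
input_value <- function(input, t_min) {
  stats::approx(input$time_min, input$value_bqml, xout = t_min,
                yleft = 0, rule = c(1, 2))$y
}

scale_input <- function(input, factor) {
  new_input_function(input$time_min, input$value_bqml * factor,
                     attr(input, "dose_mbq") * factor, attr(input, "t_inject_min"))
}

#' Tissue time-activity curve of the one-tissue-compartment model
#'
#' Solves `dCt/dt = f * Ca(t) - (f / Vd) * Ct` by an exact exponential
#' integrator with trapezoidal quadrature of the driving term on an internal
#' grid of at most `dt_min` (default 1 s), then interpolates onto the
#' requested time grid. Vectorised over `f`: with several flows a matrix
#' `length(time_min) x length(f)` is returned.
#'
#' @param f flow(s) per mL of tissue, mL/min/mL, all >= 0.
#' @param vd distribution volume, mL/mL.
#' @param input an `input_function` (absolute time axis).
#' @param time_min output time grid (min).
#' @param dt_min internal integration step (min), default 1/60 (1 s).
#' @return numeric vector (single `f`) or matrix (vector `f`) of tissue
#'   activity, Bq/mL.
#' @export
tissue_tac <- function(f, vd, input, time_min, dt_min = 1 / 60) {
  sol <- tac_fine_solution(f, vd, input, max(time_min), dt_min)
  out <- apply(sol$ct, 2L, function(col) {
    stats::approx(sol$time, col, xout = time_min, rule = 2)$y
  })
  out <- matrix(out, nrow = length(time_min), ncol = length(f))
  if (length(f) == 1L) drop(out) else out
}

# fine-grid solution shared by tissue_tac, window means and frame integrals:
# exact exponential integrator with trapezoidal quadrature of f * Ca
tac_fine_solution <- function(f, vd, input, tmax_min, dt_min = 1 / 60) {
  if (any(f < 0)) stop("negative flow", call. = FALSE)
  stopifnot(vd > 0, dt_min > 0)
  fine <- seq(0, tmax_min + dt_min, by = dt_min)
  ca <- input_value(input, fine)
  nf <- length(f)
  E <- exp(-(f / vd) * dt_min)
  ct <- matrix(0, length(fine), nf)
  cur <- numeric(nf)
  for (i in seq_len(length(fine) - 1L)) {
    cur <- cur * E + f * (dt_min / 2) * (ca[i] * E + ca[i + 1L])
    ct[i + 1L, ] <- cur
  }
  list(time = fine, ct = ct)
}

window_mean_from_solution <- function(sol, window) {
  inw <- sol$time >= window[1] - 1e-9 & sol$time <= window[2] + 1e-9
  w <- rep(1, sum(inw)); w[1] <- 0.5; w[length(w)] <- 0.5
  as.numeric(crossprod(w, sol$ct[inw, , drop = FALSE])) / sum(w)
}

# window mean of the tissue curve for a vector of flows; the workhorse behind
# the look-up tables
tissue_window_mean <- function(f, vd, input, window, dt_min = 1 / 60) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  sol <- tac_fine_solution(f, vd, input, window[2], dt_min)
  window_mean_from_solution(sol, window)
}

# per-frame window means for a vector of flows: nframe x nflow matrix
tac_frame_means <- function(f, vd, input, frame_start, frame_dur, dt_min = 1 / 60) {
  sol <- tac_fine_solution(f, vd, input, max(frame_start + frame_dur), dt_min)
  out <- matrix(0, length(frame_start), length(f))
  for (i in seq_along(frame_start)) {
    out[i, ] <- window_mean_from_solution(sol, c(frame_start[i], frame_start[i] + frame_dur[i]))
  }
  out
}
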