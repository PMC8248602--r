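# SRTM forward machinery shared by the simulator and the fitter.
#
# The simplified reference tissue model expresses a target-region TAC as
#   Ct(t) = R1 * Cr(t) + (k2 - R1 * k2a) * [Cr (*) exp(-k2a t)](t)
# with k2a = k2 / (1 + BP_ND); Cr is the reference-region (cerebellum) TAC
# and (*) denotes convolution.

# Convolution of a uniformly sampled signal with exp(-k t) by trapezoidal
# quadrature, computed recursively so each step is exact for the trapezoid
# rule: c_i = c_{i-1} e^{-k dt} + dt/2 (f_i + f_{i-1} e^{-k dt}).
conv_exp_decay <- function(f, k, dt) {
  n <- length(f)
  out <- numeric(n)
  ek <- exp(-k * dt)
  for (i in seq_len(n)[-1]) {
    out[i] <- out[i - 1] * ek + dt / 2 * (f[i] + f[i - 1] * ek)
  }
  out
}

#' Analytic reference-region time-activity curve
#'
#' A smooth two-exponential curve, zero at injection, peaking near 3.5 min
#' and washing out slowly — the shape of a cerebellar TAC after a bolus
#' injection of a reversibly binding radioligand. Used as the receptor-free
#' input to the SRTM forward model in [gen_pet_study()].
#'
#' @param t_min time points (minutes).
#' @param peak_kbq approximate peak activity (kBq/mL).
#' @return numeric vector of activities (kBq/mL).
#' @export
reference_tac <- function(t_min, peak_kbq = 25) {
  l1 <- 0.04  # slow washout, 1/min
  l2 <- 0.90  # fast uptake, 1/min
  shape <- exp(-l1 * t_min) - exp(-l2 * t_min)
  tp <- log(l2 / l1) / (l2 - l1)
  peak_shape <- exp(-l1 * tp) - exp(-l2 * tp)
  peak_kbq * shape / peak_shape
}

#' SRTM forward model on a fine time grid
#'
#' Computes the target-region TAC implied by the simplified reference tissue
#' model for given kinetic parameters, by convolution on a uniform internal
#' grid, and samples it at requested times by linear interpolation.
#'
#' @param t_out times (min) at which to return the modeled activity,
#'   typically frame midpoints.
#' @param ref_fun function of time returning the reference TAC, or a numeric
#'   vector of reference activities at `t_out` (interpolated internally).
#' @param r1 delivery ratio target/reference (unitless).
#' @param k2 target-region clearance rate (1/min).
#' @param bp_nd binding potential (unitless, >= 0).
#' @param dt internal convolution grid step (min).
#' @param t_end end of the internal grid (min); defaults to `max(t_out)`.
#' @return numeric vector of modeled activities at `t_out`.
#' @export
srtm_forward <- function(t_out, ref_fun, r1, k2, bp_nd,
                         dt = 0.05, t_end = max(t_out)) {
  k2a <- k2 / (1 + bp_nd)
  t_fine <- seq(0, t_end + dt, by = dt)
  if (is.function(ref_fun)) {
    cr <- ref_fun(t_fine)
  } else {
    cr <- stats::approx(c(0, t_out), c(0, ref_fun), xout = t_fine,
                        rule = 2)$y
  }
  conv <- conv_exp_decay(cr, k2a, dt)
  ct <- r1 * cr + (k2 - r1 * k2a) * conv
  stats::approx(t_fine, ct, xout = t_out, rule = 2)$y
}

frame_midpoints <- function(frames) (frames[, 1] + frames[, 2]) / 2
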