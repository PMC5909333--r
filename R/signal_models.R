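#' Mono-exponential T2 decay signal
#'
#' Spin-echo signal model \eqn{SI = SI_0 e^{-TE/T2}}: the signal measured at
#' echo time `te_ms` for a tissue with transverse relaxation constant `t2_ms`
#' and extrapolated zero-echo intensity `si0`.
#'
#' @param si0 Signal intensity at the theoretical TE = 0 point (a.u., >= 0).
#' @param te_ms Echo time in milliseconds (>= 0). Vectorised.
#' @param t2_ms Transverse relaxation time in milliseconds (> 0).
#' @return Signal intensity in the same arbitrary units as `si0`.
#' @examples
#' t2_signal(1000, c(0, 57), 57)   # 1000, 1000/e
#' @export
t2_signal <- function(si0, te_ms, t2_ms) {
  if (any(t2_ms <= 0)) stop("t2_ms must be positive", call. = FALSE)
  if (any(si0 < 0)) stop("si0 must be non-negative", call. = FALSE)
  if (any(te_ms < 0)) stop("te_ms must be non-negative", call. = FALSE)
  si0 * exp(-te_ms / t2_ms)
}

#' Magnitude inversion-recovery signal
#'
#' Magnitude signal of a 180-degree-prepared inversion recovery acquisition,
#' \eqn{|M| = m_0 |1 - 2 e^{-TI/T1}|}. The recovery-period (TR) term is
#' deliberately omitted: the model is the simplest one that reproduces the
#' nulling behaviour (`ir_signal` is exactly zero at `TI = T1 ln 2`) and the
#' enhancement ordering of post-contrast tissue classes.
#'
#' @param m0 Equilibrium magnetisation / proton-density scale (a.u., >= 0).
#' @param ti_ms Inversion time in milliseconds (> 0). Vectorised.
#' @param t1_ms Longitudinal relaxation time in milliseconds (> 0).
#' @return Magnitude signal (a.u.).
#' @seealso [nulling_ti()]
#' @export
ir_signal <- function(m0, ti_ms, t1_ms) {
  if (any(t1_ms <= 0)) stop("t1_ms must be positive", call. = FALSE)
  if (any(ti_ms <= 0)) stop("ti_ms must be positive", call. = FALSE)
  if (any(m0 < 0)) stop("m0 must be non-negative", call. = FALSE)
  m0 * abs(1 - 2 * exp(-ti_ms / t1_ms))
}

#' Inversion time that nulls a tissue
#'
#' The TI at which the magnitude IR signal of a tissue with longitudinal
#' relaxation `t1_ms` is zero: \eqn{TI = T1 \ln 2}. Used to emulate the
#' operator continuously adjusting TI to null remote myocardium on late
#' gadolinium enhancement series.
#'
#' @param t1_ms Longitudinal relaxation time in milliseconds (> 0).
#' @return Nulling inversion time in milliseconds.
#' @export
nulling_ti <- function(t1_ms) {
  if (any(t1_ms <= 0)) stop("t1_ms must be positive", call. = FALSE)
  t1_ms * log(2)
}

#' Post-contrast longitudinal relaxation time
#'
#' Fast-exchange relaxivity model: the post-contrast relaxation rate is the
#' native rate plus relaxivity times local gadolinium concentration,
#' \eqn{1/T1 = 1/T1_{pre} + r_1 C}.
#'
#' @param t1_pre_ms Native (pre-contrast) T1 in milliseconds (> 0).
#' @param r1 Contrast-agent longitudinal relaxivity in L mmol^-1 s^-1.
#' @param conc_mM Local agent concentration in mmol/L (>= 0). Vectorised.
#' @return Post-contrast T1 in milliseconds.
#' @export
post_contrast_t1 <- function(t1_pre_ms, r1, conc_mM) {
  if (any(t1_pre_ms <= 0)) stop("t1_pre_ms must be positive", call. = FALSE)
  if (any(conc_mM < 0)) stop("conc_mM must be non-negative", call. = FALSE)
  1000 / (1000 / t1_pre_ms + r1 * conc_mM)
}

#' Add Rician noise to a noiseless magnitude image
#'
#' Magnitude MRI noise: independent Gaussian noise of standard deviation
#' `sigma` is added to the real (signal-bearing) and imaginary channels and
#' the magnitude taken, giving Rician-distributed intensities. At high SNR
#' this approaches additive Gaussian noise; at zero signal it is Rayleigh.
#'
#' @param x Numeric array of noiseless magnitudes.
#' @param sigma Per-channel Gaussian noise SD (a.u., >= 0). `sigma = 0`
#'   returns `x` unchanged.
#' @return Array of the same shape with Rician noise applied.
#' @export
add_rician_noise <- function(x, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(x)
  n <- length(x)
  out <- sqrt((x + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}
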