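#' Calcium transient parameters
#'
#' Parameters of the periodic intracellular Ca2+ transient that drives
#' ventricular contraction. The waveform is a normalized rise--decay pulse
#' repeated every basic cycle length (BCL). In the heart-failure phenotype
#' the peak amplitude of the transient is scaled down by
#' `hf_amplitude_factor` (0.3 reproduces the canonical 70% amplitude
#' reduction of failing myocardium); the diastolic level and time course
#' are unchanged.
#'
#' @param bcl_ms Basic cycle length (pacing period), ms. Default 600 ms.
#' @param ca_diastolic_uM Diastolic Ca2+ concentration, uM.
#' @param ca_amplitude_uM Normal peak-minus-diastolic amplitude, uM.
#' @param tau_rise_ms Rise time constant of the pulse, ms.
#' @param tau_decay_ms Decay time constant of the pulse, ms; must exceed
#'   `tau_rise_ms`.
#' @param hf_amplitude_factor Fraction in \[0, 1\] multiplying the amplitude;
#'   1 is a healthy transient, 0.3 the failing-heart default.
#'
#' @return An object of class `ca_params` (a named list, times in seconds).
#' @export
#' @examples
#' p <- ca_params()                          # failing-heart drive
#' healthy <- ca_params(hf_amplitude_factor = 1)
#' ca_transient(0.05, p)
ca_params <- function(bcl_ms = 600, ca_diastolic_uM = 0.1,
                      ca_amplitude_uM = 1.0, tau_rise_ms = 20,
                      tau_decay_ms = 150, hf_amplitude_factor = 0.3) {
  stopifnot(is.numeric(bcl_ms), length(bcl_ms) == 1L)
  if (bcl_ms <= 0) stop("bcl_ms must be positive")
  if (ca_diastolic_uM < 0) stop("ca_diastolic_uM must be non-negative")
  if (ca_amplitude_uM <= 0) stop("ca_amplitude_uM must be positive")
  if (tau_rise_ms <= 0 || tau_decay_ms <= 0)
    stop("time constants must be positive")
  if (tau_rise_ms >= tau_decay_ms)
    stop("tau_rise_ms must be smaller than tau_decay_ms")
  if (hf_amplitude_factor < 0 || hf_amplitude_factor > 1)
    stop("hf_amplitude_factor must lie in [0, 1]")
  p <- list(
    bcl = bcl_ms / 1000,
    ca_diastolic = ca_diastolic_uM,
    ca_amplitude = ca_amplitude_uM,
    tau_rise = tau_rise_ms / 1000,
    tau_decay = tau_decay_ms / 1000,
    hf_amplitude_factor = hf_amplitude_factor
  )
  # peak of the un-normalized pulse (1 - e^(-s/a)) e^(-s/b) is at
  # s* = a log(1 + b/a); normalize so the pulse peaks at exactly 1
  s_star <- p$tau_rise * log(1 + p$tau_decay / p$tau_rise)
  w_star <- (1 - exp(-s_star / p$tau_rise)) * exp(-s_star / p$tau_decay)
  p$pulse_norm <- 1 / w_star
  p$t_peak <- s_star
  class(p) <- "ca_params"
  p
}

#' Evaluate the intracellular calcium transient
#'
#' Periodic drive `ca(t) = ca_diastolic + a_eff * w(t mod bcl)` where `w` is
#' a normalized (peak = 1) rise--decay pulse and
#' `a_eff = ca_amplitude * hf_amplitude_factor`.
#'
#' @param t Time, seconds (scalar or vector); must be non-negative.
#' @param params A [ca_params()] object.
#' @return Ca2+ concentration in uM, same length as `t`. Never falls below
#'   the diastolic level; exactly periodic with period `bcl`.
#' @export
ca_transient <- function(t, params) {
  stopifnot(inherits(params, "ca_params"))
  if (any(t < 0)) stop("t must be non-negative")
  s <- t %% params$bcl
  w <- params$pulse_norm *
    (1 - exp(-s / params$tau_rise)) * exp(-s / params$tau_decay)
  a_eff <- params$ca_amplitude * params$hf_amplitude_factor
  params$ca_diastolic + a_eff * w
}

#' @export
print.ca_params <- function(x, ...) {
  cat(sprintf(
    "Ca2+ transient: BCL %g ms, diastolic %g uM, amplitude %g uM x %g,\n  tau_rise %g ms, tau_decay %g ms (peak at %.1f ms)\n",
    x$bcl * 1000, x$ca_diastolic, x$ca_amplitude, x$hf_amplitude_factor,
    x$tau_rise * 1000, x$tau_decay * 1000, x$t_peak * 1000))
  invisible(x)
}
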