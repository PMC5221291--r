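#' Ventricular chamber parameters
#'
#' 0D pressure--volume law of one ventricle. Passive (end-diastolic)
#' pressure follows an exponential EDPVR
#' `P_pas = passive_scale * beta * (exp(kappa (v - v0)) - 1)` for
#' `v >= v0`, continued linearly (slope matched at `v0`) below the
#' unstressed volume. Heart-failure remodeling stiffens the passive curve
#' by `passive_scale` (5 in the failing phenotype). Active pressure couples
#' the myofilament model through a cube-root volume-to-sarcomere-length map
#' and a Laplace-like `(v_ref/v)^(1/3)` radius attenuation.
#'
#' @param v0 Unstressed volume, mL.
#' @param beta Passive pressure scale, mmHg.
#' @param kappa Passive exponential constant, 1/mL.
#' @param passive_scale Dimensionless multiplier on the whole passive
#'   curve (>= 1); 5 for the failing heart, 1 for healthy myocardium.
#' @param sl_ref Sarcomere length at the reference volume, um.
#' @param v_ref Reference volume, mL.
#' @param p_act_gain Dimensionless gain mapping active tension (on the
#'   `t_max` scale) to chamber pressure in mmHg.
#'
#' @return An object of class `ventricle_params`.
#' @export
ventricle_params <- function(v0 = 25, beta = 0.2, kappa = 0.03,
                             passive_scale = 5, sl_ref = 2.2, v_ref = 100,
                             p_act_gain = 1.6188) {
  if (v0 <= 0) stop("v0 must be positive")
  if (beta <= 0 || kappa <= 0) stop("beta and kappa must be positive")
  if (passive_scale < 1) stop("passive_scale must be >= 1")
  if (sl_ref <= 0 || v_ref <= 0) stop("sl_ref and v_ref must be positive")
  if (p_act_gain <= 0) stop("p_act_gain must be positive")
  structure(list(v0 = v0, beta = beta, kappa = kappa,
                 passive_scale = passive_scale, sl_ref = sl_ref,
                 v_ref = v_ref, p_act_gain = p_act_gain),
            class = "ventricle_params")
}

#' Passive (end-diastolic) ventricular pressure
#'
#' @param v Volume, mL (positive; scalar or vector).
#' @param params A [ventricle_params()] object.
#' @return Pressure, mmHg. Zero at `v = v0`, strictly increasing in `v`,
#'   proportional to `passive_scale` at every volume.
#' @export
passive_pressure <- function(v, params) {
  stopifnot(inherits(params, "ventricle_params"))
  if (any(v <= 0)) stop("v must be positive")
  s <- params$passive_scale * params$beta
  ifelse(v >= params$v0,
         s * (exp(params$kappa * (v - params$v0)) - 1),
         s * params$kappa * (v - params$v0))
}

#' Sarcomere length from chamber volume
#'
#' Cube-root scaling of a quasi-spherical chamber:
#' `sl = sl_ref * (v / v_ref)^(1/3)`.
#'
#' @inheritParams passive_pressure
#' @return Sarcomere length, um; monotone increasing in `v`.
#' @export
sl_from_volume <- function(v, params) {
  stopifnot(inherits(params, "ventricle_params"))
  if (any(v <= 0)) stop("v must be positive")
  params$sl_ref * (v / params$v_ref)^(1 / 3)
}

#' Total ventricular pressure (passive + active)
#'
#' `P = P_pas(v) + p_act_gain * T_act(a, sl(v)) * (v_ref / v)^(1/3)`,
#' with the Laplace-like attenuation accounting for the larger radius of a
#' dilated chamber.
#'
#' @param v Volume, mL.
#' @param a Attached cross-bridge fraction.
#' @param vp A [ventricle_params()] object.
#' @param mp A [myo_params()] object.
#' @return Pressure, mmHg; equals the passive pressure when `a = 0`.
#' @export
ventricular_pressure <- function(v, a, vp, mp) {
  stopifnot(inherits(vp, "ventricle_params"))
  sl <- sl_from_volume(v, vp)
  passive_pressure(v, vp) +
    vp$p_act_gain * active_tension(a, sl, mp) * (vp$v_ref / v)^(1 / 3)
}

#' Linear compliance-chamber pressure
#'
#' `P = (v - v_unstressed) / c`, floored at zero: a collapsed vessel or
#' atrium exerts no negative transmural pressure.
#'
#' @param v Volume, mL.
#' @param c Compliance, mL/mmHg (positive).
#' @param v_unstressed Unstressed volume, mL.
#' @return Pressure, mmHg (non-negative).
#' @export
compliance_pressure <- function(v, c, v_unstressed) {
  if (any(c <= 0)) stop("compliance must be positive")
  pmax((v - v_unstressed) / c, 0)
}
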