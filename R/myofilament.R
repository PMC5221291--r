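#' Reduced cross-bridge (myofilament) model parameters
#'
#' A two-state cross-bridge scheme: a single attached fraction `a` with
#' Ca-gated attachment (`f_app` times a Hill function of Ca2+) and
#' first-order detachment (`g_xb`). Active tension is
#' `t_max * a * SOVF_thick(sl)` where `SOVF_thick` is the single-overlap
#' fraction of thick filaments, a piecewise-linear function of sarcomere
#' length built from the filament geometry. The ATP consumption rate is the
#' detachment flux weighted by the overlap fraction,
#' `E = g_xb * a * SOVF_thick(sl)` (one ATP per detachment cycle), reported
#' in 1/s.
#'
#' @param f_app Attachment rate constant, 1/s.
#' @param g_xb Detachment rate constant, 1/s.
#' @param ca50 Half-activation Ca2+ concentration of the Hill gate, uM.
#' @param hill_h Hill coefficient (>= 1) of Ca activation.
#' @param t_max Maximal active tension on the chamber pressure scale, mmHg.
#' @param len_thick,len_hbare,len_thin Thick-filament, bare-zone and
#'   thin-filament lengths, um (sarcomere geometry of the overlap function).
#'
#' @return An object of class `myo_params`.
#' @export
myo_params <- function(f_app = 60, g_xb = 15, ca50 = 0.5, hill_h = 4,
                       t_max = 140, len_thick = 1.65, len_hbare = 0.1,
                       len_thin = 1.2) {
  if (f_app <= 0 || g_xb <= 0) stop("rate constants must be positive")
  if (ca50 <= 0) stop("ca50 must be positive")
  if (hill_h < 1) stop("hill_h must be >= 1")
  if (t_max <= 0) stop("t_max must be positive")
  if (!(len_hbare > 0 && len_hbare < len_thick))
    stop("need 0 < len_hbare < len_thick")
  if (len_thin <= 0) stop("len_thin must be positive")
  structure(list(f_app = f_app, g_xb = g_xb, ca50 = ca50, hill_h = hill_h,
                 t_max = t_max, len_thick = len_thick,
                 len_hbare = len_hbare, len_thin = len_thin),
            class = "myo_params")
}

#' Single-overlap fraction of thick filaments
#'
#' Fraction of myosin heads apposed to single-overlapped actin, as a
#' piecewise-linear function of sarcomere length: with
#' `sovr_ze = min(len_thick/2, sl/2)` and
#' `sovr_cle = max(len_thin - sl/2, len_hbare/2)`,
#' `SOVF = 2 (sovr_ze - sovr_cle) / (len_thick - len_hbare)` clamped to
#' \[0, 1\].
#'
#' @param sl Sarcomere length, um (scalar or vector, positive).
#' @param params A [myo_params()] object.
#' @return Overlap fraction in \[0, 1\].
#' @export
#' @examples
#' sovf_thick(2.2, myo_params())   # 0.93548...
sovf_thick <- function(sl, params) {
  stopifnot(inherits(params, "myo_params"))
  if (any(sl <= 0)) stop("sl must be positive")
  sovr_ze <- pmin(params$len_thick / 2, sl / 2)
  sovr_cle <- pmax(params$len_thin - sl / 2, params$len_hbare / 2)
  f <- 2 * (sovr_ze - sovr_cle) / (params$len_thick - params$len_hbare)
  pmin(pmax(f, 0), 1)
}

#' Hill gate of calcium activation
#' @param ca Ca2+ concentration, uM (non-negative).
#' @param params A [myo_params()] object.
#' @return Activation in \[0, 1): `ca^h / (ca^h + ca50^h)`.
#' @export
ca_activation <- function(ca, params) {
  stopifnot(inherits(params, "myo_params"))
  if (any(ca < 0)) stop("ca must be non-negative")
  ch <- ca^params$hill_h
  ch / (ch + params$ca50^params$hill_h)
}

#' Cross-bridge kinetics right-hand side
#'
#' `da/dt = f_app * H(ca) * (1 - a) - g_xb * a` with `H` the Hill gate.
#' The vector field points inward at both bounds, so `a` stays in \[0, 1\]
#' along any trajectory driven by a non-negative Ca signal.
#'
#' @param a Attached cross-bridge fraction in \[0, 1\].
#' @param ca Ca2+ concentration, uM.
#' @param params A [myo_params()] object.
#' @return Rate of change of `a`, 1/s.
#' @export
xb_rhs <- function(a, ca, params) {
  stopifnot(inherits(params, "myo_params"))
  if (any(a < 0 | a > 1)) stop("a must lie in [0, 1]")
  params$f_app * ca_activation(ca, params) * (1 - a) - params$g_xb * a
}

#' Steady-state attached fraction under constant calcium
#'
#' Closed form `a_ss = f_app H / (f_app H + g_xb)`; the fixed point of
#' [xb_rhs()] at constant Ca.
#'
#' @inheritParams xb_rhs
#' @return Steady-state `a` in \[0, 1).
#' @export
xb_steady_state <- function(ca, params) {
  stopifnot(inherits(params, "myo_params"))
  fH <- params$f_app * ca_activation(ca, params)
  fH / (fH + params$g_xb)
}

#' Active tension of the reduced cross-bridge model
#'
#' `T_act = t_max * a * SOVF_thick(sl)`.
#'
#' @param a Attached cross-bridge fraction.
#' @param sl Sarcomere length, um.
#' @param params A [myo_params()] object.
#' @return Tension on the `t_max` scale (mmHg-equivalent), in
#'   \[0, `t_max`\].
#' @export
active_tension <- function(a, sl, params) {
  stopifnot(inherits(params, "myo_params"))
  if (any(a < 0 | a > 1)) stop("a must lie in [0, 1]")
  params$t_max * a * sovf_thick(sl, params)
}

#' Cross-bridge ATP consumption rate
#'
#' The detachment flux weighted by the thick-filament single-overlap
#' fraction: `E = g_xb * a * SOVF_thick(sl)`, in 1/s (cross-bridge cycles,
#' hence ATP molecules, per second per available head). Zero exactly when
#' no bridges are attached or there is no filament overlap.
#'
#' @inheritParams active_tension
#' @return ATP consumption rate, 1/s (non-negative).
#' @export
atp_rate <- function(a, sl, params) {
  stopifnot(inherits(params, "myo_params"))
  if (any(a < 0 | a > 1)) stop("a must lie in [0, 1]")
  params$g_xb * a * sovf_thick(sl, params)
}
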