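#' Mitral valve flow with regurgitant leak
#'
#' Diode law with a proportional leak: forward (LA to LV) flow
#' `(p_la - p_lv) / r_mi` when `p_la > p_lv`; otherwise the backward flux
#' is `sf/100` of the forward-law flux at the same pressure difference,
#' `(p_la - p_lv) / r_mi * sf / 100`. Both branches vanish at equal
#' pressures, so the law is continuous. `sf = 0` recovers a competent
#' one-way valve.
#'
#' @param p_la Left atrial pressure, mmHg.
#' @param p_lv Left ventricular pressure, mmHg.
#' @param r_mi Forward mitral resistance, mmHg.s/mL (positive).
#' @param sf Leak scale factor, percent in \[0, 100\].
#' @return Flow in mL/s; positive is LA to LV.
#' @export
#' @examples
#' mitral_flow(10, 4, 0.05, 5)    # forward: 120 mL/s
#' mitral_flow(8, 88, 0.05, 5)    # regurgitant: -80 mL/s
mitral_flow <- function(p_la, p_lv, r_mi, sf) {
  if (any(r_mi <= 0)) stop("r_mi must be positive")
  if (any(sf < 0 | sf > 100)) stop("sf must lie in [0, 100] percent")
  dp <- p_la - p_lv
  ifelse(dp > 0, dp / r_mi, dp / r_mi * sf / 100)
}

#' Aortic valve flow with regurgitant leak
#'
#' Mirror of [mitral_flow()] for the aortic valve: forward (LV to aorta)
#' flow `(p_lv - p_ao) / r_ao` when `p_lv > p_ao`; otherwise the leak
#' `(p_lv - p_ao) / r_ao * sf / 100`.
#'
#' @param p_lv Left ventricular pressure, mmHg.
#' @param p_ao Aortic (systemic arterial) pressure, mmHg.
#' @param r_ao Forward aortic resistance, mmHg.s/mL (positive).
#' @param sf Leak scale factor, percent in \[0, 100\].
#' @return Flow in mL/s; positive is LV to aorta.
#' @export
aortic_flow <- function(p_lv, p_ao, r_ao, sf) {
  if (any(r_ao <= 0)) stop("r_ao must be positive")
  if (any(sf < 0 | sf > 100)) stop("sf must lie in [0, 100] percent")
  dp <- p_lv - p_ao
  ifelse(dp > 0, dp / r_ao, dp / r_ao * sf / 100)
}

#' LVAD withdrawal and injection fluxes
#'
#' @param config An [lvad_config()] object.
#' @return Named vector `c(q_withdraw_la, q_withdraw_lv, q_inject_sa)` in
#'   mL/s; withdrawal always equals injection (the pump conserves volume).
#' @export
lvad_flows <- function(config) {
  stopifnot(inherits(config, "lvad_config"))
  q <- switch(config$mode,
              none = c(0, 0, 0),
              laao = c(config$flow, 0, config$flow),
              lvao = c(0, config$flow, config$flow),
              stop("unknown LVAD mode"))
  names(q) <- c("q_withdraw_la", "q_withdraw_lv", "q_inject_sa")
  q
}

# linear pump derating between suction_lo and suction_hi fractions of the
# inlet chamber's unstressed volume
.suction_factor <- function(v, vu, lo = 0.1, hi = 0.2) {
  pmin(pmax((v - lo * vu) / ((hi - lo) * vu), 0), 1)
}

#' Closed-loop network derivatives (reference implementation)
#'
#' Mass balance over the eight compartments plus the two cross-bridge
#' states: each compartment's `dV/dt` is the sum of its inflows minus its
#' outflows, with valve flows from the leaky-diode laws, linear resistive
#' flows between compliance compartments, the LVAD source terms, and
#' cross-bridge kinetics driven by the calcium transient. The volume
#' derivatives sum to zero analytically (closed loop; the pump moves
#' volume, it does not create it).
#'
#' This pure-R right-hand side is the reference for the compiled
#' derivatives used by [simulate_circulation()]; it is also usable
#' directly with [deSolve::ode()].
#'
#' @param t Time, s.
#' @param state Named state vector as from [initial_state()].
#' @param model A [cv_model()] object.
#' @return A list: derivatives of the state, followed by a named vector of
#'   auxiliary outputs (pressures, flows, pump flux, ATP consumption rate,
#'   calcium and LV sarcomere length).
#' @export
network_rhs <- function(t, state, model) {
  stopifnot(inherits(model, "cv_model"))
  if (any(!is.finite(state)))
    stop("non-finite state at t = ", t)
  if (any(state[1:8] <= 0))
    stop("non-positive compartment volume at t = ", t)
  ci <- model$circulation
  mp <- model$myofilament

  ca <- ca_transient(t, model$calcium)
  p_lv <- ventricular_pressure(state[["v_lv"]], state[["a_lv"]],
                               model$lv, mp)
  p_rv <- ventricular_pressure(state[["v_rv"]], state[["a_rv"]],
                               model$rv, mp)
  p_la <- compliance_pressure(state[["v_la"]], ci$c_la, ci$vu_la)
  p_ra <- compliance_pressure(state[["v_ra"]], ci$c_ra, ci$vu_ra)
  p_sa <- compliance_pressure(state[["v_sa"]], ci$c_sa, ci$vu_sa)
  p_sv <- compliance_pressure(state[["v_sv"]], ci$c_sv, ci$vu_sv)
  p_pa <- compliance_pressure(state[["v_pa"]], ci$c_pa, ci$vu_pa)
  p_pv <- compliance_pressure(state[["v_pv"]], ci$c_pv, ci$vu_pv)

  q_mi <- mitral_flow(p_la, p_lv, ci$r_mi, ci$sf_mi)
  q_ao <- aortic_flow(p_lv, p_sa, ci$r_ao, ci$sf_ao)
  q_tr <- mitral_flow(p_ra, p_rv, ci$r_tr, 0)   # competent tricuspid
  q_pu <- aortic_flow(p_rv, p_pa, ci$r_pu, 0)   # competent pulmonary
  q_sas <- (p_sa - p_sv) / ci$r_sa
  q_svs <- (p_sv - p_ra) / ci$r_sv
  q_pas <- (p_pa - p_pv) / ci$r_pa
  q_pvs <- (p_pv - p_la) / ci$r_pv

  lf <- lvad_flows(model$lvad)
  fac <- 1
  if (model$lvad$mode == "laao")
    fac <- .suction_factor(state[["v_la"]], ci$vu_la)
  if (model$lvad$mode == "lvao")
    fac <- .suction_factor(state[["v_lv"]], model$lv$v0)
  q_pump <- lf[["q_inject_sa"]] * fac
  q_la_out <- lf[["q_withdraw_la"]] * fac
  q_lv_out <- lf[["q_withdraw_lv"]] * fac

  d <- c(
    v_lv = q_mi - q_ao - q_lv_out,
    v_la = q_pvs - q_mi - q_la_out,
    v_rv = q_tr - q_pu,
    v_ra = q_svs - q_tr,
    v_sa = q_ao + q_pump - q_sas,
    v_sv = q_sas - q_svs,
    v_pa = q_pu - q_pas,
    v_pv = q_pas - q_pvs,
    a_lv = xb_rhs(state[["a_lv"]], ca, mp),
    a_rv = xb_rhs(state[["a_rv"]], ca, mp)
  )
  aux <- c(p_lv = p_lv, p_la = p_la, p_rv = p_rv, p_ra = p_ra,
           p_sa = p_sa, p_sv = p_sv, p_pa = p_pa, p_pv = p_pv,
           q_mi = q_mi, q_ao = q_ao, q_tr = q_tr, q_pu = q_pu,
           q_sas = q_sas, q_svs = q_svs, q_pas = q_pas, q_pvs = q_pvs,
           q_pump = q_pump,
           atp_lv = atp_rate(state[["a_lv"]],
                             sl_from_volume(state[["v_lv"]], model$lv), mp),
           ca = ca,
           sl_lv = sl_from_volume(state[["v_lv"]], model$lv))
  list(d, aux)
}
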