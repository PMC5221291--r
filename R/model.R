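#' Circulation network parameters
#'
#' Resistances, compliances and unstressed volumes of the closed-loop
#' network (flow topology RV -> pulmonary artery -> pulmonary vein -> LA ->
#' LV -> systemic artery -> systemic vein -> RA -> RV), plus the leak scale
#' factors of the mitral and aortic valves. Resistances are in mmHg.s/mL,
#' compliances in mL/mmHg, volumes in mL. Leak scale factors `sf_mi` and
#' `sf_ao` are percentages: the backward flux through a leaky valve equals
#' `sf/100` of the forward-law flux at the same pressure difference
#' (equivalently, a backward resistance of `R_forward * 100 / sf`).
#'
#' @param r_mi,r_ao,r_tr,r_pu Mitral, aortic, tricuspid and pulmonary
#'   valve resistances.
#' @param r_sa,r_sv,r_pa,r_pv Systemic artery/vein and pulmonary
#'   artery/vein resistances.
#' @param c_la,c_ra,c_sa,c_sv,c_pa,c_pv Compliances of the left/right
#'   atrium and the four vascular compartments.
#' @param vu_la,vu_ra,vu_sa,vu_sv,vu_pa,vu_pv Unstressed volumes of the
#'   compliance compartments.
#' @param sf_mi,sf_ao Leak scale factors, percent in \[0, 100\].
#' @return An object of class `circ_params`.
#' @export
circ_params <- function(r_mi = 0.05, r_ao = 0.03, r_tr = 0.04, r_pu = 0.04,
                        r_sa = 2.1, r_sv = 0.20, r_pa = 0.12, r_pv = 0.10,
                        c_la = 2.0, c_ra = 2.5, c_sa = 1.5, c_sv = 7,
                        c_pa = 1.2, c_pv = 3.5,
                        vu_la = 5, vu_ra = 5, vu_sa = 20, vu_sv = 50,
                        vu_pa = 8, vu_pv = 15,
                        sf_mi = 0, sf_ao = 0) {
  r <- c(r_mi = r_mi, r_ao = r_ao, r_tr = r_tr, r_pu = r_pu,
         r_sa = r_sa, r_sv = r_sv, r_pa = r_pa, r_pv = r_pv)
  cc <- c(c_la = c_la, c_ra = c_ra, c_sa = c_sa, c_sv = c_sv,
          c_pa = c_pa, c_pv = c_pv)
  vu <- c(vu_la = vu_la, vu_ra = vu_ra, vu_sa = vu_sa, vu_sv = vu_sv,
          vu_pa = vu_pa, vu_pv = vu_pv)
  if (any(r <= 0)) stop("all resistances must be positive")
  if (any(cc <= 0)) stop("all compliances must be positive")
  if (any(vu < 0)) stop("unstressed volumes must be non-negative")
  if (sf_mi < 0 || sf_mi > 100 || sf_ao < 0 || sf_ao > 100)
    stop("leak scale factors must lie in [0, 100] percent")
  structure(c(as.list(r), as.list(cc), as.list(vu),
              list(sf_mi = sf_mi, sf_ao = sf_ao)),
            class = "circ_params")
}

#' LVAD configuration
#'
#' The assist device is an ideal flow generator: a constant volumetric
#' flux withdrawn from the inlet chamber (left atrium for `laao`, left
#' ventricle for `lvao`) and injected into the systemic artery. A suction
#' guard derates the pump linearly to zero when the inlet chamber volume
#' falls below 20% of its unstressed volume, reaching zero at 10% (the
#' guard never engages under the shipped configurations; it exists to keep
#' extreme configurations physical).
#'
#' @param mode One of `"none"`, `"laao"`, `"lvao"`.
#' @param flow Pump flux, mL/s; forced to 0 when `mode = "none"`.
#' @return An object of class `lvad_config`.
#' @export
lvad_config <- function(mode = c("none", "laao", "lvao"), flow = 40) {
  mode <- match.arg(mode)
  if (!is.numeric(flow) || length(flow) != 1L || flow < 0)
    stop("flow must be a non-negative scalar (mL/s)")
  if (mode == "none") flow <- 0
  structure(list(mode = mode, flow = flow), class = "lvad_config")
}

#' Assemble a full closed-loop cardiovascular model
#'
#' Bundles the calcium drive, the myofilament model, both ventricles, the
#' circulation network, the LVAD configuration and the total blood volume
#' into one model object consumed by [simulate_circulation()],
#' [calibrate_baseline()] and [run_grid()]. Defaults describe the
#' calibrated failing canine-scale heart (stroke volume approximately
#' 20 mL at 20% ejection fraction; see [calibrate_baseline()]).
#'
#' @param calcium A [ca_params()] object.
#' @param myofilament A [myo_params()] object (shared by both ventricles).
#' @param lv,rv [ventricle_params()] for the left and right ventricle.
#' @param circulation A [circ_params()] object.
#' @param lvad An [lvad_config()] object.
#' @param v_total Total blood volume, mL; the initial compartment volumes
#'   are rescaled proportionally to sum to it.
#' @return An object of class `cv_model`.
#' @export
#' @examples
#' m <- cv_model()
#' m$lvad <- lvad_config("laao", 40)
cv_model <- function(calcium = ca_params(),
                     myofilament = myo_params(),
                     lv = ventricle_params(),
                     rv = ventricle_params(v0 = 20, beta = 0.1,
                                           kappa = 0.035, passive_scale = 5,
                                           sl_ref = 2.2, v_ref = 70,
                                           p_act_gain = 0.9),
                     circulation = circ_params(),
                     lvad = lvad_config(),
                     v_total = 570) {
  stopifnot(inherits(calcium, "ca_params"),
            inherits(myofilament, "myo_params"),
            inherits(lv, "ventricle_params"),
            inherits(rv, "ventricle_params"),
            inherits(circulation, "circ_params"),
            inherits(lvad, "lvad_config"))
  if (v_total <= 0) stop("v_total must be positive")
  structure(list(calcium = calcium, myofilament = myofilament,
                 lv = lv, rv = rv, circulation = circulation,
                 lvad = lvad, v_total = v_total),
            class = "cv_model")
}

#' @export
print.cv_model <- function(x, ...) {
  cat("Closed-loop cardiovascular model\n")
  cat(sprintf("  drive: BCL %g ms, Ca amplitude factor %g\n",
              x$calcium$bcl * 1000, x$calcium$hf_amplitude_factor))
  cat(sprintf("  LV: passive_scale %g, p_act_gain %.4g; RV: p_act_gain %.4g\n",
              x$lv$passive_scale, x$lv$p_act_gain, x$rv$p_act_gain))
  cat(sprintf("  leak: mitral %g%%, aortic %g%%; LVAD: %s",
              x$circulation$sf_mi, x$circulation$sf_ao, x$lvad$mode))
  if (x$lvad$mode != "none") cat(sprintf(" at %g mL/s", x$lvad$flow))
  cat(sprintf("\n  total blood volume %.4g mL\n", x$v_total))
  invisible(x)
}

# state variable names, fixed order shared with the compiled RHS
.state_names <- c("v_lv", "v_la", "v_rv", "v_ra", "v_sa", "v_sv",
                  "v_pa", "v_pv", "a_lv", "a_rv")

# auxiliary output names, fixed order shared with the compiled RHS
.aux_names <- c("p_lv", "p_la", "p_rv", "p_ra", "p_sa", "p_sv", "p_pa",
                "p_pv", "q_mi", "q_ao", "q_tr", "q_pu", "q_sas", "q_svs",
                "q_pas", "q_pvs", "q_pump", "atp_lv", "ca", "sl_lv")

#' Default initial state of the circulation
#'
#' A physiologically ordered volume distribution rescaled so that the
#' compartment volumes sum to the model's total blood volume; both
#' cross-bridge fractions start at 0 (diastole).
#'
#' @param model A [cv_model()] object.
#' @return Named numeric vector: eight compartment volumes (mL) and the
#'   two attached cross-bridge fractions.
#' @export
initial_state <- function(model) {
  stopifnot(inherits(model, "cv_model"))
  v <- c(v_lv = 100, v_la = 18, v_rv = 70, v_ra = 14,
         v_sa = 150, v_sv = 160, v_pa = 34, v_pv = 66)
  v <- v * model$v_total / sum(v)
  c(v, a_lv = 0, a_rv = 0)
}

# flatten a cv_model into the parameter vector expected by the compiled
# derivatives (order must match src/circ.c)
.parms_vector <- function(model) {
  ca <- model$calcium
  mp <- model$myofilament
  lv <- model$lv
  rv <- model$rv
  ci <- model$circulation
  mode_code <- match(model$lvad$mode, c("none", "laao", "lvao")) - 1
  c(bcl = ca$bcl, ca_dia = ca$ca_diastolic,
    ca_amp_eff = ca$ca_amplitude * ca$hf_amplitude_factor,
    tau_rise = ca$tau_rise, tau_decay = ca$tau_decay,
    pulse_norm = ca$pulse_norm,
    f_app = mp$f_app, g_xb = mp$g_xb, ca50 = mp$ca50, hill_h = mp$hill_h,
    t_max = mp$t_max, len_thick = mp$len_thick, len_hbare = mp$len_hbare,
    len_thin = mp$len_thin,
    lv_v0 = lv$v0, lv_beta = lv$beta, lv_kappa = lv$kappa,
    lv_scale = lv$passive_scale, lv_sl_ref = lv$sl_ref,
    lv_v_ref = lv$v_ref, lv_gain = lv$p_act_gain,
    rv_v0 = rv$v0, rv_beta = rv$beta, rv_kappa = rv$kappa,
    rv_scale = rv$passive_scale, rv_sl_ref = rv$sl_ref,
    rv_v_ref = rv$v_ref, rv_gain = rv$p_act_gain,
    r_mi = ci$r_mi, r_ao = ci$r_ao, r_tr = ci$r_tr, r_pu = ci$r_pu,
    r_sa = ci$r_sa, r_sv = ci$r_sv, r_pa = ci$r_pa, r_pv = ci$r_pv,
    c_la = ci$c_la, c_ra = ci$c_ra, c_sa = ci$c_sa, c_sv = ci$c_sv,
    c_pa = ci$c_pa, c_pv = ci$c_pv,
    vu_la = ci$vu_la, vu_ra = ci$vu_ra, vu_sa = ci$vu_sa,
    vu_sv = ci$vu_sv, vu_pa = ci$vu_pa, vu_pv = ci$vu_pv,
    sf_mi = ci$sf_mi, sf_ao = ci$sf_ao,
    lvad_mode = mode_code, lvad_flow = model$lvad$flow,
    suction_lo = 0.1, suction_hi = 0.2)
}
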