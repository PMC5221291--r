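/* Compiled right-hand side of the closed-loop circulation model for
 * deSolve. Mirrors the pure-R reference network_rhs() exactly; the R
 * version is the readable specification, this one is the fast path used
 * by simulate_circulation(). Parameter order must match .parms_vector()
 * in R/model.R; state order v_lv, v_la, v_rv, v_ra, v_sa, v_sv, v_pa,
 * v_pv, a_lv, a_rv; output order as .aux_names. */

#include <R.h>
#include <math.h>

#define N_PARMS 54

static double parms[N_PARMS];

enum {
  P_BCL, P_CA_DIA, P_CA_AMP_EFF, P_TAU_RISE, P_TAU_DECAY, P_PULSE_NORM,
  P_F_APP, P_G_XB, P_CA50, P_HILL_H, P_T_MAX, P_LEN_THICK, P_LEN_HBARE,
  P_LEN_THIN,
  P_LV_V0, P_LV_BETA, P_LV_KAPPA, P_LV_SCALE, P_LV_SL_REF, P_LV_V_REF,
  P_LV_GAIN,
  P_RV_V0, P_RV_BETA, P_RV_KAPPA, P_RV_SCALE, P_RV_SL_REF, P_RV_V_REF,
  P_RV_GAIN,
  P_R_MI, P_R_AO, P_R_TR, P_R_PU, P_R_SA, P_R_SV, P_R_PA, P_R_PV,
  P_C_LA, P_C_RA, P_C_SA, P_C_SV, P_C_PA, P_C_PV,
  P_VU_LA, P_VU_RA, P_VU_SA, P_VU_SV, P_VU_PA, P_VU_PV,
  P_SF_MI, P_SF_AO,
  P_LVAD_MODE, P_LVAD_FLOW, P_SUCTION_LO, P_SUCTION_HI
};

void circ_initmod(void (*odeparms)(int *, double *))
{
  int n = N_PARMS;
  odeparms(&n, parms);
}

static double ca_drive(double t)
{
  double s = fmod(t, parms[P_BCL]);
  double w = parms[P_PULSE_NORM] *
    (1.0 - exp(-s / parms[P_TAU_RISE])) * exp(-s / parms[P_TAU_DECAY]);
  return parms[P_CA_DIA] + parms[P_CA_AMP_EFF] * w;
}

static double sovf_thick_c(double sl)
{
  double ze = fmin(parms[P_LEN_THICK] / 2.0, sl / 2.0);
  double cle = fmax(parms[P_LEN_THIN] - sl / 2.0, parms[P_LEN_HBARE] / 2.0);
  double f = 2.0 * (ze - cle) / (parms[P_LEN_THICK] - parms[P_LEN_HBARE]);
  if (f < 0.0) f = 0.0;
  if (f > 1.0) f = 1.0;
  return f;
}

/* passive EDPVR with linear continuation below the unstressed volume */
static double passive_p(double v, double v0, double beta, double kappa,
                        double scale)
{
  double s = scale * beta;
  if (v >= v0)
    return s * (exp(kappa * (v - v0)) - 1.0);
  return s * kappa * (v - v0);
}

static double ventricle_p(double v, double a, double v0, double beta,
                          double kappa, double scale, double sl_ref,
                          double v_ref, double gain, double *sl_out)
{
  double sl = sl_ref * cbrt(v / v_ref);
  double t_act = parms[P_T_MAX] * a * sovf_thick_c(sl);
  if (sl_out) *sl_out = sl;
  return passive_p(v, v0, beta, kappa, scale) +
    gain * t_act * cbrt(v_ref / v);
}

static double compliance_p(double v, double c, double vu)
{
  double p = (v - vu) / c;
  return p > 0.0 ? p : 0.0;
}

static double diode(double dp, double r, double sf)
{
  return dp > 0.0 ? dp / r : dp / r * sf / 100.0;
}

static double suction_factor(double v, double vu)
{
  double lo = parms[P_SUCTION_LO] * vu, hi = parms[P_SUCTION_HI] * vu;
  double f = (v - lo) / (hi - lo);
  if (f < 0.0) f = 0.0;
  if (f > 1.0) f = 1.0;
  return f;
}

void circ_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
  if (ip[0] < 20) error("nout should be at least 20");

  double v_lv = y[0], v_la = y[1], v_rv = y[2], v_ra = y[3];
  double v_sa = y[4], v_sv = y[5], v_pa = y[6], v_pv = y[7];
  double a_lv = y[8], a_rv = y[9];

  double ca = ca_drive(*t);
  double sl_lv;
  double p_lv = ventricle_p(v_lv, a_lv, parms[P_LV_V0], parms[P_LV_BETA],
                            parms[P_LV_KAPPA], parms[P_LV_SCALE],
                            parms[P_LV_SL_REF], parms[P_LV_V_REF],
                            parms[P_LV_GAIN], &sl_lv);
  double p_rv = ventricle_p(v_rv, a_rv, parms[P_RV_V0], parms[P_RV_BETA],
                            parms[P_RV_KAPPA], parms[P_RV_SCALE],
                            parms[P_RV_SL_REF], parms[P_RV_V_REF],
                            parms[P_RV_GAIN], NULL);
  double p_la = compliance_p(v_la, parms[P_C_LA], parms[P_VU_LA]);
  double p_ra = compliance_p(v_ra, parms[P_C_RA], parms[P_VU_RA]);
  double p_sa = compliance_p(v_sa, parms[P_C_SA], parms[P_VU_SA]);
  double p_sv = compliance_p(v_sv, parms[P_C_SV], parms[P_VU_SV]);
  double p_pa = compliance_p(v_pa, parms[P_C_PA], parms[P_VU_PA]);
  double p_pv = compliance_p(v_pv, parms[P_C_PV], parms[P_VU_PV]);

  double q_mi = diode(p_la - p_lv, parms[P_R_MI], parms[P_SF_MI]);
  double q_ao = diode(p_lv - p_sa, parms[P_R_AO], parms[P_SF_AO]);
  double q_tr = diode(p_ra - p_rv, parms[P_R_TR], 0.0);
  double q_pu = diode(p_rv - p_pa, parms[P_R_PU], 0.0);
  double q_sas = (p_sa - p_sv) / parms[P_R_SA];
  double q_svs = (p_sv - p_ra) / parms[P_R_SV];
  double q_pas = (p_pa - p_pv) / parms[P_R_PA];
  double q_pvs = (p_pv - p_la) / parms[P_R_PV];

  int mode = (int) parms[P_LVAD_MODE];
  double q_pump = 0.0, q_la_out = 0.0, q_lv_out = 0.0;
  if (mode == 1) {               /* LAAO: inlet at the left atrium */
    q_pump = parms[P_LVAD_FLOW] * suction_factor(v_la, parms[P_VU_LA]);
    q_la_out = q_pump;
  } else if (mode == 2) {        /* LVAO: inlet at the left ventricle */
    q_pump = parms[P_LVAD_FLOW] * suction_factor(v_lv, parms[P_LV_V0]);
    q_lv_out = q_pump;
  }

  ydot[0] = q_mi - q_ao - q_lv_out;
  ydot[1] = q_pvs - q_mi - q_la_out;
  ydot[2] = q_tr - q_pu;
  ydot[3] = q_svs - q_tr;
  ydot[4] = q_ao + q_pump - q_sas;
  ydot[5] = q_sas - q_svs;
  ydot[6] = q_pu - q_pas;
  ydot[7] = q_pas - q_pvs;

  /* cross-bridge kinetics, Hill-gated attachment */
  double ch = pow(ca, parms[P_HILL_H]);
  double H = ch / (ch + pow(parms[P_CA50], parms[P_HILL_H]));
  ydot[8] = parms[P_F_APP] * H * (1.0 - a_lv) - parms[P_G_XB] * a_lv;
  ydot[9] = parms[P_F_APP] * H * (1.0 - a_rv) - parms[P_G_XB] * a_rv;

  yout[0] = p_lv;  yout[1] = p_la;  yout[2] = p_rv;  yout[3] = p_ra;
  yout[4] = p_sa;  yout[5] = p_sv;  yout[6] = p_pa;  yout[7] = p_pv;
  yout[8] = q_mi;  yout[9] = q_ao;  yout[10] = q_tr; yout[11] = q_pu;
  yout[12] = q_sas; yout[13] = q_svs; yout[14] = q_pas; yout[15] = q_pvs;
  yout[16] = q_pump;
  yout[17] = parms[P_G_XB] * a_lv * sovf_thick_c(sl_lv);
  yout[18] = ca;
  yout[19] = sl_lv;
}
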