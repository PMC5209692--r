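/* Compiled right-hand side of the whole-body PBPK system with the
 * four-compartment heart sub-model, in the deSolve compiled-model form.
 * Parameter and state layouts mirror pack_parms() / state_names() in R;
 * the R implementation pbpk_rhs() is the reference and the test suite
 * asserts the two trajectories agree.
 */
#include <R.h>
#include <R_ext/Rdynload.h>

#define NPAR 78
#define MAX_ENZ 12

static double par[NPAR];

/* parameter offsets (keep in step with pack_parms) */
#define V_ART  par[0]
#define V_VEN  par[1]
#define V_LU   par[2]
#define V_AD   par[3]
#define V_BO   par[4]
#define V_BR   par[5]
#define V_KI   par[6]
#define V_SP   par[7]
#define V_GU   par[8]
#define V_LI   par[9]
#define V_MU   par[10]
#define V_SK   par[11]
#define V_RE   par[12]
#define V_EPI  par[13]
#define V_MID  par[14]
#define V_ENDO par[15]
#define V_PF   par[16]
#define Q_CO   par[17]
#define Q_AD   par[18]
#define Q_BO   par[19]
#define Q_BR   par[20]
#define Q_KI   par[21]
#define Q_SP   par[22]
#define Q_GU   par[23]
#define Q_HA   par[24]
#define Q_LI   par[25]
#define Q_MU   par[26]
#define Q_SK   par[27]
#define Q_RE   par[28]
#define Q_MURAL par[29]
#define Q_PF   par[30]
#define KP_LU  par[31]
#define KP_AD  par[32]
#define KP_BO  par[33]
#define KP_BR  par[34]
#define KP_KI  par[35]
#define KP_SP  par[36]
#define KP_GU  par[37]
#define KP_LI  par[38]
#define KP_MU  par[39]
#define KP_SK  par[40]
#define KP_RE  par[41]
#define KP_EPI par[42]
#define KP_MID par[43]
#define KP_ENDO par[44]
#define KP_PF  par[45]
#define FU_PF  par[46]
#define FU_H   par[47]
#define K_A    par[48]
#define P_DIFF par[49]
#define CL_REN par[50]
#define CL_CARD par[51]
#define INFUSION par[52]
#define N_ENZ  par[53]
#define VMAX(i) par[54 + (i)]
#define KM(i)   par[66 + (i)]

void pbpk_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, par);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double c_art = y[1] / V_ART;
    const double c_ven = y[2] / V_VEN;
    const double cv_lu  = y[3] / V_LU  / KP_LU;
    const double cv_ad  = y[4] / V_AD  / KP_AD;
    const double cv_bo  = y[5] / V_BO  / KP_BO;
    const double cv_br  = y[6] / V_BR  / KP_BR;
    const double cv_ki  = y[7] / V_KI  / KP_KI;
    const double cv_sp  = y[8] / V_SP  / KP_SP;
    const double cv_gu  = y[9] / V_GU  / KP_GU;
    const double cv_li  = y[10] / V_LI / KP_LI;
    const double cv_mu  = y[11] / V_MU / KP_MU;
    const double cv_sk  = y[12] / V_SK / KP_SK;
    const double cv_re  = y[13] / V_RE / KP_RE;
    const double cv_epi = y[14] / V_EPI / KP_EPI;
    const double cv_mid = y[15] / V_MID / KP_MID;
    const double cv_endo = y[16] / V_ENDO / KP_ENDO;
    const double cv_pf  = y[17] / V_PF / KP_PF;

    const double absorbed = K_A * y[0];

    const double cu_li = FU_H * y[10] / V_LI;
    const int n_enz = (int) N_ENZ;
    double r_hep = 0.0;
    for (int i = 0; i < n_enz; i++)
        r_hep += VMAX(i) * cu_li / (KM(i) + cu_li);
    const double r_ren = CL_REN * y[7] / V_KI / KP_KI;

    const double cl3 = CL_CARD / 3.0;
    const double e_epi = cl3 * cv_epi;
    const double e_mid = cl3 * cv_mid;
    const double e_endo = cl3 * cv_endo;
    const double j_pf = P_DIFF * (y[14] / V_EPI - FU_PF * y[17] / V_PF);

    const double q_out_art = Q_AD + Q_BO + Q_BR + Q_KI + Q_SP + Q_GU +
        Q_HA + Q_MU + Q_SK + Q_RE + Q_MURAL + Q_PF;

    ydot[0] = -absorbed;
    ydot[1] = Q_CO * cv_lu - q_out_art * c_art;
    ydot[2] = Q_AD * cv_ad + Q_BO * cv_bo + Q_BR * cv_br + Q_KI * cv_ki +
        Q_LI * cv_li + Q_MU * cv_mu + Q_SK * cv_sk + Q_RE * cv_re +
        Q_MURAL * cv_endo + Q_PF * cv_pf - Q_CO * c_ven + INFUSION;
    ydot[3] = Q_CO * (c_ven - cv_lu);
    ydot[4] = Q_AD * (c_art - cv_ad);
    ydot[5] = Q_BO * (c_art - cv_bo);
    ydot[6] = Q_BR * (c_art - cv_br);
    ydot[7] = Q_KI * (c_art - cv_ki) - r_ren;
    ydot[8] = Q_SP * (c_art - cv_sp);
    ydot[9] = Q_GU * (c_art - cv_gu) + absorbed;
    ydot[10] = Q_HA * c_art + Q_SP * cv_sp + Q_GU * cv_gu -
        Q_LI * cv_li - r_hep;
    ydot[11] = Q_MU * (c_art - cv_mu);
    ydot[12] = Q_SK * (c_art - cv_sk);
    ydot[13] = Q_RE * (c_art - cv_re);
    ydot[14] = Q_MURAL * (c_art - cv_epi) - j_pf - e_epi;
    ydot[15] = Q_MURAL * (cv_epi - cv_mid) - e_mid;
    ydot[16] = Q_MURAL * (cv_mid - cv_endo) - e_endo;
    ydot[17] = Q_PF * (c_art - cv_pf) + j_pf;
    ydot[18] = r_hep;
    ydot[19] = r_ren;
    ydot[20] = e_epi + e_mid + e_endo;
}
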