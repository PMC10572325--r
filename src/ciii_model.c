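/* Right-hand side of the CIII cold-sensing neuron model, in the form
 * expected by deSolve's compiled-code interface.  Temperature (Kelvin)
 * enters as forcing function number 1.
 *
 * State vector (11 elements, fixed order shared with R/model.R):
 *   Vm, m_Na, h_Na, m_K, m_Ca, h_Ca, m_BK, f_SK, Ca_i, m_TRP, h_TRP
 * In leak (level-I) TRP mode the two TRP gates are carried but frozen.
 *
 * Units: mV, s, nS, pA, nF, nM, pL, K.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPARMS 60
static double p[NPARMS];
static double forc[1];

/* parameter slots -- order is defined once in R/model.R (pack_parms) */
#define CM        p[0]
#define G_NA      p[1]
#define G_K       p[2]
#define G_CA      p[3]
#define G_BK      p[4]
#define G_SK      p[5]
#define G_L       p[6]
#define E_NA      p[7]
#define E_K       p[8]
#define E_L       p[9]
#define VM_NA     p[10]
#define KM_NA     p[11]
#define VH_NA     p[12]
#define KH_NA     p[13]
#define VM_K      p[14]
#define KM_K      p[15]
#define VM_CA     p[16]
#define KM_CA     p[17]
#define VH_CA     p[18]
#define KH_CA     p[19]
#define VM_BK     p[20]
#define KM_BK     p[21]
#define CA_BK     p[22]
#define N_BK      p[23]
#define CA_SK     p[24]
#define N_SK      p[25]
#define TAU_MNA   p[26]
#define TAU_MCA   p[27]
#define TAU_HCA   p[28]
#define TAU_MSK   p[29]
#define FARADAY   p[30]
#define RGAS      p[31]
#define ZCA       p[32]
#define VOL       p[33]
#define K_CA      p[34]
#define CA_MIN    p[35]
#define CA_E      p[36]
#define T0REF     p[37]
#define RHO_BASE  p[38]
#define PHI_BASE  p[39]
#define TAU_CONV  p[40]  /* 0 literal, 1 centered, 2 magnitude */
#define TRP_MODE  p[41]  /* 0 leak, 1 dynamic */
#define G_LTRP    p[42]
#define G_TRP_MAX p[43]
#define A_TRP     p[44]
#define B_TRP     p[45]
#define TH_TRP    p[46]
#define N_TRP     p[47]
#define CA_H      p[48]
#define TAU_MTRP  p[49]
#define TAU_HTRP  p[50]
#define P_K       p[51]
#define P_CA      p[52]
#define P_NA      p[53]
#define E_K_FIX   p[54]
#define E_NA_FIX  p[55]
#define E_CA_STAR p[56]
#define ORIENT    p[57]  /* 0 cold-activated, 1 warm (literal print) */
#define ETRP_MODE p[58]  /* 0 dynamic E_Ca, 1 literal constant */
#define TAU_PROFILE p[59] /* 0 sech (bell), 1 cosh (literal) */

void ciii_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, p);
}

void ciii_initforc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

void ciii_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double Tk = forc[0];
    double vm  = y[0];
    double mNa = y[1], hNa = y[2], mK = y[3];
    double mCa = y[4], hCa = y[5], mBK = y[6], fSK = y[7];
    double ca  = (y[8] > 1e-9) ? y[8] : 1e-9;
    double mTRP = y[9], hTRP = y[10];

    double rho = pow(RHO_BASE, (Tk - T0REF) / 10.0);
    double phi = pow(PHI_BASE, (Tk - T0REF) / 10.0);

    double eca = 1000.0 * RGAS * Tk / (ZCA * FARADAY) * log(CA_E / ca);

    double mNa_inf = 1.0 / (1.0 + exp(-(vm - VM_NA) / KM_NA));
    double hNa_inf = 1.0 / (1.0 + exp( (vm - VH_NA) / KH_NA));
    double mK_inf  = 1.0 / (1.0 + exp(-(vm - VM_K ) / KM_K ));
    double mCa_inf = 1.0 / (1.0 + exp(-(vm - VM_CA) / KM_CA));
    double hCa_inf = 1.0 / (1.0 + exp( (vm - VH_CA) / KH_CA));
    double mBK_inf = 1.0 / (1.0 + exp(-(vm - VM_BK) / KM_BK));
    double fSK_inf = 1.0 / (1.0 + pow(CA_SK / ca, N_SK));
    double fCaBK   = 1.0 / (1.0 + pow(CA_BK / ca, N_BK));

    double tau_mBK = -0.15021 / (1.0 + exp(-(vm + 46.0) / 22.7)) + 0.1806;
    double chNa, cmK;
    if (TAU_CONV < 0.5) {            /* literal: Vm + printed signed value */
        chNa = vm + VH_NA;  cmK = vm + VM_K;
    } else if (TAU_CONV < 1.5) {     /* centered: Vm - Vhalf */
        chNa = vm - VH_NA;  cmK = vm - VM_K;
    } else {                         /* magnitude: Vm + |Vhalf| */
        chNa = vm + fabs(VH_NA);  cmK = vm + fabs(VM_K);
    }
    double tau_hNa, tau_mK;
    if (TAU_PROFILE < 0.5) {     /* bell-shaped: fast away from the center */
        tau_hNa = (4.5 / cosh(chNa / (3.0 * KH_NA)) + 0.75) / 1000.0;
        tau_mK  = (5.0 / cosh(cmK  / (2.0 * KM_K )) + 0.75) / 1000.0;
    } else {                     /* literal print */
        tau_hNa = (4.5 * cosh(chNa / (3.0 * KH_NA)) + 0.75) / 1000.0;
        tau_mK  = (5.0 * cosh(cmK  / (2.0 * KM_K )) + 0.75) / 1000.0;
    }

    double psum = P_K + P_NA + P_CA;
    double etrp_ca = (ETRP_MODE < 0.5) ? eca : E_CA_STAR;
    double etrp = (P_K * E_K_FIX + P_NA * E_NA_FIX + P_CA * etrp_ca) / psum;

    double gtrp, dmTRP = 0.0, dhTRP = 0.0;
    if (TRP_MODE < 0.5) {
        gtrp = G_LTRP;
    } else {
        double s = (ORIENT < 0.5) ? 1.0 : -1.0;
        double mTRP_inf = B_TRP / (1.0 + exp(s * A_TRP * (Tk - TH_TRP)));
        double hTRP_inf = 1.0 / (1.0 + pow(ca / CA_H, N_TRP));
        /* TRP gate kinetics are not phi(T)-scaled */
        dmTRP = (mTRP_inf - mTRP) / TAU_MTRP;
        dhTRP = (hTRP_inf - hTRP) / TAU_HTRP;
        gtrp = G_TRP_MAX * mTRP * hTRP;
    }

    double INa = rho * G_NA * mNa * mNa * mNa * hNa * (vm - E_NA);
    double IK  = rho * G_K  * mK * mK * mK * mK * (vm - E_K);
    double ICa = rho * G_CA * mCa * hCa * (vm - eca);
    double IBK = rho * G_BK * fCaBK * mBK * mBK * mBK * mBK * (vm - E_K);
    double ISK = rho * G_SK * fSK * (vm - E_K);
    double IL  = rho * G_L  * (vm - E_L);
    /* the TRP current itself carries no rho(T) factor */
    double ITRP   = gtrp * (vm - etrp);
    double ITRPCa = gtrp * (P_CA / psum) * (vm - eca);

    ydot[0]  = -(INa + IK + ICa + IBK + ISK + IL + ITRP) / CM;
    ydot[1]  = phi * (mNa_inf - mNa) / TAU_MNA;
    ydot[2]  = phi * (hNa_inf - hNa) / tau_hNa;
    ydot[3]  = phi * (mK_inf  - mK ) / tau_mK;
    ydot[4]  = phi * (mCa_inf - mCa) / TAU_MCA;
    ydot[5]  = phi * (hCa_inf - hCa) / TAU_HCA;
    ydot[6]  = phi * (mBK_inf - mBK) / tau_mBK;
    ydot[7]  = phi * (fSK_inf - fSK) / TAU_MSK;
    ydot[8]  = -(ICa + ITRPCa) / (FARADAY * ZCA * VOL) - K_CA * (y[8] - CA_MIN);
    ydot[9]  = dmTRP;
    ydot[10] = dhTRP;

    if (*ip >= 12) {
        yout[0]  = INa;
        yout[1]  = IK;
        yout[2]  = ICa;
        yout[3]  = IBK;
        yout[4]  = ISK;
        yout[5]  = IL;
        yout[6]  = ITRP;
        yout[7]  = ITRPCa;
        yout[8]  = eca;
        yout[9]  = etrp;
        yout[10] = gtrp;
        yout[11] = Tk;
    }
}

static const R_CMethodDef cMethods[] = {
    {"ciii_initmod",  (DL_FUNC) &ciii_initmod,  1},
    {"ciii_initforc", (DL_FUNC) &ciii_initforc, 1},
    {"ciii_derivs",   (DL_FUNC) &ciii_derivs,   6},
    {NULL, NULL, 0}
};

void R_init_coldburst(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
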