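/* Compiled right-hand side of the tumor--immune--drug ODE system.
 *
 * State layout (length 5*(m+1) + 4):
 *   y[0 .. 5*(m+1)-1]  T-cell grid, column-major: y[i + 5*j] is
 *                      compartment i (0 SCM, 1 CM, 2 EM, 3 EFF, 4 EXH)
 *                      at senescence level j = 0..m
 *   then D_act, D_m, C (tumor cells), P (drug mg/L).
 *
 * Must stay numerically identical to rhs_flat() in R/model.R; the test
 * suite checks agreement on random states.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 36

static double parms[N_PARMS];

#define P_M        ((int) parms[0])
#define P_pC       parms[1]
#define P_kE0      parms[2]
#define P_rhoD     parms[3]
#define P_kC03     parms[4]
#define P_kC04     parms[5]
#define P_a(i)     parms[6 + (i)]      /* i = 0..3 */
#define P_pdiv(i)  parms[10 + (i)]     /* i = 0..3 */
#define P_mu(i)    parms[14 + (i)]     /* i = 0..4 */
#define P_sigmaN   parms[19]
#define P_smax     parms[20]
#define P_KD       parms[21]
#define P_KB       parms[22]
#define P_KCdc     parms[23]
#define P_mDC      parms[24]
#define P_dact     parms[25]
#define P_dm       parms[26]
#define P_KPD      parms[27]
#define P_epsKill  parms[28]
#define P_epsDiv   parms[29]
#define P_phiEM    parms[30]
#define P_Kkill    parms[31]
#define P_thalf    parms[32]
#define P_EC50     parms[33]
#define P_drugOff  (parms[34] != 0.0)
#define P_killOff  (parms[35] != 0.0)

void icisim_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void icisim_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const int m = P_M;
    const int ncol = m + 1;
    const int nt = 5 * ncol;
    const double Dact = y[nt], Dm = y[nt + 1];
    const double C = y[nt + 2] > 0 ? y[nt + 2] : 0.0;
    const double Pdrug = y[nt + 3];

    const double B = P_drugOff ? 0.0 : Pdrug / (Pdrug + P_EC50);
    const double csat = C / (C + P_KPD);
    const double boost = 1.0 + P_smax * Dm / (P_KB + Dm);

    double a[5] = {P_a(0), P_a(1), P_a(2), P_a(3), 0.0};

    for (int k = 0; k < *neq; k++) ydot[k] = 0.0;

    double sum_em = 0.0, sum_eff = 0.0, wsum = 0.0;

    for (int j = 0; j <= m; j++) {
        const double g = ((double) j / m) * csat * (1.0 - B);
        const double imp = 1.0 - P_epsDiv * g;
        double r[5];
        r[0] = P_pdiv(0) * boost;
        r[1] = P_pdiv(1) * boost;
        r[2] = P_pdiv(2) * imp;
        r[3] = P_pdiv(3) * imp;
        r[4] = 0.0;
        if (j == m) r[0] = r[1] = r[2] = r[3] = 0.0;

        for (int i = 0; i < 5; i++) {
            const double Tij = y[i + 5 * j];
            const double flux = r[i] * Tij;
            ydot[i + 5 * j] -= flux + P_mu(i) * Tij;
            if (j < m) {
                /* both daughters advance one senescence step */
                ydot[i + 5 * (j + 1)] += 2.0 * a[i] * flux;
                if (i < 4)
                    ydot[(i + 1) + 5 * (j + 1)] += 2.0 * (1.0 - a[i]) * flux;
            }
        }
        const double Tem = y[2 + 5 * j], Teff = y[3 + 5 * j];
        ydot[2 + 5 * j] -= P_kC03 * g * Tem;
        ydot[3 + 5 * j] -= P_kC04 * g * Teff;
        sum_em += Tem;
        sum_eff += Teff;
        wsum += (double) j * (Tem + Teff);
    }

    /* naive activation influx into (SCM, 0) */
    ydot[0] += P_sigmaN * Dm / (P_KD + Dm);

    /* tumor: power-law growth minus saturating kill by EM/EFF */
    double kill = 0.0;
    if (!P_killOff) {
        const double pool = sum_eff + P_phiEM * sum_em;
        if (pool > 0.0) {
            const double wj = wsum / (sum_em + sum_eff);
            const double ghat = (wj / m) * csat * (1.0 - B);
            kill = C / (C + P_Kkill) * (1.0 - P_epsKill * ghat)
                   * P_kE0 * pool;
        }
    }
    ydot[nt + 2] = P_pC * pow(C, 2.0 / 3.0) - kill;

    ydot[nt]     = P_rhoD * C / (C + P_KCdc) - (P_mDC + P_dact) * Dact;
    ydot[nt + 1] = P_mDC * Dact - P_dm * Dm;
    ydot[nt + 3] = -(M_LN2 / P_thalf) * Pdrug;
}

static const R_CMethodDef cMethods[] = {
    {"icisim_derivs", (DL_FUNC) &icisim_derivs, 6},
    {"icisim_initmod", (DL_FUNC) &icisim_initmod, 0},
    {NULL, NULL, 0}
};

void R_init_icisim(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
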