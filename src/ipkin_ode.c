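/* Right-hand side of the IP insulin absorption + whole-body kinetics ODEs,
 * in the deSolve compiled-model convention (initfunc / initforc / derivs).
 *
 * States: y[0] Qip1 (mU), y[1] Qip2 (mU), y[2] Qp (mU), y[3] Ql (mU),
 *         y[4] cumulative RaI (mU, audit integral).
 * One forcing: plasma glucose G(t) (mg/dL), linearly interpolated by deSolve.
 * Units: mU, min, L, mg/dL throughout.
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[16];
#define ABSV   parms[0]   /* absorption variant: 1, 2, 3        */
#define HEV    parms[1]   /* HE variant: 1 = A, 2 = B, 3 = C    */
#define KA1    parms[2]
#define KA2    parms[3]
#define KD     parms[4]
#define M1     parms[5]
#define M2     parms[6]
#define M4     parms[7]
#define HEB    parms[8]
#define AI     parms[9]
#define AG     parms[10]
#define GB     parms[11]
#define QLB    parms[12]
#define HEMIN  parms[13]
#define HEMAX  parms[14]
#define INF    parms[15]  /* infusion rate on the current segment (mU/min) */

static double forc[1];
#define GLUC forc[0]

void ipk_init(void (*odeparms)(int *, double *))
{
    int n = 16;
    odeparms(&n, parms);
}

void ipk_forc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

void ipk_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double rai, dq1, dq2, he, m3;
    int av = (int) ABSV, hv = (int) HEV;

    if (av == 1) {                       /* one IP compartment */
        rai = KA1 * y[0];
        dq1 = -KA1 * y[0] + INF;
        dq2 = 0.0;
    } else if (av == 2) {                /* two IP compartments, distal exit */
        rai = KA2 * y[1];
        dq1 = -KD * y[0] + INF;
        dq2 = -KA2 * y[1] + KD * y[0];
    } else {                             /* two IP compartments, both exits */
        rai = KA1 * y[0] + KA2 * y[1];
        dq1 = -(KA1 + KA2) * y[0] + INF;
        dq2 = -KA2 * y[1] + KA2 * y[0];
    }

    if (hv == 1)
        he = HEB;
    else if (hv == 2)
        he = -AG * (GLUC - GB) + HEB;
    else
        he = -AI * (y[3] - QLB) + HEB;
    if (he < HEMIN) he = HEMIN;
    if (he > HEMAX) he = HEMAX;
    m3 = he / (1.0 - he) * M1;

    ydot[0] = dq1;
    ydot[1] = dq2;
    ydot[2] = -(M2 + M4) * y[2] + M1 * y[3];
    ydot[3] = -(M1 + m3) * y[3] + M2 * y[2] + rai;
    ydot[4] = rai;

    if (*ip >= 2) {
        yout[0] = rai;
        yout[1] = he;
    }
}

static const R_CMethodDef cMethods[] = {
    {"ipk_init",   (DL_FUNC) &ipk_init,   1},
    {"ipk_forc",   (DL_FUNC) &ipk_forc,   1},
    {"ipk_derivs", (DL_FUNC) &ipk_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_ipkin(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
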