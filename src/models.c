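/* Compiled right-hand sides for the built-in kinetic models, in the deSolve
 * compiled-model convention (initfunc fills the static parameter block,
 * derivs is called by the integrator).  The exported R functions p53_rhs()
 * and arginine_rhs() are the reference implementations; these must agree
 * with them exactly. */

#include <R.h>
#include <R_ext/Rdynload.h>

/* ---------------- p53-Mdm2 negative feedback loop -------------------- */
/* states: A nuclear p53, B Mdm2, C p53-Mdm2 complex, D Mdm2 mRNA
 * k1 p53 production        k2 p53 degradation
 * k3 complex formation     k4 complex dissociation/diffusion
 * k5 Mdm2 degradation      k6 Mdm2 translation
 * k7 Mdm2-mediated p53 degradation (via the complex, releases Mdm2)
 * k8 Mdm2 transcription    k9 Mdm2 mRNA degradation */

static double p53_k[9];

void p53_initmod(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, p53_k);
}

void p53_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double *k = p53_k;
    double A = y[0], B = y[1], C = y[2], D = y[3];
    double form = k[2] * A * B;       /* complex formation flux */

    ydot[0] = k[0] - k[1] * A - form + k[3] * C;
    ydot[1] = k[5] * D - form + k[3] * C + k[6] * C - k[4] * B;
    ydot[2] = form - k[3] * C - k[6] * C;
    ydot[3] = k[7] * A - k[8] * D;
}

/* ---------------- arginine catabolism pathway ------------------------- */
/* states: A external arginine, B ornithine, C internal arginine.
 * Saturable fluxes (Michaelis-Menten-type):
 *  uptake   k1*A / (k2 + A + k7*B)   carrier uptake, ornithine competition
 *  arg II   k3*C / (k4 + C)          arginase II
 *  NOS      k5*C / (k6 + C)          nitric-oxide synthase
 *  ODC      k8*B / (k9 + B)          ornithine decarboxylase
 *  OAT      k11*B / (k12 + B)        ornithine aminotransferase
 *  efflux   k13*C / (k14 + C)        carrier efflux of arginine
 *  arg I    k15*C / (k16 + C)        arginase I
 * plus a first-order protein-synthesis drain k10*C. */

static double arg_k[16];

void arginine_initmod(void (*odeparms)(int *, double *))
{
    int n = 16;
    odeparms(&n, arg_k);
}

/* zero numerator short-circuits so that an all-zero parameter vector gives
 * zero flux even when the denominator is also zero */
static double sat_rate(double vmax, double s, double km, double inhib)
{
    double num = vmax * s;
    if (num == 0.0)
        return 0.0;
    return num / (km + s + inhib);
}

void arginine_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double *k = arg_k;
    double A = y[0], B = y[1], C = y[2];

    double v_up  = sat_rate(k[0],  A, k[1],  k[6] * B);
    double v_as2 = sat_rate(k[2],  C, k[3],  0.0);
    double v_nos = sat_rate(k[4],  C, k[5],  0.0);
    double v_odc = sat_rate(k[7],  B, k[8],  0.0);
    double v_oat = sat_rate(k[10], B, k[11], 0.0);
    double v_ef  = sat_rate(k[12], C, k[13], 0.0);
    double v_as1 = sat_rate(k[14], C, k[15], 0.0);

    ydot[0] = v_ef - v_up;
    ydot[1] = v_as1 + v_as2 - v_odc - v_oat;
    ydot[2] = v_up - v_ef - v_as1 - v_as2 - v_nos - k[9] * C;
}

/* ---------------- registration ---------------------------------------- */

static const R_CMethodDef cMethods[] = {
    {"p53_initmod",      (DL_FUNC) &p53_initmod,      1},
    {"p53_derivs",       (DL_FUNC) &p53_derivs,       6},
    {"arginine_initmod", (DL_FUNC) &arginine_initmod, 1},
    {"arginine_derivs",  (DL_FUNC) &arginine_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_fireflyde(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
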