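/* Six-compartment receptor-saturable kinetics.
 *
 * States (nmol):
 *   y[0] A1 blood, y[1] A2 spleen, y[2] A3 kidney, y[3] A4 tumor,
 *   y[4] A5 other SSTR organs, y[5] A6 rest,
 *   y[6] cumulative renal excretion, y[7] cumulative degradation.
 *
 * Uptake into compartments 2..5 saturates against a maximal binding
 * amount B_x; compartment 6 is non-saturable.  All rate constants are
 * 1/h; k12/k14 are passed already covariate-adjusted and eta-adjusted.
 * A non-finite B_x disables saturation for that compartment.
 */
#include <R.h>

static double parms[18];
#define K10  parms[0]
#define K12  parms[1]
#define K13  parms[2]
#define K14  parms[3]
#define K15  parms[4]
#define K16  parms[5]
#define K20  parms[6]
#define K30  parms[7]
#define K40  parms[8]
#define K50  parms[9]
#define K60  parms[10]
#define FU   parms[11]
#define B2   parms[12]
#define B3   parms[13]
#define B4   parms[14]
#define B5   parms[15]
#define INFRATE parms[16]
#define INFDUR  parms[17]

void theranopk_initmod(void (*odeparms)(int *, double *))
{
    int n = 18;
    odeparms(&n, parms);
}

static double free_frac(double a, double b)
{
    if (!R_FINITE(b)) return 1.0;   /* saturation disabled */
    return 1.0 - a / b;
}

void theranopk_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double a1 = y[0];
    double u2 = FU * K12 * a1 * free_frac(y[1], B2);
    double u3 = FU * K13 * a1 * free_frac(y[2], B3);
    double u4 = FU * K14 * a1 * free_frac(y[3], B4);
    double u5 = FU * K15 * a1 * free_frac(y[4], B5);
    double u6 = FU * K16 * a1;
    double inf = (INFDUR > 0.0 && *t < INFDUR) ? INFRATE : 0.0;

    ydot[0] = inf - K10 * a1 - u2 - u3 - u4 - u5 - u6;
    ydot[1] = u2 - K20 * y[1];
    ydot[2] = u3 - K30 * y[2];
    ydot[3] = u4 - K40 * y[3];
    ydot[4] = u5 - K50 * y[4];
    ydot[5] = u6 - K60 * y[5];
    ydot[6] = K10 * a1;
    ydot[7] = K20 * y[1] + K30 * y[2] + K40 * y[3] + K50 * y[4] + K60 * y[5];
}
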