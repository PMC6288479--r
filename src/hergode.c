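/* Four-state hERG Markov gating model: state y = (O, C, IO), IC = 1 - O - C - IO.
 *
 * Compiled right-hand side for deSolve. The integrator is restarted at every
 * protocol segment boundary, so each solve sees exactly one segment, described
 * in the parameter vector:
 *
 *   parms[0..7]  kO1, kO2, kC1, kC2, kI1, kI2, kA1, kA2   (ms^-1 / mV^-1)
 *   parms[8]     segment kind: 1 = hold, 2 = ramp, 3 = sine
 *   parms[9..12] kind-specific:
 *                  hold: q1 = v (mV)
 *                  ramp: q1 = vStart, q2 = vEnd, q3 = duration (ms)
 *                  sine: q1 = vOffset, q2 = amplitude, q3 = period (ms),
 *                        q4 = phase (rad)
 *   parms[13]    segment start time t0 (ms, absolute)
 */
#include <R.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 14

static double parms[N_PARMS];

void hergfit_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double seg_voltage(double t)
{
    int kind = (int) parms[8];
    double t0 = parms[13];
    if (kind == 2)
        return parms[9] + (t - t0) / parms[11] * (parms[10] - parms[9]);
    if (kind == 3)
        return parms[9] + parms[10] * sin(2.0 * M_PI * (t - t0) / parms[11] + parms[12]);
    return parms[9];
}

void hergfit_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double v = seg_voltage(*t);
    double kO = parms[0] * exp(parms[1] * v);
    double kC = parms[2] * exp(-parms[3] * v);
    double kI = parms[4] * exp(parms[5] * v);
    double kA = parms[6] * exp(-parms[7] * v);
    double O = y[0], C = y[1], IO = y[2];
    double IC = 1.0 - (O + C + IO);

    ydot[0] = kO * C + kA * IO - (kC + kI) * O;
    ydot[1] = kC * O + kA * IC - (kO + kI) * C;
    ydot[2] = kI * O + kO * IC - (kA + kC) * IO;
}

static const R_CMethodDef cMethods[] = {
    {"hergfit_initmod", (DL_FUNC) &hergfit_initmod, 1},
    {"hergfit_derivs",  (DL_FUNC) &hergfit_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_hergfit(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
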