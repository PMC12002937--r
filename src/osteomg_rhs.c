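/* Compiled right-hand side of the coupled degradation / remodelling /
 * ultrastructure ODE system, in deSolve's compiled-model interface.
 *
 * Parameter vector layout (see simulateModel):
 *  0 k1  1 v1  2 r1  3 m2  4 k2  5 r2  6 k3  7 a  8 b
 *  9 removal_form (0 = mature matrix, 1 = maturation rate)
 * 10 has_ultra (0/1) 11 k4 12 k6 13 k7 14 k8 15 Lmin 16 Lmax
 * 17 deg_model (0 none, 1 power law, 2 surface rate)
 * 18 c1 19 c2 20 c3   (power law: m1, eps_t, exponent;
 *                      surface rate: r', d', unused)
 *
 * State: x1, x2, I, N, H, Vloss [, Cwidth, L]
 */
#include <R.h>
#include <math.h>
#include <R_ext/Rdynload.h>

#define N_PARMS 21
static double p[N_PARMS];

void osteomg_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

void osteomg_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double vr = 0.0;
    if (p[17] == 1.0)
        vr = p[18] * pow(*t + p[19], p[20]);
    else if (p[17] == 2.0)
        vr = p[18] * p[19] / (p[18] * (*t) + p[19]);

    double x1 = y[0], x2 = y[1], I = y[2], N = y[3];
    double Ipos = I > 0.0 ? I : 0.0;
    double Npos = N > 0.0 ? N : 0.0;
    double hill = p[8] / (p[8] + pow(Ipos, p[7]));
    double dH = p[6] * hill * Npos;
    double removal = (p[9] == 0.0) ? p[2] * x2 * I : p[2] * (p[0] * x1) * I;

    ydot[0] = -p[0] * x1;
    ydot[1] = p[0] * x1;
    ydot[2] = p[1] * x1 - removal + p[3] * vr;
    ydot[3] = p[4] * p[0] * x1 - p[5] * dH * N;
    ydot[4] = dH;
    ydot[5] = vr;
    if (p[10] == 1.0) {
        double Cw = y[6] > 0.0 ? y[6] : 0.0;
        double dHpos = dH > 0.0 ? dH : 0.0;
        ydot[6] = p[11] * Cw * pow(dHpos, p[12]);
        ydot[7] = -p[13] * vr * (y[7] - p[15]) + p[14] * (p[16] - y[7]);
    }
    if (ip[0] >= 2) {
        yout[0] = dH;
        yout[1] = vr;
    }
}

static const R_CMethodDef CEntries[] = {
    {"osteomg_derivs",  (DL_FUNC) &osteomg_derivs,  6},
    {"osteomg_initmod", (DL_FUNC) &osteomg_initmod, 1},
    {NULL, NULL, 0}
};

void R_init_osteomg(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
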