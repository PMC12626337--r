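/* Compiled right-hand sides for the gLV system, in absolute and
 * compositional coordinates, in the deSolve compiled-model convention.
 *
 * Parameter vector layout (fixed length so the solver's initializer can
 * copy it in one block): parms[0] = m, parms[1..MAXM] = r (zero-padded),
 * parms[1+MAXM ..] = B row-major (m*m entries, zero-padded).
 *
 * Once any state is non-finite or exceeds NSUM_MAX the derivative is
 * frozen at zero: mis-specified candidates blow up in finite time, and a
 * frozen field lets the adaptive solver finish quickly so the R side can
 * flag the trajectory invalid instead of stalling on step-size underflow.
 */
#include <R.h>
#include <math.h>

#define MAXM 25
#define NPARMS (1 + MAXM + MAXM * MAXM)
#define NSUM_MAX 1e8

static double parms[NPARMS];

void glv_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

static int state_ok(const double *y, int n, double cap)
{
    for (int i = 0; i < n; i++) {
        if (!R_FINITE(y[i]) || fabs(y[i]) > cap) return 0;
    }
    return 1;
}

/* compositional coordinates: y = (x_1..x_m, Nsum) */
void glv_rel_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    int m = (int) parms[0];
    const double *r = parms + 1;
    const double *B = parms + 1 + MAXM;
    double Ns = y[m];

    if (!state_ok(y, m + 1, NSUM_MAX) || Ns == 0.0) {
        for (int i = 0; i <= m; i++) ydot[i] = 0.0;
        return;
    }
    double sum_rx = 0.0, xBx = 0.0;
    double Bx[MAXM];
    for (int i = 0; i < m; i++) {
        double s = 0.0;
        for (int j = 0; j < m; j++) s += B[i * m + j] * y[j];
        Bx[i] = s;
        sum_rx += r[i] * y[i];
        xBx += y[i] * s;
    }
    double dNs = Ns * sum_rx + Ns * Ns * xBx;
    for (int i = 0; i < m; i++) {
        ydot[i] = y[i] * (r[i] + Ns * Bx[i] - dNs / Ns);
    }
    ydot[m] = dNs;
}

/* absolute coordinates: y = (N_1..N_m) */
void glv_abs_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    int m = (int) parms[0];
    const double *r = parms + 1;
    const double *B = parms + 1 + MAXM;

    if (!state_ok(y, m, NSUM_MAX)) {
        for (int i = 0; i < m; i++) ydot[i] = 0.0;
        return;
    }
    for (int i = 0; i < m; i++) {
        double s = 0.0;
        for (int j = 0; j < m; j++) s += B[i * m + j] * y[j];
        ydot[i] = y[i] * (r[i] + s);
    }
}
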