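/* Compiled right-hand side of the depot dissolution/disposition ODE.
 *
 * State layout: y[0..n-1] per-bin solid mass (mg), y[n] regional dissolved
 * mass (mg), y[n+1] central mass (mg), y[n+2] cumulative eliminated mass
 * (mg).  All quantities are in the package's canonical units
 * (mg, mL = cm^3, cm, h).
 *
 * Parameter vector layout (fixed length 8 + 2*MAXBINS, padded with zeros):
 *   [0] n_bins  [1] S  [2] rho  [3] D  [4] h  [5] v_region  [6] cl_perf
 *   [7] ke  [8 .. 8+n-1] lag times  [8+MAXBINS ..] particle counts
 */
#include <R.h>
#include <math.h>

#define MAXBINS 64
#define NPARMS (8 + 2 * MAXBINS)

static double parms[NPARMS];

void depot_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

void depot_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    int n = (int) parms[0];
    double S = parms[1], rho = parms[2], D = parms[3], h = parms[4];
    double v_region = parms[5], cl = parms[6], ke = parms[7];
    const double *lag = parms + 8;
    const double *npart = parms + 8 + MAXBINS;

    double regional = y[n];
    double central = y[n + 1];
    double c_reg = regional / v_region;
    double drive = S - c_reg;
    double sum_rate = 0.0;

    for (int i = 0; i < n; i++) {
        double solid = y[i] > 0.0 ? y[i] : 0.0;
        double rate = 0.0;
        if (*t > lag[i] && solid > 0.0 && drive > 0.0) {
            double r = cbrt(3.0 * (solid / npart[i]) / (4.0 * M_PI * rho));
            rate = -npart[i] * (D / h) * 4.0 * M_PI * r * (r + h) * drive;
            if (rate > 0.0) rate = 0.0; /* dissolution only */
        }
        ydot[i] = rate;
        sum_rate += rate;
    }
    ydot[n] = -sum_rate - c_reg * cl;
    ydot[n + 1] = c_reg * cl - central * ke;
    ydot[n + 2] = central * ke;
}
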