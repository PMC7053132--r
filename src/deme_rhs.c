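/* Within-deme growth dynamics, compiled right-hand sides for deSolve.
 *
 * State layout: y[0..k-1] strain sizes N_i, y[k] substrate s (in cell
 * equivalents, s = S*phi), y[k+1] public good (antibiotic b = B/mu, or
 * pyoverdine P; unused slot for the base model).
 *
 * Parameter layout (see .deme_parms() on the R side):
 *   parms[0] k, parms[1] interaction (0 base / 1 antibiotics /
 *   2 pyoverdine), parms[2] clamp-consumption flag, parms[3] kappa,
 *   parms[4] gamma, parms[5] sigma,
 *   parms[6 + i]        growth factors 1 + delta_alpha_i
 *   parms[6 + k + i]    inverse yield factors 1/(1 + delta_phi_i)
 *   parms[6 + 2k + i]   public-good production rates rho_i
 */

#include <R.h>
#include <math.h>

#define MAX_PARMS 40

static double parms[MAX_PARMS];

void deme_init(void (*odeparms)(int *, double *))
{
    int n = MAX_PARMS;
    odeparms(&n, parms);
}

void deme_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    int k = (int) parms[0];
    int inter = (int) parms[1];
    int clamp = (int) parms[2];
    double kappa = parms[3], gam = parms[4], sigma = parms[5];
    double A = 1.0, Y = 1.0;
    double g = y[k + 1];
    int i;

    if (inter == 1) {
        double b = g > 0.0 ? g : 0.0;
        double h = pow(b, kappa);
        A = (1.0 - h) / (1.0 + h / gam);
    } else if (inter == 2) {
        double P = g > 0.0 ? g : 0.0;
        Y = sigma - (sigma - 1.0) * exp(-P);
    }

    /* integration is terminated by the depletion root s = 0, so the
     * right-hand side stays smooth across the whole integration range */
    double cons = 0.0, prod = 0.0;
    for (i = 0; i < k; i++) {
        double rate = parms[6 + i] * A;         /* alpha_i(t) */
        double Ni = y[i] > 0.0 ? y[i] : 0.0;
        ydot[i] = rate * Ni;
        double crate = rate;
        if (clamp && crate < 0.0) crate = 0.0;  /* dying cells do not
                                                 * regenerate substrate */
        cons += crate * Ni * parms[6 + k + i];
        prod += parms[6 + 2 * k + i] * Ni;
    }

    ydot[k] = -cons / Y;
    if (inter == 1)
        ydot[k + 1] = -prod * (g > 0.0 ? g : 0.0);
    else if (inter == 2)
        ydot[k + 1] = prod;
    else
        ydot[k + 1] = 0.0;
}

/* root function: substrate depletion s = 0 terminates the growth phase */
void deme_root(int *neq, double *t, double *y, int *ng, double *gout,
               double *out, int *ip)
{
    int k = (int) parms[0];
    gout[0] = y[k];
}
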