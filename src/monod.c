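/* Monod batch model for deSolve's compiled-model interface.
 * States: y[0] = X biomass [g CDW/L], y[1] = S glucose [g/L],
 *         y[2] = P product [mM].
 * Parameters: mu_max [1/h], Ks [g/L], Yxs [g/g], qP_max [mmol/(g h)].
 * Product drains glucose at 1 mol glucose per mol product (both C6);
 * M(glucose) = 180.16 g/mol.
 */
#include <R.h>

static double parms[4];
#define MU_MAX parms[0]
#define KS     parms[1]
#define YXS    parms[2]
#define QP_MAX parms[3]

#define M_GLC 180.16

void monod_init(void (*odeparms)(int *, double *))
{
    int n = 4;
    odeparms(&n, parms);
}

void monod_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double X = y[0];
    double S = y[1] > 0 ? y[1] : 0;
    double sat = S / (KS + S);
    double mu = MU_MAX * sat;
    double qP = QP_MAX * sat;

    ydot[0] = mu * X;
    ydot[1] = -(mu / YXS) * X - qP * X * M_GLC / 1000.0;
    ydot[2] = qP * X;
    if (y[1] <= 0)
        ydot[1] = 0.0;
}
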