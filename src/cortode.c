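/* Stacked ODE right-hand side for the hydrocortisone whole-blood PK model.
 *
 * Each subject contributes 4 states: depot amount, total central amount
 * (unbound + CBG + albumin + RBC pools in rapid equilibrium), peripheral
 * amount, cumulative eliminated amount (all nmol).  Absorption is
 * Michaelis-Menten on the depot amount; clearance and intercompartmental
 * exchange act on the unbound plasma concentration, recovered at every
 * evaluation by the closed-form inversion of the binding equilibrium.
 *
 * Parameter vector layout (padded to CORT_MAXPAR on the R side):
 *   p[0]           number of subjects N
 *   p[1 + 10*i .. ] per-subject block: CL, Q, Vc, Vp, Km, Vmax,
 *                                      Bmax, KR, Kd, NS_Alb
 */
#include <R.h>
#include <math.h>

#define CORT_MAXSUB 600
#define CORT_MAXPAR (1 + 10 * CORT_MAXSUB)

static double par[CORT_MAXPAR];

void cort_init(void (*odeparms)(int *, double *))
{
    int n = CORT_MAXPAR;
    odeparms(&n, par);
}

/* unbound concentration from total central amount; quadratic root in the
 * cancellation-safe form (rationalised when b >= 0) */
static double cort_cu(double Ac, double Vc, double Bmax, double KR,
                      double Kd, double NS)
{
    double L, b, disc;
    if (Ac <= 0.0) return 0.0;
    L = Vc * (1.0 + NS + KR);
    b = L * Kd + Bmax * Vc - Ac;
    disc = sqrt(b * b + 4.0 * L * Ac * Kd);
    if (b >= 0.0)
        return 2.0 * Ac * Kd / (b + disc);
    return (-b + disc) / (2.0 * L);
}

void cort_deriv(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    int N = (int) par[0];
    int i;
    for (i = 0; i < N; i++) {
        const double *q = par + 1 + 10 * i;
        double CL = q[0], Q = q[1], Vc = q[2], Vp = q[3];
        double Km = q[4], Vmax = q[5], Bmax = q[6], KR = q[7];
        double Kd = q[8], NS = q[9];
        double Ad = y[4 * i], Ac = y[4 * i + 1], Ap = y[4 * i + 2];
        double Cu, ra, ex;
        if (Ad < 0.0) Ad = 0.0;
        if (Ac < 0.0) Ac = 0.0;
        Cu = cort_cu(Ac, Vc, Bmax, KR, Kd, NS);
        ra = Vmax * Ad / (Km + Ad);
        ex = Q * (Cu - Ap / Vp);
        ydot[4 * i]     = -ra;
        ydot[4 * i + 1] = ra - CL * Cu - ex;
        ydot[4 * i + 2] = ex;
        ydot[4 * i + 3] = CL * Cu;
    }
}
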