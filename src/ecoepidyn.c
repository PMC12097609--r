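/* Compiled right-hand side of the eco-epidemiological model, in the
 * parameterisation used throughout the package:
 *
 *   dS/dt = [r - b S - c I - beta(x) I/(a+S) - alpha1 P/(sigma+S)] S
 *   dI/dt = [beta(x) S/(a+S) - alpha2 P/(d+I) - mu] I
 *   dP/dt = [(c1 alpha1 S/(sigma+S) + c2 alpha2 I/(d+I)) P/(theta+P) - m] P
 *   dx/dt = x (1-x) G(S,I,P)          (only when the strategy is dynamic)
 *
 * beta(x) = beta0 (1 - e x), floored at 0.  P/(theta+P) is the weak Allee
 * (mate-finding) factor; theta == 0 reduces it to exactly 1 so the
 * Allee-free model is recovered without roundoff.
 *
 * The same parameter vector is shared by the 4-state system and the 8-state
 * "pair" system (reference + companion trajectory) used by the Benettin
 * Lyapunov estimator.  Parameter order must match .ecoepi_par_order in R.
 */
#include <R.h>

static double parms[19];

#define P_r      parms[0]
#define P_b      parms[1]
#define P_c      parms[2]
#define P_beta0  parms[3]
#define P_e      parms[4]
#define P_a      parms[5]
#define P_alpha1 parms[6]
#define P_alpha2 parms[7]
#define P_sigma  parms[8]
#define P_d      parms[9]
#define P_c1     parms[10]
#define P_c2     parms[11]
#define P_mu     parms[12]
#define P_m      parms[13]
#define P_theta  parms[14]
#define P_CS     parms[15]
#define P_CP     parms[16]
#define P_xdyn   parms[17]
#define P_gmode  parms[18]

void ecoepi_initmod(void (*odeparms)(int *, double *))
{
    int n = 19;
    odeparms(&n, parms);
}

static void rhs_core(const double *y, double *dy)
{
    double S = y[0], I = y[1], P = y[2], x = y[3];
    double beta = P_beta0 * (1.0 - P_e * x);
    double phi, G;
    double aS = P_a + S, sS = P_sigma + S, dI = P_d + I;

    if (beta < 0.0) beta = 0.0;
    phi = (P_theta == 0.0) ? 1.0 : P / (P_theta + P);

    dy[0] = (P_r - P_b * S - P_c * I - beta * I / aS - P_alpha1 * P / sS) * S;
    dy[1] = (beta * S / aS - P_alpha2 * P / dI - P_mu) * I;
    dy[2] = ((P_c1 * P_alpha1 * S / sS + P_c2 * P_alpha2 * I / dI) * phi - P_m) * P;

    switch ((int) P_gmode) {
    case 2:  /* pooled prey cost */
        G = -P_CS * (S + I) + P_CP * P;
        break;
    case 3:  /* cost divided by total prey; guarded near S+I = 0 */
        G = (S + I > 1e-12) ? (-P_CS / (S + I) + P_CP * P) : P_CP * P;
        break;
    default: /* literal reading */
        G = -P_CS * S + I + P_CP * P;
    }
    dy[3] = (P_xdyn != 0.0) ? x * (1.0 - x) * G : 0.0;
}

void ecoepi_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    rhs_core(y, ydot);
    if (*neq == 8)           /* reference + companion trajectory */
        rhs_core(y + 4, ydot + 4);
}
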