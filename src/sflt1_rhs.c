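/* Right-hand side of the sFLT1 trafficking models, in the form expected by
 * deSolve's compiled-function interface.  One routine serves all eight
 * candidate models: absent processes are encoded as zero rate constants.
 *
 * State: y[0] = I, intracellular sFLT1 (#/cell)
 *        y[1] = X, extracellular sFLT1 (#/cell)
 *
 * Scalar parameters (deSolve parms vector):
 *   0 alpha  production rate (#/cell/h)
 *   1 beta   secretion rate constant (1/h)
 *   2 gamma  intracellular degradation rate constant (1/h)
 *   3 delta  extracellular degradation rate constant (1/h)
 *   4 tau    maturation delay (h); 0 disables the delayed argument
 *   5 eps    internalization rate constant (1/h)
 *   6 kappa  production decay rate constant (1/h)
 *   7 prod_mode  0: production = alpha
 *                1: production = 0 (chase, no production decay)
 *                2: production = alpha * exp(-kappa * (t - chase_t0))
 *   8 chase_t0   clock origin of the production-decay exponential (h)
 *   9 t0     start of the current integration segment (h); the delayed
 *            argument is served by deSolve's lagvalue() for times after t0
 *            and by the user-supplied history buffer before t0
 *
 * The history buffer (intracellular I on a uniform time grid ending at the
 * segment start) is set from R via .Call("sflt_set_history", ...) before
 * each dede() segment; linear interpolation, clamped at the ends.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <R_ext/Rdynload.h>

static double P[10];

#define HIST_MAX 8192
static double hist_v[HIST_MAX];
static double hist_t0 = 0.0, hist_dt = 1.0;
static int hist_n = 0;

void sflt_initparms(void (*odeparms)(int *, double *))
{
    int N = 10;
    odeparms(&N, P);
}

SEXP sflt_set_history(SEXP t0, SEXP dt, SEXP values)
{
    int n = LENGTH(values);
    if (n > HIST_MAX)
        error("delay history buffer exceeds %d samples", HIST_MAX);
    hist_n = n;
    hist_t0 = REAL(t0)[0];
    hist_dt = REAL(dt)[0];
    for (int i = 0; i < n; i++)
        hist_v[i] = REAL(values)[i];
    return R_NilValue;
}

static double hist_interp(double t)
{
    if (hist_n == 0)
        return 0.0;
    if (hist_n == 1)
        return hist_v[0];
    double s = (t - hist_t0) / hist_dt;
    if (s <= 0.0)
        return hist_v[0];
    if (s >= hist_n - 1)
        return hist_v[hist_n - 1];
    int i = (int) s;
    double w = s - i;
    return (1.0 - w) * hist_v[i] + w * hist_v[i + 1];
}

static void lagvalue(double T, int *nr, int N, double *ytau)
{
    static void (*fun)(double, int *, int, double *) = NULL;
    if (fun == NULL)
        fun = (void (*)(double, int *, int, double *))
            R_GetCCallable("deSolve", "lagvalue");
    fun(T, nr, N, ytau);
}

void sflt_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double alpha = P[0], beta = P[1], gamma = P[2], delta = P[3],
           tau = P[4], eps = P[5], kappa = P[6];
    double Id;

    if (tau > 0.0) {
        double T = *t - tau;
        if (T > P[9]) {
            int nr[1] = { 0 };
            double ytau[1] = { 0.0 };
            lagvalue(T, nr, 1, ytau);
            Id = ytau[0];
        } else {
            Id = hist_interp(T);
        }
    } else {
        Id = y[0];
    }
    /* tiny negative values can emerge from the interpolation error of the
     * solver; clamp so first-order rates never act on negative amounts */
    if (Id < 0.0) Id = 0.0;
    double X = y[1] < 0.0 ? 0.0 : y[1];

    double prod;
    if (P[7] == 0.0)
        prod = alpha;
    else if (P[7] == 1.0)
        prod = 0.0;
    else
        prod = alpha * exp(-kappa * (*t - P[8]));

    ydot[0] = prod - (beta + gamma) * Id + eps * X;
    ydot[1] = beta * Id - delta * X - eps * X;
}
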