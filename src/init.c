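#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP sflt_set_history(SEXP t0, SEXP dt, SEXP values);
void sflt_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip);
void sflt_initparms(void (*odeparms)(int *, double *));

static const R_CallMethodDef callMethods[] = {
    {"sflt_set_history", (DL_FUNC) &sflt_set_history, 3},
    {NULL, NULL, 0}
};

static const R_CMethodDef cMethods[] = {
    {"sflt_derivs",    (DL_FUNC) &sflt_derivs,    6},
    {"sflt_initparms", (DL_FUNC) &sflt_initparms, 1},
    {NULL, NULL, 0}
};

void R_init_sflt1sim(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, callMethods, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
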