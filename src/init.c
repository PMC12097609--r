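#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void ecoepi_initmod(void (*odeparms)(int *, double *));
void ecoepi_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip);

/* deSolve resolves these by name through getNativeSymbolInfo() */
static const R_CMethodDef CEntries[] = {
    {"ecoepi_initmod", (DL_FUNC) &ecoepi_initmod, 1},
    {"ecoepi_derivs",  (DL_FUNC) &ecoepi_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_ecoepidyn(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
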