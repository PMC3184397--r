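#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_redox_rhs(SEXP sy, SEXP sp);
void redox_initmod(void (*odeparms)(int *, double *));
void redox_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip);

static const R_CallMethodDef call_entries[] = {
    {"C_redox_rhs", (DL_FUNC) &C_redox_rhs, 2},
    {NULL, NULL, 0}
};

void R_init_redoxrbc(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE); /* deSolve looks up redox_derivs by name */
}
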