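#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP costim_logic_rhs(SEXP, SEXP, SEXP);
extern SEXP costim_set_model(SEXP, SEXP);
extern void costim_derivs(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
    {"costim_logic_rhs", (DL_FUNC) &costim_logic_rhs, 3},
    {"costim_set_model", (DL_FUNC) &costim_set_model, 2},
    {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
    {"costim_derivs", (DL_FUNC) &costim_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_costim(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
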