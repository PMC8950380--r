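#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP _synsurv_ar1_poisson_chain(SEXP, SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"_synsurv_ar1_poisson_chain", (DL_FUNC) &_synsurv_ar1_poisson_chain, 5},
    {NULL, NULL, 0}
};

void R_init_synsurv(DllInfo *dll) {
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
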