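#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void marm_init(void (*odeparms)(int *, double *));
void marm_derivs(int *, double *, double *, double *, double *, int *);
void marm_root(int *, double *, double *, int *, double *, double *, int *);
SEXP cc_label(SEXP, SEXP);

static const R_CMethodDef CEntries[] = {
    {"marm_init",   (DL_FUNC) &marm_init,   1},
    {"marm_derivs", (DL_FUNC) &marm_derivs, 6},
    {"marm_root",   (DL_FUNC) &marm_root,   7},
    {NULL, NULL, 0}
};

static const R_CallMethodDef CallEntries[] = {
    {"cc_label", (DL_FUNC) &cc_label, 2},
    {NULL, NULL, 0}
};

void R_init_sonopore(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
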