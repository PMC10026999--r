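#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_sha512_256(SEXP data);

static const R_CallMethodDef call_entries[] = {
    {"C_sha512_256", (DL_FUNC) &C_sha512_256, 1},
    {NULL, NULL, 0}
};

void R_init_mammodb(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
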