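#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP lg_bf_block(SEXP, SEXP);
SEXP lg_bf_cbc_encrypt(SEXP, SEXP, SEXP);
SEXP lg_bf_cbc_decrypt(SEXP, SEXP, SEXP);
SEXP lg_pbkdf2(SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef callMethods[] = {
  {"lg_bf_block",       (DL_FUNC) &lg_bf_block,       2},
  {"lg_bf_cbc_encrypt", (DL_FUNC) &lg_bf_cbc_encrypt, 3},
  {"lg_bf_cbc_decrypt", (DL_FUNC) &lg_bf_cbc_decrypt, 3},
  {"lg_pbkdf2",         (DL_FUNC) &lg_pbkdf2,         4},
  {NULL, NULL, 0}
};

void R_init_leakguard(DllInfo *info) {
  R_registerRoutines(info, NULL, callMethods, NULL, NULL);
  R_useDynamicSymbols(info, FALSE);
}
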