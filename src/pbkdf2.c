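/* PBKDF2-HMAC-SHA256 via libcrypto. */
#include <string.h>
#include <R.h>
#include <Rinternals.h>
#include <openssl/evp.h>

SEXP lg_pbkdf2(SEXP passphrase, SEXP salt, SEXP iterations, SEXP keylen) {
  const char *pass;
  int iter, len, ok;
  SEXP out;
  if (TYPEOF(passphrase) != STRSXP || XLENGTH(passphrase) != 1)
    error("passphrase must be a single string");
  if (TYPEOF(salt) != RAWSXP) error("salt must be raw");
  pass = CHAR(STRING_ELT(passphrase, 0));
  iter = asInteger(iterations);
  len = asInteger(keylen);
  if (iter < 1) error("iterations must be >= 1");
  if (len < 1 || len > 1024) error("keylen out of range");
  out = PROTECT(allocVector(RAWSXP, len));
  ok = PKCS5_PBKDF2_HMAC(pass, (int)strlen(pass), RAW(salt),
                         (int)XLENGTH(salt), iter, EVP_sha256(), len,
                         RAW(out));
  UNPROTECT(1);
  if (!ok) error("PBKDF2 key derivation failed");
  return out;
}
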