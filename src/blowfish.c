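/* Blowfish block cipher (64-bit blocks, 16 rounds) with CBC mode and
 * PKCS#7 padding. Implemented from the published algorithm definition;
 * initial P-array/S-boxes are the hexadecimal digits of pi (see
 * blowfish_tables.h). Key length 4..56 bytes.
 */
#include <stdint.h>
#include <string.h>
#include <R.h>
#include <Rinternals.h>
#include "blowfish_tables.h"

typedef struct {
  uint32_t P[18];
  uint32_t S[4][256];
} bf_ctx;

static uint32_t bf_f(const bf_ctx *c, uint32_t x) {
  uint32_t h = c->S[0][x >> 24] + c->S[1][(x >> 16) & 0xff];
  return (h ^ c->S[2][(x >> 8) & 0xff]) + c->S[3][x & 0xff];
}

static void bf_encrypt_block(const bf_ctx *c, uint32_t *xl, uint32_t *xr) {
  uint32_t l = *xl, r = *xr, t;
  int i;
  for (i = 0; i < 16; i++) {
    l ^= c->P[i];
    r ^= bf_f(c, l);
    t = l; l = r; r = t;
  }
  t = l; l = r; r = t;          /* undo last swap */
  r ^= c->P[16];
  l ^= c->P[17];
  *xl = l; *xr = r;
}

static void bf_decrypt_block(const bf_ctx *c, uint32_t *xl, uint32_t *xr) {
  uint32_t l = *xl, r = *xr, t;
  int i;
  for (i = 17; i > 1; i--) {
    l ^= c->P[i];
    r ^= bf_f(c, l);
    t = l; l = r; r = t;
  }
  t = l; l = r; r = t;
  r ^= c->P[1];
  l ^= c->P[0];
  *xl = l; *xr = r;
}

static void bf_init(bf_ctx *c, const unsigned char *key, int keylen) {
  int i, j, k;
  uint32_t l = 0, r = 0;
  memcpy(c->P, bf_init_P, sizeof(c->P));
  memcpy(c->S, bf_init_S, sizeof(c->S));
  for (i = 0, j = 0; i < 18; i++) {
    uint32_t d = 0;
    for (k = 0; k < 4; k++) {
      d = (d << 8) | key[j];
      j = (j + 1) % keylen;
    }
    c->P[i] ^= d;
  }
  for (i = 0; i < 18; i += 2) {
    bf_encrypt_block(c, &l, &r);
    c->P[i] = l; c->P[i + 1] = r;
  }
  for (i = 0; i < 4; i++)
    for (j = 0; j < 256; j += 2) {
      bf_encrypt_block(c, &l, &r);
      c->S[i][j] = l; c->S[i][j + 1] = r;
    }
}

static uint32_t be32(const unsigned char *p) {
  return ((uint32_t)p[0] << 24) | ((uint32_t)p[1] << 16) |
         ((uint32_t)p[2] << 8) | (uint32_t)p[3];
}

static void put_be32(unsigned char *p, uint32_t v) {
  p[0] = (unsigned char)(v >> 24); p[1] = (unsigned char)(v >> 16);
  p[2] = (unsigned char)(v >> 8);  p[3] = (unsigned char)v;
}

static void check_key(SEXP key) {
  R_xlen_t n = XLENGTH(key);
  if (TYPEOF(key) != RAWSXP || n < 4 || n > 56)
    error("Blowfish key must be a raw vector of 4..56 bytes");
}

/* single-block ECB encryption, used for known-answer validation */
SEXP lg_bf_block(SEXP key, SEXP block) {
  bf_ctx c;
  uint32_t l, r;
  SEXP out;
  check_key(key);
  if (TYPEOF(block) != RAWSXP || XLENGTH(block) != 8)
    error("block must be 8 raw bytes");
  bf_init(&c, RAW(key), (int)XLENGTH(key));
  l = be32(RAW(block)); r = be32(RAW(block) + 4);
  bf_encrypt_block(&c, &l, &r);
  out = PROTECT(allocVector(RAWSXP, 8));
  put_be32(RAW(out), l); put_be32(RAW(out) + 4, r);
  UNPROTECT(1);
  return out;
}

SEXP lg_bf_cbc_encrypt(SEXP data, SEXP key, SEXP iv) {
  bf_ctx c;
  R_xlen_t n, padded, i;
  int pad, k;
  unsigned char prev[8], blk[8];
  SEXP out;
  check_key(key);
  if (TYPEOF(iv) != RAWSXP || XLENGTH(iv) != 8)
    error("iv must be 8 raw bytes");
  if (TYPEOF(data) != RAWSXP) error("data must be raw");
  n = XLENGTH(data);
  pad = 8 - (int)(n % 8);
  padded = n + pad;
  out = PROTECT(allocVector(RAWSXP, padded));
  bf_init(&c, RAW(key), (int)XLENGTH(key));
  memcpy(prev, RAW(iv), 8);
  for (i = 0; i < padded; i += 8) {
    uint32_t l, r;
    for (k = 0; k < 8; k++) {
      unsigned char b = (i + k < n) ? RAW(data)[i + k] : (unsigned char)pad;
      blk[k] = b ^ prev[k];
    }
    l = be32(blk); r = be32(blk + 4);
    bf_encrypt_block(&c, &l, &r);
    put_be32(RAW(out) + i, l); put_be32(RAW(out) + i + 4, r);
    memcpy(prev, RAW(out) + i, 8);
  }
  UNPROTECT(1);
  return out;
}

SEXP lg_bf_cbc_decrypt(SEXP data, SEXP key, SEXP iv) {
  bf_ctx c;
  R_xlen_t n, i;
  int pad, k;
  unsigned char prev[8], blk[8];
  unsigned char *buf;
  SEXP out;
  check_key(key);
  if (TYPEOF(iv) != RAWSXP || XLENGTH(iv) != 8)
    error("iv must be 8 raw bytes");
  if (TYPEOF(data) != RAWSXP) error("data must be raw");
  n = XLENGTH(data);
  if (n == 0 || n % 8 != 0)
    error("ciphertext length must be a positive multiple of 8");
  buf = (unsigned char *) R_alloc(n, 1);
  bf_init(&c, RAW(key), (int)XLENGTH(key));
  memcpy(prev, RAW(iv), 8);
  for (i = 0; i < n; i += 8) {
    uint32_t l = be32(RAW(data) + i), r = be32(RAW(data) + i + 4);
    bf_decrypt_block(&c, &l, &r);
    put_be32(blk, l); put_be32(blk + 4, r);
    for (k = 0; k < 8; k++) buf[i + k] = blk[k] ^ prev[k];
    memcpy(prev, RAW(data) + i, 8);
  }
  pad = buf[n - 1];
  if (pad < 1 || pad > 8) error("bad padding");
  for (k = 0; k < pad; k++)
    if (buf[n - 1 - k] != pad) error("bad padding");
  out = PROTECT(allocVector(RAWSXP, n - pad));
  memcpy(RAW(out), buf, n - pad);
  UNPROTECT(1);
  return out;
}
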