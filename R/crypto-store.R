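# Encrypted store of hashed germline variant keys.
#
# On-disk layout (all integers little-endian, "GLF1" format version 1):
#   bytes 1-4    magic "GLF1"
#   byte  5      format version (1)
#   byte  6      hash protocol id (1 = SHA512, 2 = MD5)
#   byte  7      cipher id (1 = AES-256-CBC, 2 = Blowfish-CBC)
#   bytes 8-11   PBKDF2 iteration count (uint32)
#   bytes 12-27  KDF salt (16 bytes)
#   byte  28     IV length (16 for AES, 8 for Blowfish)
#   ...          IV bytes
#   16 bytes     passphrase verifier
#   uint32       digest count
#   uint32       ciphertext length, then the ciphertext
#   32 bytes     HMAC-SHA256 over every preceding byte (encrypt-then-MAC)
#
# Key material: PBKDF2-HMAC-SHA256(passphrase, salt, iterations, 80 bytes)
# split into encryption key (32), MAC key (32) and verifier (16). The
# verifier distinguishes a wrong passphrase from a corrupted file; the MAC
# makes corruption detectable before any decryption output is trusted.
# The plaintext payload is the digest set, as raw digest bytes
# concatenated in sorted hex order, so stores built from the same variant
# set are identical given identical salt/iv.

.STORE_MAGIC <- charToRaw("GLF1")
.STORE_VERSION <- 1L
.HASH_IDS <- c(SHA512 = 1L, MD5 = 2L)
.CIPHER_IDS <- c(AES = 1L, Blowfish = 2L)
.DIGEST_BYTES <- c(SHA512 = 64L, MD5 = 16L)

.badCredentials <- function(msg) {
  stop(errorCondition(msg, class = c("leakguard_bad_credentials",
                                     "leakguard_error")))
}

.integrityError <- function(msg) {
  stop(errorCondition(msg, class = c("leakguard_integrity_error",
                                     "leakguard_error")))
}

.hexToRaw <- function(hex) {
  as.raw(strtoi(substring(hex, seq(1L, nchar(hex), 2L),
                          seq(2L, nchar(hex), 2L)), 16L))
}

.rawToHex <- function(bytes) paste(sprintf("%02x", as.integer(bytes)),
                                   collapse = "")

.deriveKeys <- function(passphrase, salt, iterations) {
  km <- .Call("lg_pbkdf2", passphrase, salt, as.integer(iterations), 80L,
              PACKAGE = "leakguard")
  list(enc = km[1:32], mac = km[33:64], verifier = km[65:80])
}

.hmac256 <- function(msg, key) {
  as.raw(openssl::sha256(msg, key = key))
}

.encryptPayload <- function(plain, key, iv, cipher) {
  if (cipher == "AES") {
    as.raw(openssl::aes_cbc_encrypt(plain, key = key, iv = iv))
  } else {
    .Call("lg_bf_cbc_encrypt", plain, key, iv, PACKAGE = "leakguard")
  }
}

.decryptPayload <- function(ciphertext, key, iv, cipher) {
  if (cipher == "AES") {
    openssl::aes_cbc_decrypt(ciphertext, key = key, iv = iv)
  } else {
    .Call("lg_bf_cbc_decrypt", ciphertext, key, iv, PACKAGE = "leakguard")
  }
}

#' Serialize variant keys to their canonical hashed form
#'
#' `serializeKey()` returns the canonical `"chrom:pos:ref:alt"` strings
#' (see [canonicalKeys()]); `hashKey()` maps canonical strings to
#' lowercase hex digests under the chosen protocol. The digest is the
#' plain SHA-512 (or MD5) of the string's UTF-8 bytes, unsalted, so
#' digests are comparable across independently built stores.
#'
#' @param key a [VariantKeySet-class].
#' @return `serializeKey()`: character vector of canonical strings.
#' @export
serializeKey <- function(key) {
  stopifnot(is(key, "VariantKeySet"))
  canonicalKeys(key)
}

#' @rdname serializeKey
#' @param canonical character vector of canonical key strings.
#' @param protocol `"SHA512"` (default) or `"MD5"`.
#' @return `hashKey()`: character vector of hex digests (128 hex characters
#'   for SHA512, 32 for MD5).
#' @examples
#' hashKey("1:12345:A:G")
#' @export
hashKey <- function(canonical, protocol = c("SHA512", "MD5")) {
  protocol <- match.arg(protocol)
  if (!length(canonical)) return(character())
  if (protocol == "SHA512") {
    as.character(openssl::sha512(canonical))
  } else {
    as.character(openssl::md5(canonical))
  }
}

#' Build an encrypted germline store
#'
#' Hashes every canonical germline variant key, then writes the digest set
#' to `out` encrypted under a key derived from `passphrase` (PBKDF2, salt
#' and iteration count recorded in the plaintext header). The resulting
#' file contains no genotypes and no plaintext variant identities; it is
#' the only artefact that needs to travel to a public-facing server.
#'
#' @param germline a [VariantKeySet-class] of germline truth calls.
#' @param passphrase non-empty secret string.
#' @param out output path for the store file.
#' @param hashProtocol `"SHA512"` (default) or `"MD5"`.
#' @param cipher `"AES"` (default, AES-256-CBC) or `"Blowfish"` (CBC).
#' @param iterations PBKDF2 iteration count.
#' @param saltMaterial optional raw vector or string; when supplied, salt
#'   and IV are derived from it deterministically (reproducible builds).
#'   By default both are drawn fresh from the OS entropy source, so two
#'   builds of the same set produce different file bytes that decrypt to
#'   the same digest set.
#' @return (invisibly) the store header as a named list (`magic`,
#'   `version`, `hashProtocol`, `cipher`, `kdfIterations`, `digestCount`).
#' @seealso [loadStore()], [countLeaks()]
#' @export
buildStore <- function(germline, passphrase, out,
                       hashProtocol = c("SHA512", "MD5"),
                       cipher = c("AES", "Blowfish"),
                       iterations = 10000L, saltMaterial = NULL) {
  stopifnot(is(germline, "VariantKeySet"))
  hashProtocol <- match.arg(hashProtocol)
  cipher <- match.arg(cipher)
  if (!is.character(passphrase) || length(passphrase) != 1L ||
      !nzchar(passphrase))
    stop("passphrase must be a non-empty string")
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L)
    stop("iterations must be a positive integer")

  digests <- sort(hashKey(serializeKey(germline), hashProtocol),
                  method = "radix")
  payload <- if (length(digests)) {
    do.call(c, lapply(digests, .hexToRaw))
  } else raw()

  ivLen <- if (cipher == "AES") 16L else 8L
  if (is.null(saltMaterial)) {
    salt <- openssl::rand_bytes(16L)
    iv <- openssl::rand_bytes(ivLen)
  } else {
    seedBytes <- as.raw(openssl::sha512(
      if (is.raw(saltMaterial)) saltMaterial else charToRaw(as.character(saltMaterial))))
    salt <- seedBytes[1:16]
    iv <- seedBytes[17:(16L + ivLen)]
  }

  keys <- .deriveKeys(passphrase, salt, iterations)
  ciphertext <- .encryptPayload(payload, keys$enc, iv, cipher)

  con <- rawConnection(raw(), "wb")
  writeBin(.STORE_MAGIC, con)
  writeBin(as.raw(c(.STORE_VERSION, .HASH_IDS[[hashProtocol]],
                    .CIPHER_IDS[[cipher]])), con)
  writeBin(iterations, con, size = 4L, endian = "little")
  writeBin(salt, con)
  writeBin(as.raw(ivLen), con)
  writeBin(iv, con)
  writeBin(keys$verifier, con)
  writeBin(length(digests), con, size = 4L, endian = "little")
  writeBin(length(ciphertext), con, size = 4L, endian = "little")
  writeBin(ciphertext, con)
  headerAndPayload <- rawConnectionValue(con)
  close(con)
  mac <- .hmac256(headerAndPayload, keys$mac)

  fileCon <- file(out, "wb")
  tryCatch({
    writeBin(headerAndPayload, fileCon)
    writeBin(mac, fileCon)
  }, finally = close(fileCon))

  invisible(list(magic = "GLF1", version = .STORE_VERSION,
                 hashProtocol = hashProtocol, cipher = cipher,
                 kdfIterations = iterations,
                 digestCount = length(digests)))
}

#' Load an encrypted germline store into memory
#'
#' Verifies the passphrase and the file's integrity tag, then decrypts the
#' digest set in memory. No decrypted bytes are ever written to disk. A
#' wrong passphrase raises a `leakguard_bad_credentials` error before any
#' decryption is attempted; a damaged or truncated file raises a
#' `leakguard_integrity_error`. In neither case is a partial digest set
#' returned.
#'
#' @param path path to a file written by [buildStore()].
#' @param passphrase the store's secret.
#' @return a [GermlineStore-class].
#' @export
loadStore <- function(path, passphrase) {
  if (!file.exists(path)) stop("no such store file: ", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  need <- function(n, at) {
    if (at + n - 1L > length(bytes))
      .integrityError("store file is truncated")
    bytes[at:(at + n - 1L)]
  }
  if (!identical(need(4L, 1L), .STORE_MAGIC))
    stop("not a leakguard store file (bad magic)")
  version <- as.integer(need(1L, 5L))
  if (version != .STORE_VERSION)
    stop("unsupported store format version: ", version)
  hashId <- as.integer(need(1L, 6L))
  cipherId <- as.integer(need(1L, 7L))
  if (!hashId %in% .HASH_IDS) stop("unknown hash protocol id: ", hashId)
  if (!cipherId %in% .CIPHER_IDS) stop("unknown cipher id: ", cipherId)
  hashProtocol <- names(.HASH_IDS)[match(hashId, .HASH_IDS)]
  cipher <- names(.CIPHER_IDS)[match(cipherId, .CIPHER_IDS)]
  iterations <- readBin(need(4L, 8L), "integer", size = 4L,
                        endian = "little")
  salt <- need(16L, 12L)
  ivLen <- as.integer(need(1L, 28L))
  if (!ivLen %in% c(8L, 16L)) .integrityError("invalid IV length")
  iv <- need(ivLen, 29L)
  at <- 29L + ivLen
  verifier <- need(16L, at); at <- at + 16L
  digestCount <- readBin(need(4L, at), "integer", size = 4L,
                         endian = "little"); at <- at + 4L
  ctLen <- readBin(need(4L, at), "integer", size = 4L,
                   endian = "little"); at <- at + 4L
  if (ctLen < 0L) .integrityError("invalid ciphertext length")
  ciphertext <- need(ctLen, at); at <- at + ctLen
  mac <- need(32L, at)
  if (at + 32L - 1L != length(bytes))
    .integrityError("store file has trailing bytes")

  keys <- .deriveKeys(passphrase, salt, iterations)
  if (!identical(keys$verifier, verifier))
    .badCredentials("wrong passphrase for store file")
  expected <- .hmac256(bytes[1:(at - 1L)], keys$mac)
  if (!identical(as.raw(expected), as.raw(mac)))
    .integrityError("store file failed integrity check (corrupted)")

  payload <- tryCatch(
    .decryptPayload(ciphertext, keys$enc, iv, cipher),
    error = function(e) .integrityError(paste0("decryption failed: ",
                                               conditionMessage(e))))
  dlen <- .DIGEST_BYTES[[hashProtocol]]
  if (length(payload) != digestCount * dlen)
    .integrityError("decrypted payload size disagrees with digest count")
  digests <- if (digestCount > 0L) {
    m <- matrix(as.integer(payload), nrow = dlen)
    apply(m, 2L, function(col) paste(sprintf("%02x", col), collapse = ""))
  } else character()
  new("GermlineStore", digests = digests, hashProtocol = hashProtocol,
      cipher = cipher, kdfIterations = iterations, path = path)
}

#' @rdname accessors
#' @export
setMethod("digestCount", "GermlineStore", function(x) length(x@digests))

#' @rdname accessors
#' @export
setMethod("hashProtocol", "GermlineStore", function(x) x@hashProtocol)

#' @rdname accessors
#' @export
setMethod("cipherName", "GermlineStore", function(x) x@cipher)

setMethod("show", "GermlineStore", function(object) {
  cat(sprintf("GermlineStore: %d %s digest%s, sealed with %s",
              digestCount(object), object@hashProtocol,
              if (digestCount(object) == 1L) "" else "s", object@cipher))
  if (nzchar(object@path)) cat(sprintf(" [%s]", object@path))
  cat("\n")
})
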