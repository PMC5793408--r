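test_that("canonical serialization is the documented injective form", {
  ks <- VariantKeySet(chrom = c("1", "X"), pos = c(12345L, 7L),
                      ref = c("A", "C"), alt = c("G", "T"))
  expect_identical(serializeKey(ks), c("1:12345:A:G", "X:7:C:T"))
  # keys differing only in alt serialize differently
  k1 <- VariantKeySet("1", 5L, "A", "G")
  k2 <- VariantKeySet("1", 5L, "A", "T")
  expect_false(serializeKey(k1) == serializeKey(k2))
})

test_that("digests match an independent reference implementation", {
  # frozen from Python hashlib on the same UTF-8 bytes
  expect_identical(
    hashKey("1:12345:A:G", "SHA512"),
    paste0("63f647b03d4cd200e66f08eb5ce9ed1e444c760ab84d3d65f21b446c715f6062",
           "39e30223ea4c3ea7b63f40ee6e3edf1517c678e9a5b597c580af321faf258adb"))
  expect_identical(hashKey("1:12345:A:G", "MD5"),
                   "0037696b1aa67d1d2ff63e538ce0d219")
  # and against a second in-session implementation
  skip_if_not_installed("digest")
  s <- "X:7:C:T"
  expect_identical(hashKey(s, "SHA512"),
                   digest::digest(s, algo = "sha512", serialize = FALSE))
  expect_identical(hashKey(s, "MD5"),
                   digest::digest(s, algo = "md5", serialize = FALSE))
})

test_that("digest lengths are 64 bytes for SHA512 and 16 for MD5", {
  expect_identical(nchar(hashKey("1:1:A:G", "SHA512")), 128L)
  expect_identical(nchar(hashKey("1:1:A:G", "MD5")), 32L)
  expect_identical(hashKey("1:1:A:G"), hashKey("1:1:A:G"))  # deterministic
})

test_that("PBKDF2 key derivation matches the reference implementation", {
  # frozen from Python hashlib.pbkdf2_hmac('sha256', b'pass', b'salt', 1000, 32)
  out <- .Call("lg_pbkdf2", "pass", charToRaw("salt"), 1000L, 32L,
               PACKAGE = "leakguard")
  expect_identical(
    paste(sprintf("%02x", as.integer(out)), collapse = ""),
    "ce7834ce3ad3ce55207a94de959d37afbd9f8eea479d46cbe7959a53d1ab5ecb")
})

test_that("Blowfish block cipher reproduces the published known-answer vectors", {
  kat <- function(keyHex, ptHex) {
    toupper(paste(sprintf("%02x", as.integer(
      .Call("lg_bf_block",
            as.raw(strtoi(substring(keyHex, seq(1, 15, 2), seq(2, 16, 2)), 16L)),
            as.raw(strtoi(substring(ptHex, seq(1, 15, 2), seq(2, 16, 2)), 16L)),
            PACKAGE = "leakguard"))), collapse = ""))
  }
  expect_identical(kat("0000000000000000", "0000000000000000"),
                   "4EF997456198DD78")
  expect_identical(kat("FFFFFFFFFFFFFFFF", "FFFFFFFFFFFFFFFF"),
                   "51866FD5B85ECB8A")
})

test_that("Blowfish CBC round-trips arbitrary payloads with PKCS7 padding", {
  set.seed(501)
  key <- as.raw(sample(0:255, 16, replace = TRUE))
  iv <- as.raw(sample(0:255, 8, replace = TRUE))
  for (n in c(0L, 1L, 7L, 8L, 9L, 64L, 1000L)) {
    plain <- as.raw(sample(0:255, n, replace = TRUE))
    ct <- .Call("lg_bf_cbc_encrypt", plain, key, iv, PACKAGE = "leakguard")
    expect_identical(length(ct) %% 8L, 0L)
    expect_gt(length(ct), n - 1L)
    expect_identical(
      .Call("lg_bf_cbc_decrypt", ct, key, iv, PACKAGE = "leakguard"),
      plain)
  }
})

test_that("build/load round-trips the digest set for every protocol pairing", {
  set.seed(502)
  keys <- randomKeySet(25)
  for (hp in c("SHA512", "MD5")) for (ci in c("AES", "Blowfish")) {
    f <- tempfile(fileext = ".store")
    hdr <- buildStore(keys, "passphrase", f, hashProtocol = hp, cipher = ci)
    expect_identical(hdr$digestCount, 25L)
    st <- loadStore(f, "passphrase")
    expect_identical(hashProtocol(st), hp)
    expect_identical(cipherName(st), ci)
    expect_setequal(st@digests, hashKey(serializeKey(keys), hp))
  }
})

test_that("an empty variant set builds a valid store with zero digests", {
  f <- tempfile(fileext = ".store")
  hdr <- buildStore(VariantKeySet(), "pw", f)
  expect_identical(hdr$digestCount, 0L)
  expect_identical(digestCount(loadStore(f, "pw")), 0L)
})

test_that("store bytes differ across builds but decrypt identically", {
  set.seed(503)
  keys <- randomKeySet(5)
  f1 <- tempfile(); f2 <- tempfile()
  buildStore(keys, "pw", f1)
  buildStore(keys, "pw", f2)
  b1 <- readBin(f1, "raw", file.info(f1)$size)
  b2 <- readBin(f2, "raw", file.info(f2)$size)
  expect_false(identical(b1, b2))          # fresh salt/iv every build
  expect_identical(loadStore(f1, "pw")@digests, loadStore(f2, "pw")@digests)
  # deterministic when explicit salt material is supplied
  f3 <- tempfile(); f4 <- tempfile()
  buildStore(keys, "pw", f3, saltMaterial = "fixed-entropy")
  buildStore(keys, "pw", f4, saltMaterial = "fixed-entropy")
  expect_identical(readBin(f3, "raw", file.info(f3)$size),
                   readBin(f4, "raw", file.info(f4)$size))
})

test_that("wrong passphrase is a credentials error, never a partial set", {
  set.seed(504)
  f <- tempfile()
  buildStore(randomKeySet(10), "correct", f)
  err <- tryCatch(loadStore(f, "wrong"), error = identity)
  expect_s3_class(err, "leakguard_bad_credentials")
})

test_that("corruption and truncation raise integrity errors", {
  set.seed(505)
  f <- tempfile()
  buildStore(randomKeySet(10), "pw", f)
  bytes <- readBin(f, "raw", file.info(f)$size)
  # flip one ciphertext byte
  corrupt <- bytes
  i <- length(bytes) - 40L
  corrupt[i] <- xor(corrupt[i], as.raw(1L))
  fc <- tempfile(); writeBin(corrupt, fc)
  expect_s3_class(tryCatch(loadStore(fc, "pw"), error = identity),
                  "leakguard_integrity_error")
  # truncate
  ft <- tempfile(); writeBin(bytes[1:(length(bytes) - 10L)], ft)
  expect_s3_class(tryCatch(loadStore(ft, "pw"), error = identity),
                  "leakguard_integrity_error")
})

test_that("store files contain no plaintext canonical key strings", {
  set.seed(506)
  keys <- randomKeySet(20)
  f <- tempfile()
  buildStore(keys, "pw", f)
  blob <- readBin(f, "raw", file.info(f)$size)
  for (k in canonicalKeys(keys))
    expect_length(grepRaw(k, blob, fixed = TRUE), 0L)
})

test_that("canonical strings and SHA512 digests are collision-free at scale", {
  set.seed(507)
  n <- 100000L
  bases <- c("A", "C", "G", "T")
  chrom <- as.character(sample(1:22, n, replace = TRUE))
  pos <- sample.int(200000000L, n)
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "",
                USE.NAMES = FALSE)
  canon <- unique(paste(chrom, pos, ref, alt, sep = ":"))
  expect_gt(length(canon), n * 0.99)       # near-distinct by construction
  digests <- hashKey(canon, "SHA512")
  expect_identical(anyDuplicated(digests), 0L)
})
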