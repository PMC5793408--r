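#' @import methods
NULL

#' Set of canonical variant keys
#'
#' A `VariantKeySet` holds the deduplicated, normalized identities of
#' single-nucleotide variants: chromosome (without any `chr` prefix),
#' 1-based position, reference allele and alternate allele, all uppercase.
#' Two call sets match on a variant exactly when all four fields are equal;
#' this is the identity every other function in the package works with.
#'
#' Records are stored sorted by (chromosome, position, ref, alt), with
#' chromosomes ordered numerically where possible (1..22 before X, Y, MT).
#'
#' @slot chrom character vector of normalized chromosome labels.
#' @slot pos integer vector of 1-based positions.
#' @slot ref character vector of reference alleles (uppercase, A/C/G/T).
#' @slot alt character vector of alternate alleles (uppercase, A/C/G/T).
#' @slot sourceLabel free-text provenance string.
#' @slot dropped named integer vector of records dropped on ingest
#'   (`non_snv`, `filtered`, `symbolic`, `invalid`, `duplicate`).
#'
#' @seealso [readVariantKeys()], [canonicalKeys()]
#' @export
setClass("VariantKeySet",
  representation(
    chrom = "character",
    pos = "integer",
    ref = "character",
    alt = "character",
    sourceLabel = "character",
    dropped = "integer"
  ),
  prototype(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), sourceLabel = "",
    dropped = c(non_snv = 0L, filtered = 0L, symbolic = 0L,
                invalid = 0L, duplicate = 0L)
  )
)

setValidity("VariantKeySet", function(object) {
  n <- length(object@chrom)
  if (length(object@pos) != n || length(object@ref) != n ||
      length(object@alt) != n)
    return("chrom, pos, ref and alt must have equal length")
  if (n == 0L) return(TRUE)
  if (anyNA(object@pos) || any(object@pos < 1L))
    return("positions must be >= 1")
  if (any(!nzchar(object@chrom)))
    return("chromosome labels must be non-empty")
  if (any(grepl("^chr", object@chrom, ignore.case = TRUE)))
    return("chromosome labels must be normalized (no 'chr' prefix)")
  if (any(object@ref == object@alt))
    return("ref and alt alleles must differ")
  if (any(grepl("[^ACGT]", object@ref)) || any(grepl("[^ACGT]", object@alt)))
    return("alleles must be uppercase strings over {A,C,G,T}")
  key <- paste(object@chrom, object@pos, object@ref, object@alt, sep = ":")
  if (anyDuplicated(key))
    return("duplicate variant keys are not allowed")
  TRUE
})

#' Encrypted store of hashed germline variant keys
#'
#' In-memory handle on a decrypted germline store: the set of digests of
#' canonical variant keys plus the protocol metadata needed to hash somatic
#' calls the same way. Only the encrypted file form ever touches disk; the
#' decrypted digest set lives exclusively in this object.
#'
#' @slot digests character vector of lowercase hex digests, sorted.
#' @slot hashProtocol `"SHA512"` or `"MD5"`.
#' @slot cipher `"AES"` or `"Blowfish"` (the cipher the file was sealed with).
#' @slot kdfIterations PBKDF2 iteration count recorded in the file header.
#' @slot path path the store was loaded from (informational).
#'
#' @seealso [buildStore()], [loadStore()], [countLeaks()]
#' @export
setClass("GermlineStore",
  representation(
    digests = "character",
    hashProtocol = "character",
    cipher = "character",
    kdfIterations = "integer",
    path = "character"
  )
)

setValidity("GermlineStore", function(object) {
  if (!object@hashProtocol %in% c("SHA512", "MD5"))
    return("hashProtocol must be SHA512 or MD5")
  if (!object@cipher %in% c("AES", "Blowfish"))
    return("cipher must be AES or Blowfish")
  want <- if (object@hashProtocol == "SHA512") 128L else 32L
  if (length(object@digests) && any(nchar(object@digests) != want))
    return(sprintf("all digests must be %d hex characters", want))
  TRUE
})

#' Leak report for one somatic submission
#'
#' @slot submissionLabel label of the scored submission.
#' @slot totalCalls number of distinct somatic keys considered.
#' @slot leakCount number of calls exactly matching a germline variant.
#' @slot leakKeys the leaked keys (populated in local mode only; empty in
#'   server mode, which reports counts and never positions).
#' @slot serverMode logical; `TRUE` when matched against an encrypted store.
#' @slot skippedRecords records dropped while reading the submission.
#' @slot threshold leak-count threshold for whole-submission rejection
#'   (`Inf` = report-only).
#' @slot rejected `TRUE` when `leakCount > threshold`.
#'
#' @seealso [countLeaks()], [locateLeaks()], [filterSubmission()]
#' @export
setClass("LeakReport",
  representation(
    submissionLabel = "character",
    totalCalls = "integer",
    leakCount = "integer",
    leakKeys = "VariantKeySet",
    serverMode = "logical",
    skippedRecords = "integer",
    threshold = "numeric",
    rejected = "logical"
  ),
  prototype(threshold = Inf, rejected = FALSE, serverMode = FALSE,
            skippedRecords = 0L)
)

setValidity("LeakReport", function(object) {
  if (object@leakCount < 0L || object@leakCount > object@totalCalls)
    return("leakCount must be between 0 and totalCalls")
  if (!object@serverMode && length(object@leakKeys) != object@leakCount)
    return("in local mode leakKeys must carry exactly leakCount keys")
  if (object@serverMode && length(object@leakKeys) != 0L)
    return("in server mode leakKeys must be empty")
  TRUE
})

#' Evaluation of a somatic prediction set against truth call sets
#'
#' Counts and metrics for one submission scored against the somatic truth
#' set, with germline leakage quantified against the germline truth set.
#' Precision is the fraction of submitted calls that are true somatic SNVs,
#' recall the fraction of true somatic SNVs recovered, and F1 their harmonic
#' mean. With zero predictions, precision (and hence F1) is defined as 0.
#'
#' @slot tp,fp,fn integer counts over distinct canonical keys.
#' @slot precision,recall,f1 metrics in `[0, 1]`.
#' @slot leakCount predicted keys exactly matching a germline truth variant.
#' @slot leakFractionOfCalls leakCount / total predicted calls (0 when none).
#' @slot leakFractionOfFp leakCount / fp (`NaN` when fp is 0).
#' @slot ambiguous keys present in both truth sets (counted as TP).
#'
#' @seealso [scoreCalls()], [classifyCalls()]
#' @export
setClass("EvaluationResult",
  representation(
    tp = "integer", fp = "integer", fn = "integer",
    precision = "numeric", recall = "numeric", f1 = "numeric",
    leakCount = "integer",
    leakFractionOfCalls = "numeric",
    leakFractionOfFp = "numeric",
    ambiguous = "integer"
  )
)

setValidity("EvaluationResult", function(object) {
  for (s in c("precision", "recall", "f1")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      return(sprintf("%s must be a single value in [0, 1]", s))
  }
  if (object@tp < 0L || object@fp < 0L || object@fn < 0L)
    return("tp, fp and fn must be non-negative")
  if (object@leakCount < 0L || object@leakCount > object@tp + object@fp)
    return("leakCount must not exceed the number of predictions")
  TRUE
})

#' Configuration of the synthetic tumour/normal simulator
#'
#' Parameters of the VCF-level emulation of a spike-in benchmark: germline
#' and somatic truth variants placed uniformly at random over a synthetic
#' genome, and simulated callers that recover somatic truth with a given
#' sensitivity, emit random false positives, and leak each germline variant
#' with a given probability (a desk-scale proxy for the effect of
#' infiltrating normal cells; no read-level simulation is performed).
#'
#' @slot nChroms number of chromosomes in the synthetic genome.
#' @slot chromLength length of each chromosome in bp.
#' @slot nGermline number of germline spike-ins.
#' @slot nSomatic number of somatic spike-ins.
#' @slot sensitivity probability a somatic truth variant is called.
#' @slot fpRate expected (Poisson) number of novel false-positive calls.
#' @slot leakRate probability each germline variant leaks into the calls.
#' @slot seed integer seed controlling truth-set generation.
#'
#' @seealso [SimulationConfig()], [simulateTruth()], [simulateCaller()]
#' @export
setClass("SimulationConfig",
  representation(
    nChroms = "integer", chromLength = "integer",
    nGermline = "integer", nSomatic = "integer",
    sensitivity = "numeric", fpRate = "numeric", leakRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  if (object@nChroms < 1L || object@chromLength < 1L)
    return("nChroms and chromLength must be positive")
  if (object@nGermline < 0L || object@nSomatic < 0L)
    return("spike-in counts must be non-negative")
  total <- as.double(object@nChroms) * as.double(object@chromLength)
  if (object@nGermline + object@nSomatic > total)
    return("requested spike-ins exceed available genome positions")
  if (object@sensitivity < 0 || object@sensitivity > 1)
    return("sensitivity must be in [0, 1]")
  if (object@leakRate < 0 || object@leakRate > 1)
    return("leakRate must be in [0, 1]")
  if (object@fpRate < 0)
    return("fpRate must be non-negative")
  TRUE
})

#' In-process leakage-checking session over encrypted stores
#'
#' Holds one or more decrypted [GermlineStore-class] objects, keyed by
#' tumour label, for the lifetime of the session. Mirrors the server-side
#' deployment: stores are decrypted once, held only in memory, and
#' submissions are matched against them by label. Closing the session
#' discards the digest sets and refuses further queries.
#'
#' @slot env environment holding the loaded stores and the open/closed flag.
#' @seealso [leakSession()], [queryLeaks()], [closeSession()]
#' @export
setClass("LeakSession", representation(env = "environment"))
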