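# Online leakage checking: count, locate and strip germline leaks from
# somatic SNV prediction sets. A somatic call is a leak exactly when its
# chromosome, position, reference allele and alternate allele all equal a
# germline variant's. Server mode works against an encrypted digest store
# and reports counts only; local mode has plaintext germline access and
# may report the leaked positions themselves.

.leakReport <- function(label, totalCalls, leakKeys = VariantKeySet(),
                        leakCount = length(leakKeys), serverMode = FALSE,
                        skipped = 0L, threshold = Inf) {
  new("LeakReport", submissionLabel = label,
      totalCalls = as.integer(totalCalls), leakCount = as.integer(leakCount),
      leakKeys = leakKeys, serverMode = serverMode,
      skippedRecords = as.integer(skipped), threshold = threshold,
      rejected = leakCount > threshold)
}

#' @rdname accessors
#' @export
setMethod("leakCount", "LeakReport", function(x) x@leakCount)

#' @rdname accessors
#' @export
setMethod("leakKeys", "LeakReport", function(x) x@leakKeys)

#' @rdname accessors
#' @export
setMethod("isRejected", "LeakReport", function(x) x@rejected)

#' @describeIn LeakReport number of distinct somatic calls considered.
#' @param x a `LeakReport`.
#' @export
setMethod("length", "LeakReport", function(x) x@totalCalls)

setMethod("show", "LeakReport", function(object) {
  cat(sprintf("LeakReport [%s]: %d leak%s in %d call%s (%s mode)%s\n",
              object@submissionLabel, object@leakCount,
              if (object@leakCount == 1L) "" else "s",
              object@totalCalls,
              if (object@totalCalls == 1L) "" else "s",
              if (object@serverMode) "server" else "local",
              if (object@rejected) " -- REJECTED: exceeds leak threshold"
              else ""))
})

#' Count germline leaks against an encrypted store (server mode)
#'
#' Hashes each distinct somatic call key under the store's hash protocol
#' and counts exact matches against the store's digest set, entirely in
#' memory. The report carries the count only — never positions or alleles —
#' which is what allows this check to run on a public-facing server.
#'
#' @param somatic a [VariantKeySet-class] of somatic predictions (already
#'   deduplicated by construction).
#' @param store a loaded [GermlineStore-class].
#' @param threshold leak count above which the submission is flagged
#'   rejected (default `Inf`: report-only).
#' @return a [LeakReport-class] with empty `leakKeys`.
#' @examples
#' g <- VariantKeySet(chrom = "1", pos = c(100, 200), ref = "A", alt = "G")
#' s <- VariantKeySet(chrom = "1", pos = c(100, 300), ref = "A", alt = "G")
#' store <- tempfile(fileext = ".store")
#' buildStore(g, "secret", store)
#' countLeaks(s, loadStore(store, "secret"))   # 1 leak among 2 calls
#' @export
countLeaks <- function(somatic, store, threshold = Inf) {
  stopifnot(is(somatic, "VariantKeySet"), is(store, "GermlineStore"))
  digests <- hashKey(serializeKey(somatic), hashProtocol(store))
  n <- sum(digests %in% store@digests)
  .leakReport(sourceLabel(somatic), totalCalls = length(somatic),
              leakCount = n, serverMode = TRUE, threshold = threshold,
              skipped = sum(droppedRecords(somatic)))
}

#' Locate germline leaks with plaintext germline access (local mode)
#'
#' Computes the exact set of somatic calls that match a germline variant,
#' by plaintext set intersection of canonical keys. Only for local use by
#' the data owner; the returned report lists the leaked keys, sorted by
#' chromosome and position.
#'
#' @param somaticVcf path to the somatic prediction VCF.
#' @param germlineVcf path to the plaintext germline truth VCF.
#' @param threshold as in [countLeaks()].
#' @param quiet passed to [readVariantKeys()].
#' @return a [LeakReport-class] with `leakKeys` populated.
#' @export
locateLeaks <- function(somaticVcf, germlineVcf, threshold = Inf,
                        quiet = TRUE) {
  somatic <- readVariantKeys(somaticVcf, quiet = quiet)
  germline <- readVariantKeys(germlineVcf, quiet = quiet)
  leaks <- keyIntersect(somatic, germline)
  .leakReport(sourceLabel(somatic), totalCalls = length(somatic),
              leakKeys = leaks, serverMode = FALSE, threshold = threshold,
              skipped = sum(droppedRecords(somatic)))
}

#' Strip germline leaks from a submission VCF
#'
#' Locates the leaked calls (local mode) and rewrites the submission with
#' those data lines removed, leaving all other bytes untouched. Re-running
#' [locateLeaks()] on the output yields zero leaks. When `threshold` is
#' finite and exceeded, the report is flagged rejected — the
#' whole-submission rejection policy — but the filtered file is still
#' written so the caller can decide.
#'
#' @inheritParams locateLeaks
#' @param outVcf path for the filtered VCF.
#' @param listLeaks optional path; when given, the leaked keys are written
#'   there as a TSV with columns `chrom`, `pos`, `ref`, `alt` (1-based).
#' @return a [LeakReport-class] (local mode).
#' @export
filterSubmission <- function(somaticVcf, germlineVcf, outVcf,
                             threshold = Inf, listLeaks = NULL,
                             quiet = TRUE) {
  report <- locateLeaks(somaticVcf, germlineVcf, threshold = threshold,
                        quiet = quiet)
  writeFilteredVcf(somaticVcf, leakKeys(report), outVcf, quiet = quiet)
  if (!is.null(listLeaks))
    utils::write.table(as.data.frame(leakKeys(report)), listLeaks,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  report
}

#' Open a leakage-checking session over one or more encrypted stores
#'
#' Loads every store once, decrypting the digest sets into memory for the
#' session's lifetime, and routes submissions to stores by tumour label.
#' This mirrors a server deployment that checks many submissions against
#' several tumours' germline sets without re-reading the stores.
#'
#' @param storePaths named character vector of store file paths; names are
#'   the tumour labels used to route queries.
#' @param passphrase passphrase, or a function returning one (so secrets
#'   can come from a prompt or environment rather than code).
#' @return a [LeakSession-class].
#' @examples
#' \dontrun{
#' ses <- leakSession(c(IS1 = "is1.store", IS2 = "is2.store"),
#'                    function() Sys.getenv("LEAKGUARD_PASSPHRASE"))
#' queryLeaks(ses, "IS1", "submission.vcf")
#' closeSession(ses)
#' }
#' @export
leakSession <- function(storePaths, passphrase) {
  if (is.null(names(storePaths)) || any(!nzchar(names(storePaths))))
    stop("storePaths must be a named vector of tumour labels")
  secret <- if (is.function(passphrase)) passphrase() else passphrase
  env <- new.env(parent = emptyenv())
  env$stores <- lapply(storePaths, loadStore, passphrase = secret)
  env$open <- TRUE
  new("LeakSession", env = env)
}

#' Query a session with one somatic submission
#'
#' @param session a [LeakSession-class].
#' @param tumourLabel which store to match against.
#' @param somatic a [VariantKeySet-class] or a path to a somatic VCF.
#' @param threshold as in [countLeaks()].
#' @return a [LeakReport-class] (server mode: counts only).
#' @export
queryLeaks <- function(session, tumourLabel, somatic, threshold = Inf) {
  stopifnot(is(session, "LeakSession"))
  if (!isTRUE(session@env$open))
    stop("session is closed; no further queries accepted")
  if (!tumourLabel %in% names(session@env$stores))
    stop("unknown tumour label: ", tumourLabel)
  if (is.character(somatic))
    somatic <- readVariantKeys(somatic, quiet = TRUE)
  countLeaks(somatic, session@env$stores[[tumourLabel]],
             threshold = threshold)
}

#' Close a leakage-checking session
#'
#' Discards the decrypted digest sets; subsequent queries are refused.
#'
#' @param session a [LeakSession-class].
#' @return (invisibly) `TRUE`.
#' @export
closeSession <- function(session) {
  stopifnot(is(session, "LeakSession"))
  session@env$stores <- NULL
  session@env$open <- FALSE
  invisible(TRUE)
}

setMethod("show", "LeakSession", function(object) {
  if (isTRUE(object@env$open)) {
    cat(sprintf("LeakSession: open, %d store%s (%s)\n",
                length(object@env$stores),
                if (length(object@env$stores) == 1L) "" else "s",
                paste(names(object@env$stores), collapse = ", ")))
  } else cat("LeakSession: closed\n")
})
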