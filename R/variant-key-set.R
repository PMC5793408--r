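# Canonical variant identity: normalization, construction, set algebra.

.normalizeChrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

# order chromosomes 1..22 numerically, then X, Y, MT/M, then others
.chromRank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  rank <- ifelse(!is.na(num), num,
                 ifelse(chrom == "X", 100,
                        ifelse(chrom == "Y", 101,
                               ifelse(chrom %in% c("MT", "M"), 102, 1000))))
  rank
}

.keyOrder <- function(chrom, pos, ref, alt) {
  order(.chromRank(chrom), chrom, pos, ref, alt)
}

#' Construct a set of canonical variant keys
#'
#' Normalizes (strips any leading `chr` prefix, uppercases alleles),
#' deduplicates, and sorts the given variant records into a
#' [VariantKeySet-class].
#'
#' @param chrom chromosome labels.
#' @param pos 1-based positions (coerced to integer).
#' @param ref,alt alleles (A/C/G/T; lowercase soft-masked alleles accepted
#'   and uppercased).
#' @param sourceLabel free-text provenance string.
#' @param dropped named integer vector of ingest drop counts (used by
#'   [readVariantKeys()]); duplicates removed here are added to its
#'   `duplicate` entry.
#' @return a [VariantKeySet-class].
#' @examples
#' VariantKeySet(chrom = c("chr1", "1"), pos = c(100, 100),
#'               ref = c("a", "A"), alt = c("g", "G"))  # one key: 1:100:A:G
#' @export
VariantKeySet <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          sourceLabel = "",
                          dropped = c(non_snv = 0L, filtered = 0L,
                                      symbolic = 0L, invalid = 0L,
                                      duplicate = 0L)) {
  chrom <- .normalizeChrom(chrom)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  if (n > 0L) {
    lens <- c(length(chrom), length(pos), length(ref), length(alt))
    if (any(!lens %in% c(1L, n)))
      stop("chrom, pos, ref and alt must have length 1 or a common length")
    chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
    ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  }
  key <- paste(chrom, pos, ref, alt, sep = ":")
  dup <- duplicated(key)
  if (any(dup)) {
    chrom <- chrom[!dup]; pos <- pos[!dup]; ref <- ref[!dup]; alt <- alt[!dup]
    dropped["duplicate"] <- dropped["duplicate"] + sum(dup)
  }
  o <- .keyOrder(chrom, pos, ref, alt)
  new("VariantKeySet", chrom = chrom[o], pos = pos[o], ref = ref[o],
      alt = alt[o], sourceLabel = as.character(sourceLabel),
      dropped = dropped)
}

.keySetFromCanonical <- function(canonical, sourceLabel = "") {
  if (!length(canonical))
    return(VariantKeySet(sourceLabel = sourceLabel))
  parts <- strsplit(canonical, ":", fixed = TRUE)
  VariantKeySet(chrom = vapply(parts, `[`, "", 1L),
                pos = as.integer(vapply(parts, `[`, "", 2L)),
                ref = vapply(parts, `[`, "", 3L),
                alt = vapply(parts, `[`, "", 4L),
                sourceLabel = sourceLabel)
}

#' @describeIn VariantKeySet number of distinct keys in the set.
#' @param x a `VariantKeySet`.
#' @export
setMethod("length", "VariantKeySet", function(x) length(x@chrom))

#' @rdname canonicalKeys
#' @export
setMethod("canonicalKeys", "VariantKeySet", function(x) {
  if (!length(x)) return(character())
  paste(x@chrom, x@pos, x@ref, x@alt, sep = ":")
})

#' Accessors for leakguard objects
#'
#' @param x a leakguard S4 object.
#' @name accessors
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setMethod("sourceLabel", "VariantKeySet", function(x) x@sourceLabel)

#' @rdname accessors
#' @export
setMethod("droppedRecords", "VariantKeySet", function(x) x@dropped)

#' @describeIn VariantKeySet keys as a data.frame with columns
#'   `chrom`, `pos`, `ref`, `alt`.
#' @param row.names,optional,... passed on conventions of the generic;
#'   ignored.
#' @export
setMethod("as.data.frame", "VariantKeySet",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(chrom = x@chrom, pos = x@pos, ref = x@ref, alt = x@alt,
               stringsAsFactors = FALSE)
  })

setMethod("show", "VariantKeySet", function(object) {
  cat(sprintf("VariantKeySet with %d key%s", length(object),
              if (length(object) == 1L) "" else "s"))
  if (nzchar(object@sourceLabel))
    cat(sprintf(" [%s]", object@sourceLabel))
  cat("\n")
  n <- length(object)
  if (n) {
    shown <- head(canonicalKeys(object), 5L)
    cat("  ", paste(shown, collapse = ", "),
        if (n > 5L) sprintf(", ... (%d more)", n - 5L) else "", "\n",
        sep = "")
  }
  drops <- object@dropped[object@dropped > 0L]
  if (length(drops))
    cat("  dropped on ingest: ",
        paste(sprintf("%s=%d", names(drops), drops), collapse = ", "),
        "\n", sep = "")
})

#' Set algebra over variant key sets
#'
#' Intersection, difference and union over the canonical keys of two
#' [VariantKeySet-class] objects.
#'
#' @param x,y `VariantKeySet` objects.
#' @return a `VariantKeySet`.
#' @export
keyIntersect <- function(x, y) {
  .keySetFromCanonical(intersect(canonicalKeys(x), canonicalKeys(y)),
                       sourceLabel = x@sourceLabel)
}

#' @rdname keyIntersect
#' @export
keySetdiff <- function(x, y) {
  .keySetFromCanonical(setdiff(canonicalKeys(x), canonicalKeys(y)),
                       sourceLabel = x@sourceLabel)
}

#' @rdname keyIntersect
#' @export
keyUnion <- function(x, y) {
  .keySetFromCanonical(union(canonicalKeys(x), canonicalKeys(y)),
                       sourceLabel = x@sourceLabel)
}
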