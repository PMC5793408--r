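#' Canonical serialization of variant keys
#'
#' Serializes each variant key as `"chrom:pos:ref:alt"` — single colon
#' delimiters, no whitespace, position in base 10 with no leading zeros.
#' The serialization is injective over valid keys; it is the exact byte
#' string that gets hashed when building or querying a germline store.
#'
#' @param x a [VariantKeySet-class].
#' @return character vector, one canonical string per key, in set order.
#' @examples
#' ks <- VariantKeySet(chrom = "1", pos = 12345, ref = "A", alt = "G")
#' canonicalKeys(ks)   # "1:12345:A:G"
#' @export
setGeneric("canonicalKeys", function(x) standardGeneric("canonicalKeys"))

#' @rdname accessors
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))

#' @rdname accessors
#' @export
setGeneric("droppedRecords", function(x) standardGeneric("droppedRecords"))

#' @rdname accessors
#' @export
setGeneric("leakCount", function(x) standardGeneric("leakCount"))

#' @rdname accessors
#' @export
setGeneric("leakKeys", function(x) standardGeneric("leakKeys"))

#' @rdname accessors
#' @export
setGeneric("isRejected", function(x) standardGeneric("isRejected"))

#' @rdname accessors
#' @export
setGeneric("digestCount", function(x) standardGeneric("digestCount"))

#' @rdname accessors
#' @export
setGeneric("hashProtocol", function(x) standardGeneric("hashProtocol"))

#' @rdname accessors
#' @export
setGeneric("cipherName", function(x) standardGeneric("cipherName"))
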