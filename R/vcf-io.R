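# Line-level VCF ingest and byte-preserving filtered rewrite.
#
# Filtering must drop exactly the leaked data lines and leave every other
# byte of the submission untouched, and parse errors must name the
# offending line; both requirements make this a line-oriented pass rather
# than a matrix ingest through a VCF reader.

.readVcfLines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# Tokenize all data lines at once; parse errors carry the 1-based line
# number within the file. Returns per-record columns with multi-allelic
# ALT fields still unsplit.
.parseDataLines <- function(lines, lineNumbers) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    i <- which(nf < 5L)[1L]
    stop(sprintf("malformed VCF line %d: expected at least 5 tab-separated fields, found %d",
                 lineNumbers[i], nf[i]), call. = FALSE)
  }
  getCol <- function(j) vapply(fields, `[`, "", j)
  pos <- suppressWarnings(as.integer(getCol(2L)))
  if (anyNA(pos) || any(pos < 1L)) {
    i <- which(is.na(pos) | pos < 1L)[1L]
    stop(sprintf("malformed VCF line %d: POS '%s' is not a positive integer",
                 lineNumbers[i], getCol(2L)[i]), call. = FALSE)
  }
  list(chrom = .normalizeChrom(getCol(1L)),
       pos = pos,
       ref = toupper(getCol(4L)),
       alt = toupper(getCol(5L)),
       filter = ifelse(nf >= 7L, vapply(fields, function(f)
         if (length(f) >= 7L) f[7L] else ".", ""), "."))
}

.isSymbolicAllele <- function(alt) {
  !nzchar(alt) | grepl("[<>\\[\\]]", alt) | alt %in% c(".", "*") |
    grepl("[^ACGTN]", alt)
}

#' Read canonical variant keys from a VCF file
#'
#' Parses a VCF 4.x file (plain or gzip-compressed), normalizes each record
#' (strip `chr` prefix, uppercase alleles), splits multi-allelic ALT fields
#' into one key per alternate allele, and returns the deduplicated
#' [VariantKeySet-class]. Genotype columns are ignored. Symbolic and
#' breakend ALT alleles (`<DEL>`, `]]`, `.`, `*`) are always dropped.
#' Counts of dropped records are reported via [message()] and carried on
#' the returned object (see [droppedRecords()]).
#'
#' @param path path to a VCF file (`.vcf` or `.vcf.gz`).
#' @param snvOnly drop records that are not single-nucleotide substitutions
#'   (default `TRUE`; the match rule is defined for SNVs).
#' @param passOnly drop records whose FILTER is neither `PASS` nor `.`
#'   (default `FALSE`: submissions are final call sets and ingested whole).
#' @param label provenance label stored on the result (defaults to the
#'   file name).
#' @param quiet suppress the drop-count message.
#' @return a [VariantKeySet-class].
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c("##fileformat=VCFv4.2",
#'              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
#'              "chr1\t12345\t.\tA\tG,T\t.\tPASS\t."), vcf)
#' ks <- readVariantKeys(vcf)
#' canonicalKeys(ks)  # "1:12345:A:G" "1:12345:A:T"
#' @export
readVariantKeys <- function(path, snvOnly = TRUE, passOnly = FALSE,
                            label = basename(path), quiet = FALSE) {
  lines <- .readVcfLines(path)
  isHeader <- startsWith(lines, "#")
  body <- which(!isHeader & nzchar(lines))
  drops <- c(non_snv = 0L, filtered = 0L, symbolic = 0L, invalid = 0L,
             duplicate = 0L)
  chrom <- character(); pos <- integer(); ref <- character(); alt <- character()
  if (length(body)) {
    rec <- .parseDataLines(lines[body], body)
    keepRec <- rep(TRUE, length(body))
    if (passOnly) {
      failed <- !rec$filter %in% c("PASS", ".")
      drops["filtered"] <- sum(failed)
      keepRec <- !failed
    }
    # one row per (record, alt allele)
    altList <- strsplit(rec$alt[keepRec], ",", fixed = TRUE)
    nAlt <- lengths(altList)
    idx <- rep(which(keepRec), nAlt)
    chrom <- rec$chrom[idx]; pos <- rec$pos[idx]; ref <- rec$ref[idx]
    alt <- unlist(altList, use.names = FALSE)
    if (length(alt)) {
      symbolic <- .isSymbolicAllele(alt)
      invalid <- !symbolic & (grepl("[^ACGT]", ref) | grepl("[^ACGT]", alt) |
                                ref == alt)
      nonSnv <- if (snvOnly) {
        !symbolic & !invalid & (nchar(ref) != 1L | nchar(alt) != 1L)
      } else rep(FALSE, length(alt))
      drops["symbolic"] <- sum(symbolic)
      drops["invalid"] <- sum(invalid)
      drops["non_snv"] <- sum(nonSnv)
      keep <- !(symbolic | invalid | nonSnv)
      chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]
      alt <- alt[keep]
    }
  }
  ks <- VariantKeySet(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      sourceLabel = label, dropped = drops)
  if (!quiet && any(droppedRecords(ks) > 0L)) {
    d <- droppedRecords(ks)
    message(sprintf("readVariantKeys[%s]: dropped %s", label,
                    paste(sprintf("%s=%d", names(d)[d > 0L], d[d > 0L]),
                          collapse = ", ")))
  }
  ks
}

#' Rewrite a VCF with leaked variants removed
#'
#' Copies `path` to `out`, omitting every data line at least one of whose
#' canonical keys (one per ALT allele) is present in `leaks`. The header
#' and all retained data lines are preserved byte-for-byte. This is the
#' publication-preparation step: strip the germline leaks, change nothing
#' else.
#'
#' @param path input VCF (`.vcf` or `.vcf.gz`).
#' @param leaks a [VariantKeySet-class] of keys to remove.
#' @param out output path (gzip-compressed when it ends in `.gz`).
#' @param quiet suppress the removed-line message.
#' @return (invisibly) the number of data lines written, with attribute
#'   `removed` giving the number of lines omitted.
#' @export
writeFilteredVcf <- function(path, leaks, out, quiet = FALSE) {
  stopifnot(is(leaks, "VariantKeySet"))
  lines <- .readVcfLines(path)
  isHeader <- startsWith(lines, "#")
  leakSet <- canonicalKeys(leaks)
  keep <- rep(TRUE, length(lines))
  removed <- 0L
  body <- which(!isHeader & nzchar(lines))
  if (length(body) && length(leakSet)) {
    rec <- .parseDataLines(lines[body], body)
    altList <- strsplit(rec$alt, ",", fixed = TRUE)
    nAlt <- lengths(altList)
    idx <- rep(seq_along(body), nAlt)
    keys <- paste(rec$chrom[idx], rec$pos[idx], rec$ref[idx],
                  unlist(altList, use.names = FALSE), sep = ":")
    hit <- unique(idx[keys %in% leakSet])
    keep[body[hit]] <- FALSE
    removed <- length(hit)
  }
  con <- if (grepl("\\.gz$", out)) gzfile(out, "wb") else file(out, "wb")
  tryCatch(writeLines(lines[keep], con, useBytes = TRUE),
           finally = close(con))
  written <- sum(keep & !isHeader & nzchar(lines))
  if (!quiet && removed > 0L)
    message(sprintf("writeFilteredVcf: removed %d leaked line%s, wrote %d data line%s",
                    removed, if (removed == 1L) "" else "s",
                    written, if (written == 1L) "" else "s"))
  invisible(structure(written, removed = removed))
}

#' Write a variant key set as a minimal VCF
#'
#' Serializes a [VariantKeySet-class] as a minimal valid VCF 4.2 file
#' (CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO; no genotypes). Used by
#' the simulator to emit truth sets and synthetic submissions.
#'
#' @param keys a [VariantKeySet-class].
#' @param path output path (gzip-compressed when it ends in `.gz`).
#' @param source value for the `##source` header line.
#' @return (invisibly) the number of data lines written.
#' @export
writeVariantVcf <- function(keys, path, source = "leakguard") {
  stopifnot(is(keys, "VariantKeySet"))
  header <- c("##fileformat=VCFv4.2",
              sprintf("##source=%s", source),
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  body <- if (length(keys)) {
    paste(keys@chrom, keys@pos, ".", keys@ref, keys@alt, ".", "PASS", ".",
          sep = "\t")
  } else character()
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  tryCatch(writeLines(c(header, body), con), finally = close(con))
  invisible(length(body))
}
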