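# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# write a VCF with the standard 8-column header and the given data lines
writeTestVcf <- function(dataLines, path = tempfile(fileext = ".vcf"),
                         extraHeader = character()) {
  writeLines(c("##fileformat=VCFv4.2",
               extraHeader,
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", sep = "\t"),
               dataLines), path)
  path
}

vcfLine <- function(chrom, pos, ref, alt, filter = "PASS", id = ".") {
  paste(chrom, pos, id, ref, alt, ".", filter, ".", sep = "\t")
}

# random distinct SNV keys drawn from the current RNG stream
randomKeySet <- function(n, label = "random", maxPos = 100000L) {
  if (n == 0L) return(VariantKeySet(sourceLabel = label))
  bases <- c("A", "C", "G", "T")
  pos <- sample.int(maxPos, n)          # distinct positions => distinct keys
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  VariantKeySet(chrom = as.character(sample(1:22, n, replace = TRUE)),
                pos = pos, ref = ref, alt = alt, sourceLabel = label)
}

# split a key set into two by index
splitKeys <- function(keys, idx) {
  df <- as.data.frame(keys)
  list(
    a = VariantKeySet(df$chrom[idx], df$pos[idx], df$ref[idx], df$alt[idx]),
    b = VariantKeySet(df$chrom[-idx], df$pos[-idx], df$ref[-idx],
                      df$alt[-idx])
  )
}

# a seven-data-line somatic VCF with two lines matching leaked germline keys
fixtureSubmission <- function() {
  germline <- VariantKeySet(
    chrom = c("1", "1", "2", "3", "X"),
    pos = c(100L, 250L, 40L, 77L, 900L),
    ref = c("A", "C", "G", "T", "A"),
    alt = c("G", "T", "A", "C", "C"))
  somaticLines <- c(
    vcfLine("1", 100, "A", "G"),    # leak
    vcfLine("1", 150, "C", "A"),
    vcfLine("2", 40, "G", "A"),     # leak
    vcfLine("2", 41, "G", "A"),
    vcfLine("5", 7, "T", "G"),
    vcfLine("9", 1234, "A", "T"),
    vcfLine("X", 901, "A", "C"))
  list(germline = germline,
       somaticVcf = writeTestVcf(somaticLines),
       germlineVcf = local({
         p <- tempfile(fileext = ".vcf")
         writeVariantVcf(germline, p)
         p
       }),
       leakKeys = c("1:100:A:G", "2:40:G:A"))
}

# brute-force mid-rank Spearman: ranks computed by direct enumeration
bruteSpearman <- function(x, y) {
  midRank <- function(v) {
    vapply(seq_along(v), function(i) {
      less <- sum(v < v[i])
      ties <- sum(v == v[i])
      less + (ties + 1) / 2
    }, 0)
  }
  rx <- midRank(x); ry <- midRank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
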