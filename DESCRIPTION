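Package: leakguard
Title: Privacy-Preserving Detection and Removal of Germline Leakage in
    Somatic SNV Call Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Somatic single-nucleotide variant (SNV) prediction pipelines
    occasionally report true germline polymorphisms as somatic calls, a
    failure mode known as germline leakage that can make nominally
    de-identified tumour call sets re-identifiable. leakguard counts,
    locates and strips leaked germline variants from somatic SNV VCFs.
    The germline truth set is stored only as an encrypted file of hashed
    variant keys, so leakage checks can run on a public-facing server
    without ever exposing genotypes. The package also ships the
    benchmarking layer used to study leakage across a calling challenge
    cohort (precision/recall/F1 scoring against spiked-in truth sets,
    per-tumour leak medians, F1-versus-leak Spearman correlation,
    best-per-team selection, leaked-variant recurrence) and a synthetic
    VCF-level tumour/normal generator so the whole stack is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    openssl,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    digest,
    vcfR,
    yaml
NeedsCompilation: yes
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
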