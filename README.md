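# leakguard

Privacy-preserving detection, quantification and removal of **germline
leakage** in somatic SNV call sets.

## The problem

Somatic single-nucleotide variants (SNVs) are acquired by tumour cells
and absent from the patient's inherited genome, so somatic call sets
are often considered safe to share openly. But tumour/normal calling
pipelines are imperfect: true germline polymorphisms occasionally slip
into the somatic predictions. Since roughly 30–80 independent SNPs are
enough to re-identify a person, every leaked germline variant erodes
the de-identification that open release relies on. Data providers who
host somatic predictions — benchmarking challenges, cloud SNV
databases — need to count and strip these leaks at upload time, on a
server that must never hold the patient's germline genotypes in usable
form.

## The method

Everything operates on canonical variant keys
`(chrom, pos, ref, alt)`; a somatic call is a **leak** iff it exactly
matches a germline variant in all four fields. Offline, the data owner
hashes each germline key's serialization `chrom:pos:ref:alt`
(SHA-512 by default, MD5 supported) and ships only the encrypted digest
set (AES-256-CBC default or Blowfish-CBC, key via PBKDF2, encrypt-then-MAC).
Online, the server decrypts the digests in memory, hashes each incoming
somatic call the same way, and reports the number of matches — counts
only, never positions. With plaintext germline access (local mode) the
leaked calls can also be located and removed, rewriting the submission
byte-identically except for the dropped lines.

Submissions are scored challenge-style against spiked-in truth sets,
over distinct keys:

```
precision = TP / (TP + FP)    recall = TP / (TP + FN)
F1 = 2 * precision * recall / (precision + recall)
```

with cohort statistics on top: per-tumour leak medians and ranges,
Spearman correlation (mid-ranks) of F1 versus leak count, best
submission per team (highest F1; ties by fewest leaks, then submission
id), and leaked-variant recurrence across submissions. A synthetic
spike-in generator (`simulateTruth()` / `simulateCaller()` /
`simulateCohort()`) emulates the whole benchmark at the VCF level so
the stack is testable without any external data.

## Worked example

```r
library(leakguard)

cfg   <- SimulationConfig(seed = 42L)        # 5000 germline + 4000 somatic spike-ins
truth <- simulateTruth(cfg)

germStore <- tempfile(fileext = ".store")
buildStore(truth$germline, passphrase = "demo-secret", germStore)

sub   <- simulateCaller(truth$somatic, truth$germline, cfg, callerSeed = 7L)
store <- loadStore(germStore, "demo-secret")
store
#> GermlineStore: 5000 SHA512 digests, sealed with AES [...]

countLeaks(sub$calls, store)                 # server mode: counts only
#> LeakReport [caller_7]: 21 leaks in 3918 calls (server mode)

scoreCalls(sub$calls, truth$somatic, truth$germline)
#> EvaluationResult: TP=3596 FP=322 FN=404 | precision=0.9178 recall=0.8990 F1=0.9083 | leaks=21
```

So this simulated caller made 3918 distinct calls, of which 21 exactly
match germline variants — enough to worry about for open release. With
local (plaintext) germline access the leaks can be stripped:

```r
writeVariantVcf(sub$calls, "sub.vcf")
writeVariantVcf(truth$germline, "germ.vcf")
filterSubmission("sub.vcf", "germ.vcf", "clean.vcf")
#> LeakReport [sub.vcf]: 21 leaks in 3918 calls (local mode)
leakCount(locateLeaks("clean.vcf", "germ.vcf"))
#> [1] 0
```

The filtered file is byte-identical to the input except for the 21
removed data lines, and re-checking it finds zero leaks.

See the vignette (`vignettes/germline-leakage-control.Rmd`) for the
store format, the scoring conventions and what the simulator does and
does not emulate.

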