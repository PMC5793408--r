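---
title: "Controlling germline leakage in somatic SNV call sets"
author: "leakguard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlling germline leakage in somatic SNV call sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leakguard)
```

## The problem

Somatic single-nucleotide variants (SNVs) arise in tumour cells and are
absent from a patient's inherited genome, so a set of somatic SNV calls
is, in principle, not identifying and can be shared openly. In practice,
somatic callers work by subtracting the matched normal from the tumour,
and that subtraction is imperfect: true germline polymorphisms
occasionally survive into the somatic call set. This *germline leakage*
matters because a few dozen independent SNPs suffice to re-identify an
individual; a leaked germline variant is exactly such a SNP. A data
provider who wants to offer barrier-free access to somatic predictions
therefore needs to (i) measure how much each call set leaks, and (ii)
strip the leaked calls before release — ideally on the server that
receives uploads, without that server ever holding the patient's
germline genotypes in usable form.

leakguard implements both halves: a privacy-preserving leakage check
that runs against an encrypted file of hashed germline variant keys, and
the benchmarking machinery (precision/recall/F1 scoring, cohort
statistics, a synthetic spike-in generator) needed to study leakage
across many callers.

## Variant identity and the exact-match rule

Every operation works on canonical variant keys: chromosome label with
any `chr` prefix stripped, 1-based position, uppercase reference allele,
uppercase alternate allele. A somatic call is a leak **iff** all four
fields equal a germline variant's — a call at a germline position with a
different alternate allele is not a leak. Keys serialize as
`"chrom:pos:ref:alt"`, which is injective over valid keys, and sets of
keys are deduplicated on construction, so every count in the package is
a count of distinct variants. Multi-allelic VCF records are split into
one key per alternate allele: the match rule is defined per substitution
and a half-matching multi-allelic record must not block or hide a leak.
Symbolic and breakend alleles (`<DEL>`, `]]`, `*`, `.`) are dropped with
a counted warning; they have no SNV identity. All drop counts are
reported via R conditions and carried on the returned object.

## The encrypted germline store

The germline truth set never travels in plaintext. `buildStore()`
serializes each key, hashes it (SHA-512 by default, MD5 supported), and
writes the digest set encrypted under a passphrase-derived key;
`loadStore()` reverses this entirely in memory. Design choices worth
knowing:

* **Unsalted key digests.** Digests of the same variant must agree
  across independently built stores and sessions, so `hashKey()` is the
  plain digest of the canonical string. The residual risk — an adversary
  hashing a dictionary of known common variants and matching — is
  inherent to any comparable-digest design; the file-level encryption
  exists precisely as the second layer against casual exposure of the
  digest list.
* **Key derivation.** PBKDF2-HMAC-SHA256 with a fresh 16-byte salt and a
  recorded iteration count (default 10000) derives 80 bytes: a 32-byte
  cipher key, a 32-byte MAC key and a 16-byte passphrase verifier. The
  verifier lets a wrong passphrase fail fast as a credentials error,
  distinct from file corruption.
* **Encrypt-then-MAC.** The payload (digests concatenated in sorted
  order) is encrypted with AES-256-CBC (default) or Blowfish-CBC, and an
  HMAC-SHA256 over header plus ciphertext makes any tampering or
  truncation an integrity error before any decrypted byte is trusted.
  Blowfish is provided for parity with the established protocol choices
  in this niche; since modern crypto libraries have retired it, the
  package carries its own implementation of the cipher (validated
  against the published known-answer vectors; its P/S-box constants are
  the hex digits of pi, as the algorithm defines).
* **Canonical payload.** Sorted digests mean two stores of the same
  variant set differ only by salt/IV. Fresh salt/IV are drawn from the
  OS entropy source on every build, so file bytes differ across builds
  while decrypting identically; passing `saltMaterial` makes a build
  fully deterministic when reproducible bytes are wanted.

The store format is versioned and documented byte-by-byte in
`R/crypto-store.R`. It is a clean-room layout: files are not
interchangeable with any other tool's store format.

## Server mode versus local mode

`countLeaks()` (and the session wrapper `leakSession()`/`queryLeaks()`)
is *server mode*: it hashes the submission's keys and counts matches
against the store, returning **counts only** — returning positions would
defeat the purpose, since each reported position would itself be a
germline variant. `locateLeaks()` and `filterSubmission()` are *local
mode*: they require the plaintext germline VCF and may therefore return
the leaked keys themselves and rewrite the submission without them. The
filtered rewrite is byte-preserving for the header and every retained
line, and removing a line is driven purely by the exact-match rule, so
filtering is idempotent and re-counting a filtered file yields zero.

Whole-submission rejection is available as a configurable leak-count
`threshold` on the reports (default `Inf`, i.e. report-only): the
literature describes both per-call removal and rejecting entire
submissions, without fixing a threshold, so the policy is left to the
operator and the report only carries the flag.

## Scoring and its conventions

`scoreCalls()` computes, over distinct keys: precision = TP/(TP+FP),
recall = TP/(TP+FN), F1 = their harmonic mean, plus the leak count and
the leak fractions of total calls and of false positives. Specificity
is deliberately absent — at whole-genome scale the true-negative count
is astronomically large and would render it meaningless. Conventions:
with zero predictions, precision := 0 and hence F1 := 0 (keeps cohort
statistics total); a key present in both truth sets counts once as a
true positive and is flagged `ambiguous` (a well-formed benchmark never
produces one, and the simulator guarantees disjoint truth sets).

## Cohort statistics

`summarizeCohort()` reports per-tumour and overall leak medians and
ranges and the per-tumour Spearman correlation between F1 and leak
count. Choices that were genuinely open and are fixed here:

* **Median**: mean-of-central-pair for even n (the standard convention;
  with leak counts dominated by 0s and 1s the median is robust anyway).
* **Spearman**: Pearson correlation of mid-ranks (average ranks on
  ties), via `stats::cor(method = "spearman")`; only the coefficient is
  reported, no permutation p-values. It is undefined (error) for
  constant vectors and `NA` in summaries when a group is too small.
* **Best per team** (`bestPerTeam()`): highest F1 per (tumour, team);
  ties broken by smallest leak count, then lexicographically smallest
  submission id — an arbitrary but documented, reproducible rule.
* **Administrator submissions** are kept in all statistics (published
  cohort counts include them) but flagged, with an exclusion switch.

`leakRecurrence()` counts, for each distinct leaked variant, the number
of submissions leaking it; recurrent leaks are the privacy-relevant
minority, since ensemble calling would retain them.

## The synthetic benchmark generator

`simulateTruth()` and `simulateCaller()` emulate a spike-in benchmark at
the VCF level: germline and somatic truth variants are placed uniformly
at random, without replacement, across a synthetic genome (so the truth
sets are disjoint by construction), with ref/alt drawn uniformly from
the 12 ordered substitutions. A simulated caller recovers each somatic
truth variant with probability `sensitivity`, leaks each germline
variant with probability `leakRate`, and adds Poisson(`fpRate`) novel
false calls, rejection-sampled away from both truth sets so the
TP/leak/other-FP partition of every submission is exact by
construction.

Defaults (22 chromosomes × 1 Mbp, 5000 germline and 4000 somatic
spike-ins, sensitivity 0.9, 300 expected false positives, leak rate
0.005, seed 1) were chosen once to give call-set sizes in the few
thousands and leak counts in the zero-to-tens range — the regime the
method is designed for — while keeping a full cohort simulation in
seconds on one CPU. The test suite runs the generator at these or
smaller scales (hundreds to a few thousand spike-ins; the
parameter-recovery check uses 5000 germline variants × 200 replicate
callers), and the acceptance script simulates a 21-team × 3-tumour
cohort at the default scale.

What the generator does **not** emulate, and what passing tests
therefore do not show: no reads or alignments exist, so nothing is
learned about *why* callers leak (coverage, contamination at the read
level, mapping artefacts); `leakRate` is a single per-variant Bernoulli
proxy for the net effect of infiltrating normal cells; variant
positions are uniform, with no mutational hotspots, trinucleotide
context or subclonal structure; and all callers are conditionally
independent given the truth, unlike real pipelines that share error
modes. Conclusions about real pipelines require real tumour/normal
data; the generator's job is to make the *accounting* — counting,
filtering, scoring, aggregation — testable end to end.

Randomness is confined to documented streams: truth generation uses
`seed`; each caller uses a stream derived from `(seed, callerSeed)` with
a fixed draw order (somatic Bernoulli, germline Bernoulli, Poisson
count, novel keys), so every fixture is bit-reproducible; and both
restore the caller's RNG state afterwards.

## Numerical and degenerate-input choices

* Leak counting deduplicates first; duplicate submission lines cannot
  double-count one leaked polymorphism.
* An empty VCF body, an empty variant set and an empty store are all
  valid (zero counts), not errors; an empty *somatic truth* set is a
  contract violation for scoring, since recall is undefined.
* Key sets sort by (chromosome, position, ref, alt) with chromosomes
  1–22 ordered numerically before X, Y, MT; leak lists inherit this
  order.
* Malformed VCF data lines fail hard with the offending line number;
  silently skipping a corrupt line could hide a leak.
* Digest comparison uses lowercase hex strings of fixed per-protocol
  length (128/32 characters), enforced by class validity.

## Limitations

The store protects against exposure of the germline file on the server,
not against an adversary who can submit adaptively and observe counts
(repeated-query inference is out of scope, as is any multi-party or
public-key scheme). Scoring is whole-genome SNV-only: no indels, no
structural variants, no region masking. And the leakage filter
necessarily trades a small amount of somatic sensitivity for privacy:
any true somatic mutation that coincides exactly with a germline
variant of the same patient is removed with the leaks — flagged as
`ambiguous` by the scorer rather than adjudicated.

## A worked end-to-end run

```{r example, eval = FALSE}
cfg <- SimulationConfig(seed = 42L)
truth <- simulateTruth(cfg)
germStore <- tempfile(fileext = ".store")
buildStore(truth$germline, passphrase = "demo-secret", germStore)

sub <- simulateCaller(truth$somatic, truth$germline, cfg, callerSeed = 7L)
store <- loadStore(germStore, "demo-secret")
countLeaks(sub$calls, store)          # server mode: count only
scoreCalls(sub$calls, truth$somatic, truth$germline)
```
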