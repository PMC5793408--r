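smallConfig <- function(...) {
  SimulationConfig(nChroms = 4L, chromLength = 50000L, nGermline = 100L,
                   nSomatic = 50L, fpRate = 10, leakRate = 0.1, seed = 11L,
                   ...)
}

test_that("truth sets have the requested sizes, are disjoint and reproducible", {
  cfg <- smallConfig()
  tr <- simulateTruth(cfg)
  expect_length(tr$germline, 100L)
  expect_length(tr$somatic, 50L)
  expect_length(keyIntersect(tr$germline, tr$somatic), 0L)
  tr2 <- simulateTruth(cfg)
  expect_identical(canonicalKeys(tr$germline), canonicalKeys(tr2$germline))
  expect_identical(canonicalKeys(tr$somatic), canonicalKeys(tr2$somatic))
  # a different seed moves the variants
  cfg2 <- smallConfig(); cfg2@seed <- 12L
  expect_false(identical(canonicalKeys(simulateTruth(cfg2)$germline),
                         canonicalKeys(tr$germline)))
})

test_that("positions stay inside the genome and alleles are valid substitutions", {
  tr <- simulateTruth(smallConfig())
  df <- as.data.frame(keyUnion(tr$germline, tr$somatic))
  expect_true(all(df$pos >= 1 & df$pos <= 50000))
  expect_true(all(df$chrom %in% as.character(1:4)))
  expect_true(all(df$ref %in% c("A", "C", "G", "T")))
  expect_true(all(df$ref != df$alt))
})

test_that("requests beyond genome capacity raise a capacity error", {
  expect_error(SimulationConfig(nChroms = 1L, chromLength = 10L,
                                nGermline = 8L, nSomatic = 3L),
               "exceed")
})

test_that("a perfect caller reproduces the somatic truth exactly", {
  cfg <- smallConfig()
  cfg@sensitivity <- 1; cfg@leakRate <- 0; cfg@fpRate <- 0
  tr <- simulateTruth(cfg)
  sim <- simulateCaller(tr$somatic, tr$germline, cfg, callerSeed = 1L)
  expect_identical(canonicalKeys(sim$calls), canonicalKeys(tr$somatic))
  ev <- scoreCalls(sim$calls, tr$somatic, tr$germline)
  expect_equal(ev@f1, 1)
  expect_identical(leakCount(ev), 0L)
})

test_that("leakRate 1 leaks the whole germline set", {
  cfg <- smallConfig()
  cfg@leakRate <- 1
  tr <- simulateTruth(cfg)
  sim <- simulateCaller(tr$somatic, tr$germline, cfg, callerSeed = 2L)
  ev <- scoreCalls(sim$calls, tr$somatic, tr$germline)
  expect_identical(leakCount(ev), length(tr$germline))
})

test_that("submissions are reproducible per caller seed and differ across seeds", {
  cfg <- smallConfig()
  tr <- simulateTruth(cfg)
  a <- simulateCaller(tr$somatic, tr$germline, cfg, callerSeed = 5L)
  b <- simulateCaller(tr$somatic, tr$germline, cfg, callerSeed = 5L)
  c_ <- simulateCaller(tr$somatic, tr$germline, cfg, callerSeed = 6L)
  expect_identical(canonicalKeys(a$calls), canonicalKeys(b$calls))
  expect_false(identical(canonicalKeys(a$calls), canonicalKeys(c_$calls)))
})

test_that("caller bookkeeping matches plaintext set arithmetic", {
  cfg <- smallConfig()
  tr <- simulateTruth(cfg)
  for (seed in 1:5) {
    sim <- simulateCaller(tr$somatic, tr$germline, cfg, callerSeed = seed)
    expect_identical(length(keyIntersect(sim$calls, tr$somatic)), sim$nTp)
    expect_identical(length(keyIntersect(sim$calls, tr$germline)),
                     sim$nLeak)
    expect_identical(length(keySetdiff(keySetdiff(sim$calls, tr$somatic),
                                       tr$germline)), sim$nFp)
    expect_identical(length(sim$calls), sim$nTp + sim$nLeak + sim$nFp)
  }
})

test_that("written submissions re-read to the same key set", {
  cfg <- smallConfig()
  tr <- simulateTruth(cfg)
  out <- tempfile(fileext = ".vcf")
  sim <- simulateCaller(tr$somatic, tr$germline, cfg, callerSeed = 3L,
                        out = out)
  expect_identical(canonicalKeys(readVariantKeys(out)),
                   canonicalKeys(sim$calls))
})

test_that("recall and leak counts recover the generating parameters", {
  # moderate scale here; the full stated-scale check runs in the
  # acceptance suite
  cfg <- SimulationConfig(nChroms = 10L, chromLength = 200000L,
                          nGermline = 1000L, nSomatic = 500L,
                          sensitivity = 0.8, fpRate = 20, leakRate = 0.05,
                          seed = 21L)
  tr <- simulateTruth(cfg)
  reps <- 40L
  recalls <- leaks <- numeric(reps)
  for (i in seq_len(reps)) {
    sim <- simulateCaller(tr$somatic, tr$germline, cfg, callerSeed = i)
    recalls[i] <- sim$nTp / length(tr$somatic)
    leaks[i] <- sim$nLeak
  }
  seRecall <- sqrt(0.8 * 0.2 / (500 * reps))
  expect_lt(abs(mean(recalls) - 0.8), 3 * seRecall)
  seLeak <- sqrt(1000 * 0.05 * 0.95 / reps)
  expect_lt(abs(mean(leaks) - 1000 * 0.05), 3 * seLeak)
})

test_that("mean leakage is non-decreasing in the leak rate", {
  cfg <- smallConfig()
  tr <- simulateTruth(cfg)
  meanLeak <- vapply(c(0, 0.05, 0.2, 0.6), function(lr) {
    c2 <- cfg; c2@leakRate <- lr
    mean(vapply(1:15, function(s)
      simulateCaller(tr$somatic, tr$germline, c2, callerSeed = s)$nLeak,
      0))
  }, 0)
  expect_true(all(diff(meanLeak) >= 0))
})

test_that("cohort simulation produces a scoreable table with exact bookkeeping", {
  grid <- expand.grid(team = paste0("T", 1:3), tumour = c("IS1", "IS2"),
                      stringsAsFactors = FALSE)
  grid$sensitivity <- c(.95, .85, .75, .95, .85, .75)
  grid$fpRate <- 10
  grid$leakRate <- c(0, .02, .08, 0, .02, .08)
  co <- simulateCohort(grid, smallConfig(), baseSeed = 31L)
  expect_identical(nrow(co$records), 6L)
  expect_setequal(unique(co$records$tumour), c("IS1", "IS2"))
  # evaluation on simulated submissions equals plaintext set arithmetic
  for (i in seq_len(nrow(co$records))) {
    r <- co$records[i, ]
    leakSet <- co$leakSets[[r$tumour]][[r$submission_id]]
    expect_identical(r$leak_count, length(leakSet))
  }
  # perfect callers leak nothing
  perfect <- grid; perfect$sensitivity <- 1
  perfect$leakRate <- 0; perfect$fpRate <- 0
  coP <- simulateCohort(perfect, smallConfig(), baseSeed = 32L)
  expect_true(all(coP$records$leak_count == 0L))
  expect_true(all(coP$records$f1 == 1))
  s <- summarizeCohort(coP$records)
  expect_true(all(s$perTumour$leak_median == 0))
})

test_that("cohort files round-trip through the output directory", {
  grid <- data.frame(team = "T1", tumour = "IS1", sensitivity = .9,
                     fpRate = 5, leakRate = .05, stringsAsFactors = FALSE)
  outdir <- file.path(tempfile(), "fixtures")
  co <- simulateCohort(grid, smallConfig(), baseSeed = 33L,
                       outdir = outdir)
  expect_true(file.exists(file.path(outdir, "submissions.tsv")))
  tab <- readSubmissionTable(file.path(outdir, "submissions.tsv"))
  expect_equal(tab$f1, co$records$f1, tolerance = 1e-6)
  germ <- readVariantKeys(co$files$IS1[["germline"]])
  expect_identical(canonicalKeys(germ),
                   canonicalKeys(co$truth$IS1$germline))
  subVcf <- file.path(outdir, paste0(co$records$submission_id[1], ".vcf"))
  expect_true(file.exists(subVcf))
  rep <- locateLeaks(subVcf, co$files$IS1[["germline"]])
  expect_identical(leakCount(rep), co$records$leak_count[1])
})
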