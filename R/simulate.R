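# VCF-level emulation of a spike-in tumour/normal benchmark: known
# germline and somatic truth sets placed on a synthetic genome, plus
# simulated callers with controlled sensitivity, false-positive rate and
# germline-leak rate. No reads are simulated; the leak rate is a
# desk-scale proxy for the effect of infiltrating normal cells.

# the 12 ordered single-nucleotide substitutions
.SUBSTITUTIONS <- local({
  b <- c("A", "C", "G", "T")
  g <- expand.grid(ref = b, alt = b, stringsAsFactors = FALSE)
  g[g$ref != g$alt, ]
})

# run expr under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

#' Construct a simulation configuration
#'
#' Defaults describe a desk-scale benchmark whose call-set sizes and leak
#' counts resemble a real challenge cohort: a few thousand spiked-in
#' variants on a 22-chromosome synthetic genome, callers around 0.9
#' sensitivity with a few hundred false positives and a small germline
#' leak probability.
#'
#' @param nChroms number of chromosomes (default 22).
#' @param chromLength chromosome length in bp (default 1e6).
#' @param nGermline germline spike-ins (default 5000).
#' @param nSomatic somatic spike-ins (default 4000).
#' @param sensitivity probability a somatic truth variant is called
#'   (default 0.9).
#' @param fpRate expected Poisson count of novel false calls (default 300).
#' @param leakRate probability each germline variant leaks (default 0.005).
#' @param seed integer seed for truth-set generation (default 1).
#' @return a [SimulationConfig-class].
#' @export
SimulationConfig <- function(nChroms = 22L, chromLength = 1000000L,
                             nGermline = 5000L, nSomatic = 4000L,
                             sensitivity = 0.9, fpRate = 300,
                             leakRate = 0.005, seed = 1L) {
  new("SimulationConfig", nChroms = as.integer(nChroms),
      chromLength = as.integer(chromLength),
      nGermline = as.integer(nGermline), nSomatic = as.integer(nSomatic),
      sensitivity = as.numeric(sensitivity), fpRate = as.numeric(fpRate),
      leakRate = as.numeric(leakRate), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d chrom x %d bp | germline=%d ",
                     "somatic=%d | sens=%.3g fpRate=%.3g leakRate=%.3g ",
                     "seed=%d\n"),
              object@nChroms, object@chromLength, object@nGermline,
              object@nSomatic, object@sensitivity, object@fpRate,
              object@leakRate, object@seed))
})

# map linear genome indices to (chrom, pos) and random substitutions
.keysFromIndices <- function(idx, chromLength, label) {
  sub <- .SUBSTITUTIONS[sample.int(nrow(.SUBSTITUTIONS), length(idx),
                                   replace = TRUE), ]
  VariantKeySet(chrom = as.character((idx - 1L) %/% chromLength + 1L),
                pos = (idx - 1L) %% chromLength + 1L,
                ref = sub$ref, alt = sub$alt, sourceLabel = label)
}

#' Simulate germline and somatic truth sets
#'
#' Places `nGermline + nSomatic` variants uniformly at random, without
#' replacement, across the synthetic genome, so the two truth sets are
#' disjoint by construction (distinct positions). Ref/alt pairs are drawn
#' uniformly from the 12 ordered single-nucleotide substitutions. Fully
#' reproducible from `seed`.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `germline` and `somatic`
#'   ([VariantKeySet-class]).
#' @export
simulateTruth <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  total <- as.double(config@nChroms) * as.double(config@chromLength)
  n <- config@nGermline + config@nSomatic
  if (n > total)
    stop("requested spike-ins exceed available genome positions")
  .withSeed(config@seed, {
    idx <- sample.int(total, n)
    germline <- .keysFromIndices(idx[seq_len(config@nGermline)],
                                 config@chromLength, "truth_germline")
    somatic <- .keysFromIndices(idx[config@nGermline + seq_len(config@nSomatic)],
                                config@chromLength, "truth_somatic")
    list(germline = germline, somatic = somatic)
  })
}

#' Simulate one caller's somatic submission
#'
#' Emits each somatic truth variant with probability `sensitivity`, leaks
#' each germline truth variant with probability `leakRate`, and adds a
#' Poisson(`fpRate`) number of novel false calls at positions that collide
#' with neither truth set (rejection-sampled), so the TP / leak / other-FP
#' partition of the output is exact. Draw order is fixed (somatic
#' Bernoulli, germline Bernoulli, Poisson count, novel keys) and the
#' stream is seeded from `(config@seed, callerSeed)`, so submissions are
#' reproducible.
#'
#' @param truthSomatic,truthGermline truth sets from [simulateTruth()].
#' @param config a [SimulationConfig-class] (supplies the error rates and
#'   genome geometry).
#' @param callerSeed integer distinguishing callers on the same truth.
#' @param out optional path; when given the submission is written as a
#'   minimal VCF.
#' @param label submission label.
#' @return list: `calls` ([VariantKeySet-class]), bookkeeping counts
#'   `nTp`, `nLeak`, `nFp`, and `path` (`NULL` unless written).
#' @export
simulateCaller <- function(truthSomatic, truthGermline, config,
                           callerSeed = 1L, out = NULL,
                           label = sprintf("caller_%d", callerSeed)) {
  stopifnot(is(truthSomatic, "VariantKeySet"),
            is(truthGermline, "VariantKeySet"),
            is(config, "SimulationConfig"))
  seed <- (as.double(config@seed) * 100003 + as.double(callerSeed)) %%
    2147483647
  .withSeed(seed, {
    somaticKeys <- canonicalKeys(truthSomatic)
    germlineKeys <- canonicalKeys(truthGermline)
    called <- somaticKeys[stats::runif(length(somaticKeys)) <
                            config@sensitivity]
    leaked <- germlineKeys[stats::runif(length(germlineKeys)) <
                             config@leakRate]
    nFp <- stats::rpois(1L, config@fpRate)
    total <- as.double(config@nChroms) * as.double(config@chromLength)
    forbidden <- c(somaticKeys, germlineKeys)
    novel <- character(0)
    while (length(novel) < nFp) {
      need <- nFp - length(novel)
      idx <- sample.int(total, need, replace = TRUE)
      sub <- .SUBSTITUTIONS[sample.int(12L, need, replace = TRUE), ]
      cand <- paste((idx - 1L) %/% config@chromLength + 1L,
                    (idx - 1L) %% config@chromLength + 1L,
                    sub$ref, sub$alt, sep = ":")
      cand <- setdiff(cand, c(forbidden, novel))
      novel <- c(novel, cand)
    }
    calls <- .keySetFromCanonical(c(called, leaked, novel), label)
    path <- NULL
    if (!is.null(out)) {
      writeVariantVcf(calls, out, source = label)
      path <- out
    }
    list(calls = calls, nTp = length(called), nLeak = length(leaked),
         nFp = length(novel), path = path)
  })
}

#' Simulate a whole challenge cohort
#'
#' Generates shared truth sets per tumour and one submission per row of
#' `grid`, scores each against its tumour's truth, and returns a
#' submission table ready for [summarizeCohort()] / [bestPerTeam()],
#' together with per-submission leak key sets for [leakRecurrence()].
#'
#' @param grid data.frame with one row per submission and columns `team`,
#'   `tumour`, `sensitivity`, `fpRate`, `leakRate` (optional `is_admin`).
#' @param config a [SimulationConfig-class]; geometry and spike-in counts
#'   are shared by all tumours, and each tumour's truth seed is
#'   `config@seed` plus its index.
#' @param baseSeed integer; submission i uses caller seed `baseSeed + i`.
#' @param outdir optional directory; when given, truth sets and every
#'   submission are also written as VCFs.
#' @return list: `records` (data.frame with the standard submission
#'   columns plus the generating parameters), `truth` (per-tumour truth
#'   sets), `leakSets` (per-tumour named lists of leaked
#'   [VariantKeySet-class]s), `files` (paths, when `outdir` given).
#' @export
simulateCohort <- function(grid, config = SimulationConfig(),
                           baseSeed = 1L, outdir = NULL) {
  stopifnot(is.data.frame(grid),
            all(c("team", "tumour", "sensitivity", "fpRate", "leakRate")
                %in% names(grid)))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  tumours <- unique(as.character(grid$tumour))
  truth <- list()
  files <- list()
  for (ti in seq_along(tumours)) {
    cfgT <- config
    cfgT@seed <- config@seed + ti
    truth[[tumours[ti]]] <- simulateTruth(cfgT)
    if (!is.null(outdir)) {
      gPath <- file.path(outdir, sprintf("%s_truth_germline.vcf", tumours[ti]))
      sPath <- file.path(outdir, sprintf("%s_truth_somatic.vcf", tumours[ti]))
      writeVariantVcf(truth[[tumours[ti]]]$germline, gPath)
      writeVariantVcf(truth[[tumours[ti]]]$somatic, sPath)
      files[[tumours[ti]]] <- c(germline = gPath, somatic = sPath)
    }
  }
  records <- vector("list", nrow(grid))
  leakSets <- stats::setNames(
    lapply(tumours, function(t) list()), tumours)
  for (i in seq_len(nrow(grid))) {
    tm <- as.character(grid$tumour[i])
    cfg <- config
    cfg@sensitivity <- grid$sensitivity[i]
    cfg@fpRate <- grid$fpRate[i]
    cfg@leakRate <- grid$leakRate[i]
    subId <- sprintf("%s_%s_%03d", tm, grid$team[i], i)
    out <- if (!is.null(outdir)) {
      file.path(outdir, paste0(subId, ".vcf"))
    } else NULL
    sim <- simulateCaller(truth[[tm]]$somatic, truth[[tm]]$germline, cfg,
                          callerSeed = baseSeed + i, out = out,
                          label = subId)
    ev <- scoreCalls(sim$calls, truth[[tm]]$somatic, truth[[tm]]$germline)
    records[[i]] <- data.frame(
      tumour = tm, submission_id = subId,
      team_id = as.character(grid$team[i]),
      precision = ev@precision, recall = ev@recall, f1 = ev@f1,
      leak_count = ev@leakCount,
      is_admin = if ("is_admin" %in% names(grid)) {
        isTRUE(grid$is_admin[i])
      } else FALSE,
      sensitivity = grid$sensitivity[i], fpRate = grid$fpRate[i],
      leakRate = grid$leakRate[i], stringsAsFactors = FALSE)
    leakSets[[tm]][[subId]] <-
      keyIntersect(sim$calls, truth[[tm]]$germline)
  }
  records <- do.call(rbind, records)
  if (!is.null(outdir))
    utils::write.table(records[, .SUBMISSION_COLS],
                       file.path(outdir, "submissions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  list(records = records, truth = truth, leakSets = leakSets,
       files = if (length(files)) files else NULL)
}
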