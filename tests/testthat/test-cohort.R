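makeRecords <- function(tumour, f1, leaks, team = seq_along(f1),
                        admin = FALSE) {
  pr <- f1   # precision = recall = f1 is self-consistent (harmonic mean)
  data.frame(tumour = tumour,
             submission_id = sprintf("%s_s%02d", tumour, seq_along(f1)),
             team_id = paste0("T", team),
             precision = pr, recall = pr, f1 = f1,
             leak_count = as.integer(leaks),
             is_admin = admin, stringsAsFactors = FALSE)
}

test_that("spearmanRho matches brute-force mid-rank Pearson, ties included", {
  set.seed(801)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    # draw from a small support so ties are frequent
    x <- sample.int(5, n, replace = TRUE)
    y <- sample.int(5, n, replace = TRUE)
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
    expect_equal(spearmanRho(x, y), bruteSpearman(x, y), tolerance = 1e-12)
  }
})

test_that("spearmanRho hits the exact anti-monotone bound and is permutation-invariant", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(9, 7, 5, 3, 1)
  expect_equal(spearmanRho(x, y), -1)
  set.seed(802)
  p <- sample(5)
  expect_equal(spearmanRho(x[p], y[p]), -1)
  x2 <- c(1, 2, 3, 4); y2 <- c(2, 2, 5, 7)
  expect_equal(spearmanRho(x2, y2), bruteSpearman(x2, y2))
})

test_that("spearmanRho rejects degenerate input", {
  expect_error(spearmanRho(c(1, 2), c(3, 4)), "at least 3")
  expect_error(spearmanRho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearmanRho(1:3, 1:4), "equal length")
})

test_that("cohort summary computes medians and ranges per tumour and overall", {
  rec <- rbind(makeRecords("IS1", c(.9, .8, .7, .6, .5),
                           c(0, 1, 1, 2, 45300)),
               makeRecords("IS2", c(.9, .85, .8), c(6, 2, 10)))
  s <- summarizeCohort(rec)
  expect_identical(s$overall$n_submissions, 8L)
  # sorted counts 0,1,1,2,2,6,10,45300: central pair (2,2)
  expect_equal(s$overall$leak_median, 2)
  expect_identical(s$overall$leak_min, 0L)
  expect_identical(s$overall$leak_max, 45300L)
  is1 <- s$perTumour[s$perTumour$tumour == "IS1", ]
  expect_equal(is1$leak_median, 1)
  expect_equal(is1$leak_max, 45300)
  is2 <- s$perTumour[s$perTumour$tumour == "IS2", ]
  expect_equal(is2$leak_median, 6)
})

test_that("cohort summary is invariant to record order and handles one record", {
  rec <- makeRecords("IS3", c(.9, .7, .8, .6), c(3, 0, 5, 1))
  set.seed(803)
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(summarizeCohort(rec), summarizeCohort(shuffled))
  one <- summarizeCohort(makeRecords("IS1", 0.5, 7))
  expect_equal(one$overall$leak_median, 7)
  expect_identical(one$overall$leak_min, 7L)
  expect_identical(one$overall$leak_max, 7L)
  expect_error(summarizeCohort(rec[0, ]), "non-empty")
})

test_that("per-tumour Spearman relates F1 to leak count with the expected sign", {
  # leakier submissions score strictly worse: rho must be -1
  rec <- makeRecords("IS1", c(.9, .8, .7, .6), c(0, 2, 5, 9))
  s <- summarizeCohort(rec)
  expect_equal(s$perTumour$spearman_rho, -1)
})

test_that("best per team maximizes F1 with documented tie-breaks", {
  rec <- rbind(
    makeRecords("IS1", c(.8, .9), c(5, 7), team = c(1, 1)),
    makeRecords("IS1", c(.9, .9), c(3, 0), team = c(2, 2)),
    makeRecords("IS2", c(.7, .7), c(1, 1), team = c(1, 1)))
  best <- bestPerTeam(rec)
  expect_identical(nrow(best), 3L)
  t1 <- best[best$tumour == "IS1" & best$team_id == "T1", ]
  expect_equal(t1$f1, 0.9)
  t2 <- best[best$tumour == "IS1" & best$team_id == "T2", ]
  expect_identical(t2$leak_count, 0L)              # tie broken on leaks
  t3 <- best[best$tumour == "IS2", ]
  expect_identical(t3$submission_id, "IS2_s01")    # then on submission id
})

test_that("best per team covers every (tumour, team) pair and warns on missing teams", {
  rec <- do.call(rbind, lapply(c("IS1", "IS2"), function(tm)
    makeRecords(tm, runif(6, .5, .95), rpois(6, 2), team = rep(1:3, 2))))
  expect_identical(nrow(bestPerTeam(rec)), 6L)
  rec$team_id[1] <- NA
  expect_warning(bestPerTeam(rec), "without team_id")
})

test_that("leak recurrence counts occurrences across submissions", {
  a <- VariantKeySet("1", 1L, "A", "G")
  b <- VariantKeySet("1", 2L, "C", "T")
  c_ <- VariantKeySet("1", 3L, "G", "A")
  res <- leakRecurrence(list(s1 = keyUnion(a, b), s2 = keyUnion(b, c_),
                             s3 = b))
  counts <- setNames(res$counts$occurrences, res$counts$key)
  expect_identical(counts[["1:2:C:T"]], 3L)
  expect_identical(counts[["1:1:A:G"]], 1L)
  expect_identical(res$nDistinct, 3L)
  expect_identical(res$nRecurrent, 1L)
  # disjoint sets: everything occurs once
  disj <- leakRecurrence(list(a, c_))
  expect_true(all(disj$counts$occurrences == 1L))
  expect_identical(disj$nRecurrent, 0L)
  # empty input
  none <- leakRecurrence(list())
  expect_identical(none$nDistinct, 0L)
})

test_that("submission tables round-trip through TSV and CSV with validation", {
  rec <- rbind(makeRecords("IS1", c(.9, .8), c(1, 2)),
               makeRecords("IS2", c(.7, .6), c(0, 4), admin = TRUE))
  tsv <- tempfile(fileext = ".tsv")
  write.table(rec, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readSubmissionTable(tsv)
  expect_equal(back$f1, rec$f1)
  expect_identical(back$leak_count, rec$leak_count)
  expect_identical(readSubmissionTable(tsv, excludeAdmin = TRUE)$tumour,
                   c("IS1", "IS1"))
  csv <- tempfile(fileext = ".csv")
  write.csv(rec, csv, row.names = FALSE)
  expect_equal(readSubmissionTable(csv), back)
  # shuffled column order is accepted; missing column is not
  write.table(rec[, rev(names(rec))], tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(readSubmissionTable(tsv), back)
  write.table(rec[, -3], tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSubmissionTable(tsv), "team_id")
  # inconsistent f1 draws a warning
  bad <- rec; bad$f1[1] <- bad$f1[1] + 0.01
  write.table(bad, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(readSubmissionTable(tsv), "inconsistent")
})
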