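# Cohort-level statistics over per-submission results: leak medians and
# ranges per tumour, F1-versus-leak Spearman correlation, best-per-team
# selection and leaked-variant recurrence.

.SUBMISSION_COLS <- c("tumour", "submission_id", "team_id", "precision",
                      "recall", "f1", "leak_count", "is_admin")

#' Read a cohort submission table
#'
#' Reads a TSV/CSV with one row per submission and (in any order) columns
#' `tumour`, `submission_id`, `team_id`, `precision`, `recall`, `f1`,
#' `leak_count`, `is_admin`. F1 is cross-checked against
#' 2·precision·recall/(precision+recall); disagreement beyond 5e-4
#' (table-rounding tolerance) raises a warning naming the rows.
#'
#' @param path path to the table; the delimiter is taken from the
#'   extension (`.csv` → comma, otherwise tab).
#' @param excludeAdmin drop rows flagged as administrator submissions.
#' @return a data.frame with the standard columns.
#' @export
readSubmissionTable <- function(path, excludeAdmin = FALSE) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  missing <- setdiff(.SUBMISSION_COLS, names(df))
  if (length(missing))
    stop("submission table lacks column(s): ", paste(missing, collapse = ", "))
  df <- df[, .SUBMISSION_COLS]
  df$is_admin <- as.logical(df$is_admin)
  for (col in c("precision", "recall", "f1")) df[[col]] <- as.numeric(df[[col]])
  df$leak_count <- as.integer(df$leak_count)
  pr <- df$precision + df$recall
  expect <- ifelse(pr > 0, 2 * df$precision * df$recall / pr, 0)
  bad <- which(abs(expect - df$f1) > 5e-4)
  if (length(bad))
    warning("F1 inconsistent with precision/recall in row(s): ",
            paste(utils::head(bad, 10L), collapse = ", "))
  if (excludeAdmin) df <- df[!df$is_admin, , drop = FALSE]
  df
}

#' Spearman rank correlation (mid-ranks)
#'
#' Pearson correlation of mid-ranks; ties receive average ranks. Used to
#' relate submission accuracy (F1) to germline leak counts, where a
#' negative value means leakier submissions score worse.
#'
#' @param x,y numeric vectors of equal length, at least 3, neither
#'   constant.
#' @return correlation in `[-1, 1]`.
#' @examples
#' spearmanRho(1:5, c(10, 8, 7, 3, 1))   # -1: perfectly anti-monotone
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("Spearman correlation is undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

.median3 <- function(x) {
  # mean-of-central-pair convention, as stats::median for even n
  stats::median(x)
}

.summarizeGroup <- function(leaks, f1) {
  rho <- if (length(leaks) >= 3L && length(unique(leaks)) > 1L &&
             length(unique(f1)) > 1L) spearmanRho(f1, leaks) else NA_real_
  list(n_submissions = length(leaks),
       leak_median = .median3(leaks),
       leak_min = min(leaks),
       leak_max = max(leaks),
       spearman_rho = rho)
}

#' Summarize a cohort of submissions
#'
#' Per-tumour and overall leak-count medians (mean-of-central-pair
#' convention), ranges, and per-tumour Spearman correlation between F1 and
#' leak count (`NA` when fewer than 3 submissions or either vector is
#' constant). Administrator submissions are included unless
#' `excludeAdmin`.
#'
#' @param records data.frame as returned by [readSubmissionTable()] or
#'   [simulateCohort()].
#' @param excludeAdmin drop administrator submissions first.
#' @return a list with `overall` (named list: `n_submissions`,
#'   `leak_median`, `leak_min`, `leak_max`) and `perTumour` (data.frame
#'   with one row per tumour and a `spearman_rho` column).
#' @export
summarizeCohort <- function(records, excludeAdmin = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  if (excludeAdmin) records <- records[!records$is_admin, , drop = FALSE]
  if (nrow(records) == 0L) stop("no records left after admin exclusion")
  overall <- .summarizeGroup(records$leak_count, records$f1)
  overall$spearman_rho <- NULL
  tumours <- sort(unique(records$tumour))
  perTumour <- do.call(rbind, lapply(tumours, function(tm) {
    g <- records[records$tumour == tm, , drop = FALSE]
    s <- .summarizeGroup(g$leak_count, g$f1)
    data.frame(tumour = tm, n_submissions = s$n_submissions,
               leak_median = s$leak_median, leak_min = s$leak_min,
               leak_max = s$leak_max, spearman_rho = s$spearman_rho)
  }))
  list(overall = overall, perTumour = perTumour)
}

#' Select each team's best submission per tumour
#'
#' For every (tumour, team) pair, returns the submission with the highest
#' F1-score. Ties are broken deterministically: smallest leak count, then
#' lexicographically smallest submission id. Rows with a missing team id
#' are skipped with a warning.
#'
#' @param records data.frame of submissions (see [readSubmissionTable()]).
#' @return a data.frame with one row per (tumour, team).
#' @export
bestPerTeam <- function(records) {
  stopifnot(is.data.frame(records))
  noTeam <- is.na(records$team_id) | !nzchar(as.character(records$team_id))
  if (any(noTeam)) {
    warning(sum(noTeam), " record(s) without team_id skipped")
    records <- records[!noTeam, , drop = FALSE]
  }
  if (nrow(records) == 0L) return(records)
  groups <- split(records,
                  list(records$tumour, records$team_id), drop = TRUE)
  best <- lapply(groups, function(g) {
    o <- order(-g$f1, g$leak_count, as.character(g$submission_id))
    g[o[1L], , drop = FALSE]
  })
  out <- do.call(rbind, best)
  rownames(out) <- NULL
  out[order(out$tumour, out$team_id), , drop = FALSE]
}

#' Recurrence of leaked variants across submissions
#'
#' Given the leaked key sets of several submissions on the same tumour,
#' counts in how many submissions each distinct leaked variant occurs.
#' Recurrent leaks (occurring more than once) are the privacy-relevant
#' ones: an ensemble over pipelines would retain them.
#'
#' @param leakSets list of [VariantKeySet-class] objects, one per
#'   submission (names used as submission labels).
#' @return a list with `counts` (data.frame `key`, `occurrences`, sorted
#'   by decreasing occurrence), `nDistinct` (distinct leaked variants) and
#'   `nRecurrent` (those seen in more than one submission).
#' @export
leakRecurrence <- function(leakSets) {
  stopifnot(is.list(leakSets))
  if (!length(leakSets))
    return(list(counts = data.frame(key = character(),
                                    occurrences = integer()),
                nDistinct = 0L, nRecurrent = 0L))
  keys <- unlist(lapply(leakSets, canonicalKeys), use.names = FALSE)
  tab <- table(keys)
  counts <- data.frame(key = names(tab),
                       occurrences = as.integer(tab),
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$occurrences, counts$key), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts, nDistinct = nrow(counts),
       nRecurrent = sum(counts$occurrences > 1L))
}
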