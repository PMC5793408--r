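# Challenge-style scoring of somatic predictions against spiked-in truth.

#' Partition predicted calls into TP / germline leak / other FP
#'
#' Each distinct predicted key is classified as a true positive (present
#' in the somatic truth set), a germline leak (present in the germline
#' truth set but not the somatic one), or an other false positive. A key
#' present in both truth sets counts once as a true positive and is
#' additionally flagged ambiguous; a well-formed benchmark keeps its truth
#' sets disjoint so this set is normally empty.
#'
#' @param predicted,truthSomatic,truthGermline [VariantKeySet-class]
#'   objects.
#' @return a named list of `VariantKeySet`s: `tp`, `leak`, `otherFp`,
#'   `ambiguous`.
#' @export
classifyCalls <- function(predicted, truthSomatic, truthGermline) {
  stopifnot(is(predicted, "VariantKeySet"),
            is(truthSomatic, "VariantKeySet"),
            is(truthGermline, "VariantKeySet"))
  tp <- keyIntersect(predicted, truthSomatic)
  leak <- keySetdiff(keyIntersect(predicted, truthGermline), truthSomatic)
  otherFp <- keySetdiff(keySetdiff(predicted, truthSomatic), truthGermline)
  ambiguous <- keyIntersect(tp, truthGermline)
  list(tp = tp, leak = leak, otherFp = otherFp, ambiguous = ambiguous)
}

#' Score a somatic prediction set
#'
#' Computes precision (fraction of submitted calls that are true somatic
#' SNVs), recall (fraction of true somatic SNVs recovered), their harmonic
#' mean F1, and germline leakage (predicted keys exactly matching a
#' germline truth variant at chromosome, position, ref and alt). All
#' counting is over distinct canonical keys. Specificity is deliberately
#' not computed: at whole-genome scale the true-negative count would
#' swamp it.
#'
#' Zero conventions: with no predicted calls, precision is 0; when
#' precision + recall is 0, F1 is 0. This keeps cohort statistics total
#' over degenerate submissions.
#'
#' @inheritParams classifyCalls
#' @return an [EvaluationResult-class].
#' @examples
#' ts <- VariantKeySet(chrom = "1", pos = 1:10, ref = "A", alt = "G")
#' tg <- VariantKeySet(chrom = "2", pos = 1:5, ref = "C", alt = "T")
#' pred <- keyUnion(
#'   VariantKeySet(chrom = "1", pos = 1:6, ref = "A", alt = "G"),
#'   VariantKeySet(chrom = "2", pos = 1:2, ref = "C", alt = "T"))
#' scoreCalls(pred, ts, tg)   # precision 0.75, recall 0.6, 2 leaks
#' @export
scoreCalls <- function(predicted, truthSomatic, truthGermline) {
  if (length(truthSomatic) == 0L)
    stop("truthSomatic must be non-empty")
  parts <- classifyCalls(predicted, truthSomatic, truthGermline)
  tp <- length(parts$tp)
  fp <- length(parts$leak) + length(parts$otherFp)
  fn <- length(truthSomatic) - tp
  total <- tp + fp
  leakCount <- length(keyIntersect(predicted, truthGermline))
  precision <- if (total > 0L) tp / total else 0
  recall <- tp / length(truthSomatic)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  new("EvaluationResult",
      tp = tp, fp = fp, fn = fn,
      precision = precision, recall = recall, f1 = f1,
      leakCount = as.integer(leakCount),
      leakFractionOfCalls = if (total > 0L) leakCount / total else 0,
      leakFractionOfFp = if (fp > 0L) leakCount / fp else NaN,
      ambiguous = length(parts$ambiguous))
}

#' @describeIn EvaluationResult metrics as a one-row data.frame.
#' @param x an `EvaluationResult`.
#' @param row.names,optional,... ignored.
#' @export
setMethod("as.data.frame", "EvaluationResult",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(tp = x@tp, fp = x@fp, fn = x@fn,
               precision = x@precision, recall = x@recall, f1 = x@f1,
               leak_count = x@leakCount,
               leak_fraction_of_calls = x@leakFractionOfCalls,
               leak_fraction_of_fp = x@leakFractionOfFp,
               ambiguous = x@ambiguous)
  })

#' @rdname accessors
#' @export
setMethod("leakCount", "EvaluationResult", function(x) x@leakCount)

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf(paste0("EvaluationResult: TP=%d FP=%d FN=%d | ",
                     "precision=%.4f recall=%.4f F1=%.4f | leaks=%d\n"),
              object@tp, object@fp, object@fn, object@precision,
              object@recall, object@f1, object@leakCount))
  if (object@ambiguous > 0L)
    cat(sprintf("  note: %d key(s) present in both truth sets (counted as TP)\n",
                object@ambiguous))
})
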