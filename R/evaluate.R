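#' Transfer call scores to labeled regions
#'
#' Labeled evaluation regions rarely coincide with called regions, so each
#' labeled region receives the overlap-weighted mean of the scores of the
#' calls overlapping it: with n_i overlapping calls of scores c_j and
#' overlaps o_j bp, the transferred score is sum(o_j c_j) / sum(o_j).
#' A labeled region with no overlapping call is assigned the lowest
#' weighted score observed for the call set.
#'
#' @param labels \code{GRanges} of labeled regions (e.g. from
#'   \code{\link{readLabeledBed}})
#' @param calls \code{GRanges} of scored calls (numeric \code{score}
#'   metadata column)
#' @return \code{labels} with added metadata columns
#'   \code{transferredScore} and \code{scored} (FALSE where the minimum was
#'   assigned for lack of overlap)
#' @export
transferScores <- function(labels, calls) {
  if (length(labels) == 0L) stop("no labeled regions supplied")
  if (is.null(calls$score)) stop("calls must carry a numeric score column")
  ov <- GenomicRanges::findOverlaps(labels, calls, minoverlap = 1L)
  if (length(ov) == 0L)
    stop("no call overlaps any labeled region; scores cannot be transferred")
  inter <- IRanges::pintersect(
    labels[S4Vectors::queryHits(ov)], calls[S4Vectors::subjectHits(ov)])
  o <- GenomicRanges::width(inter)
  cs <- calls$score[S4Vectors::subjectHits(ov)]
  num <- tapply(o * cs, S4Vectors::queryHits(ov), sum)
  den <- tapply(o, S4Vectors::queryHits(ov), sum)
  score <- rep(NA_real_, length(labels))
  score[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  scored <- !is.na(score)
  score[!scored] <- min(score[scored])
  labels$transferredScore <- score
  labels$scored <- scored
  labels
}

#' Precision, recall and F1 at a score cutoff
#'
#' Predictions are \code{score >= cutoff}. Zero-denominator cases are
#' reported as \code{NA} (undefined), not 0.
#'
#' @param labels binary truth labels (0/1 vector, or a \code{GRanges} with
#'   \code{label} and \code{transferredScore} columns as produced by
#'   \code{\link{transferScores}})
#' @param scores numeric prediction scores (ignored when \code{labels} is a
#'   \code{GRanges} carrying them)
#' @param cutoff decision cutoff (inclusive)
#' @return list with \code{precision}, \code{recall}, \code{f1} and the
#'   \code{tp}, \code{fp}, \code{fn}, \code{tn} counts
#' @export
precisionRecallF1 <- function(labels, scores = NULL, cutoff = 0.5) {
  if (is(labels, "GRanges")) {
    scores <- labels$transferredScore
    labels <- labels$label
  }
  stopifnot(length(labels) == length(scores),
            all(labels %in% c(0L, 1L)))
  if (!any(labels == 1L) || !any(labels == 0L))
    warning("labels contain a single class; some metrics are undefined")
  pred <- scores >= cutoff
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  tn <- sum(!pred & labels == 0L)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Precision-recall curve and its area
#'
#' Sweeps the cutoff over the distinct transferred scores (all tied labels
#' flip together) and integrates precision over recall by the trapezoidal
#' rule, anchored at recall 0 with the precision of the strictest cutoff.
#' Labels sharing the assigned minimum score (those no call overlapped)
#' all flip at the final cutoff, producing the terminal linear portion of
#' the curve out to recall 1.
#'
#' @inheritParams precisionRecallF1
#' @return list with \code{points} (data.frame cutoff/recall/precision)
#'   and \code{auc}
#' @export
prCurve <- function(labels, scores = NULL) {
  if (is(labels, "GRanges")) {
    scores <- labels$transferredScore
    labels <- labels$label
  }
  stopifnot(length(labels) == length(scores))
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("PR curve needs both positive and negative labels")
  cuts <- sort(unique(scores), decreasing = TRUE)
  pts <- vapply(cuts, function(ct) {
    pred <- scores >= ct
    tp <- sum(pred & labels == 1L)
    fp <- sum(pred & labels == 0L)
    c(recall = tp / sum(labels == 1L),
      precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_)
  }, numeric(2))
  rec <- c(0, pts["recall", ])
  prec <- c(pts["precision", 1L], pts["precision", ])
  auc <- sum(diff(rec) * (head(prec, -1L) + tail(prec, -1L)) / 2)
  list(points = data.frame(cutoff = cuts, recall = pts["recall", ],
                           precision = pts["precision", ]),
       auc = auc)
}

#' Observed recall under label noise
#'
#' With noisy truth labels, measured recall mixes the true recall with the
#' true false positive rate: observed recall =
#' trueRecall * P(y=1|z=1) + trueFpr * (1 - P(y=1|z=1)), where z is the
#' noisy label and y the unobserved truth.
#'
#' @param trueRecall true recall in [0,1]
#' @param trueFpr true false positive rate in [0,1]
#' @param pY1givenZ1 probability that a positively labeled region is truly
#'   positive, in [0,1] (1 = error-free labels)
#' @return the observed (contaminated) recall
#' @export
observedRecall <- function(trueRecall, trueFpr, pY1givenZ1) {
  args <- c(trueRecall, trueFpr, pY1givenZ1)
  if (any(!is.finite(args)) || any(args < 0) || any(args > 1))
    stop("all arguments must lie in [0, 1]")
  trueRecall * pY1givenZ1 + trueFpr * (1 - pY1givenZ1)
}
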