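#' Temporal intersection-over-union of two frame intervals
#'
#' Intervals are 0-based inclusive `[start, end]` frame index pairs,
#' treated as frame sets: the IOU is the number of overlapping frames
#' divided by the number of union frames. Symmetric, bounded in
#' `[0, 1]`, and 1 exactly when the intervals are identical.
#'
#' @param a,b length-2 integer vectors `c(start, end)`.
#' @return the temporal IOU.
#' @examples
#' temporalIOU(c(0, 9), c(5, 14))  # 5 / 15
#' @export
temporalIOU <- function(a, b) {
  inter <- min(a[2], b[2]) - max(a[1], b[1]) + 1
  if (inter <= 0) return(0)
  union <- (a[2] - a[1] + 1) + (b[2] - b[1] + 1) - inter
  inter / union
}

# per-pair detection time error in seconds: mean absolute error of the
# start, middle and end positions (middle may be half-integral)
.pairTimeError <- function(det, gt, fps) {
  dm <- (det[1] + det[2]) / 2
  gm <- (gt[1] + gt[2]) / 2
  (abs(det[1] - gt[1]) + abs(dm - gm) + abs(det[2] - gt[2])) / 3 / fps
}

#' Greedy confidence-ordered matching of detections to ground truth
#'
#' Detections are processed in descending confidence (ties: earlier
#' start first). Each detection considers the not-yet-claimed ground
#' truths with IOU strictly above `iouTh`; when several qualify it
#' claims the one with the lowest start/middle/end time error (ties:
#' highest IOU, then earliest ground-truth start). A detection whose
#' only above-threshold ground truths were already claimed by
#' higher-confidence detections is *ignored* — not a false positive.
#' A detection with no above-threshold ground truth is a false
#' positive, and unclaimed ground truths are false negatives.
#'
#' @param dets data.frame of detections (`start_frame`, `end_frame`,
#'   `confidence`, optional `video_id`).
#' @param gts data.frame of ground truths (`start_frame`, `end_frame`,
#'   optional `video_id`).
#' @param iouTh IOU threshold (default 0.3).
#' @param fps frame rate used for time errors (default 15).
#' @return a [MatchResult-class].
#' @export
matchDetections <- function(dets, gts, iouTh = 0.3, fps = 15) {
  vd <- unique(c(if (!is.null(dets$video_id)) dets$video_id,
                 if (!is.null(gts$video_id)) gts$video_id))
  if (length(vd) > 1L)
    stopf("matchDetections expects intervals from one video, got: %s",
          paste(vd, collapse = ", "))
  nd <- nrow(dets); ng <- nrow(gts)
  claimed <- rep(FALSE, ng)
  kind <- character(nd)           # "tp", "fp", "ignored"
  match <- integer(nd)
  ord <- order(-dets$confidence, dets$start_frame)
  for (i in ord) {
    di <- c(dets$start_frame[i], dets$end_frame[i])
    ious <- if (ng > 0)
      vapply(seq_len(ng), function(j)
        temporalIOU(di, c(gts$start_frame[j], gts$end_frame[j])), numeric(1))
    else numeric()
    over <- which(ious > iouTh)
    if (length(over) == 0L) { kind[i] <- "fp"; next }
    free <- over[!claimed[over]]
    if (length(free) == 0L) { kind[i] <- "ignored"; next }
    terr <- vapply(free, function(j)
      .pairTimeError(di, c(gts$start_frame[j], gts$end_frame[j]), fps),
      numeric(1))
    # precedence: lowest time error, then highest IOU, then earliest gt
    o <- order(terr, -ious[free], gts$start_frame[free])
    j <- free[o[1]]
    claimed[j] <- TRUE
    kind[i] <- "tp"; match[i] <- j
  }
  tpIdx <- which(kind == "tp")
  tp <- if (length(tpIdx) > 0) data.frame(
    det_start = dets$start_frame[tpIdx], det_end = dets$end_frame[tpIdx],
    confidence = dets$confidence[tpIdx],
    gt_start = gts$start_frame[match[tpIdx]],
    gt_end = gts$end_frame[match[tpIdx]],
    iou = vapply(tpIdx, function(i) temporalIOU(
      c(dets$start_frame[i], dets$end_frame[i]),
      c(gts$start_frame[match[i]], gts$end_frame[match[i]])), numeric(1)),
    time_error_s = vapply(tpIdx, function(i) .pairTimeError(
      c(dets$start_frame[i], dets$end_frame[i]),
      c(gts$start_frame[match[i]], gts$end_frame[match[i]]), fps),
      numeric(1)))
  else data.frame(det_start = integer(), det_end = integer(),
                  confidence = numeric(), gt_start = integer(),
                  gt_end = integer(), iou = numeric(),
                  time_error_s = numeric())
  new("MatchResult",
      tpPairs = tp,
      fp = dets[kind == "fp", , drop = FALSE],
      ignored = dets[kind == "ignored", , drop = FALSE],
      fn = gts[setdiff(seq_len(ng), match[tpIdx]), , drop = FALSE])
}

#' Precision, recall and F1 from pooled confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and F1 is
#' their harmonic mean. Ignored detections are excluded from the
#' precision denominator (they are neither correct nor spurious).
#' Undefined ratios (zero denominators) are returned as `NaN` with a
#' warning rather than an error. Percent rendering in reports rounds
#' half-up to 2 decimals.
#'
#' @param TP,FP,FN non-negative confusion counts.
#' @return list with `precision`, `recall`, `f1` (proportions),
#'   their percent renderings (`*_pct`), and the counts.
#' @examples
#' m <- precisionRecallF1(466, 184, 157)
#' c(m$precision_pct, m$recall_pct, m$f1_pct)
#' @export
precisionRecallF1 <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  precision <- if (TP + FP > 0) TP / (TP + FP) else {
    warning("precision undefined: no predicted detections"); NaN
  }
  recall <- if (TP + FN > 0) TP / (TP + FN) else {
    warning("recall undefined: no true detections"); NaN
  }
  f1 <- if (is.finite(precision) && is.finite(recall) &&
            precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else NaN
  list(precision = precision, recall = recall, f1 = f1,
       precision_pct = roundHalfUp(100 * precision, 2),
       recall_pct = roundHalfUp(100 * recall, 2),
       f1_pct = roundHalfUp(100 * f1, 2),
       TP = TP, FP = FP, FN = FN)
}

#' Mean detection time error over matched pairs
#'
#' Per TP pair, the error is the mean of the absolute start, middle
#' and end frame differences (middle = (start + end) / 2, computed on
#' real-valued frame positions) converted to seconds; the result is
#' the mean over pairs.
#'
#' @param tpPairs the `tpPairs` data.frame of a [MatchResult-class]
#'   (or a [MatchResult-class] itself).
#' @param fps frame rate (default 15).
#' @return mean time error in seconds (`NaN` with a warning when there
#'   are no pairs).
#' @export
detectionTimeError <- function(tpPairs, fps = 15) {
  if (is(tpPairs, "MatchResult")) tpPairs <- tpPairs@tpPairs
  if (nrow(tpPairs) == 0L) {
    warning("time error undefined: no matched detections")
    return(NaN)
  }
  errs <- mapply(function(a, b, c, d)
    .pairTimeError(c(a, b), c(c, d), fps),
    tpPairs$det_start, tpPairs$det_end, tpPairs$gt_start, tpPairs$gt_end)
  mean(errs)
}

#' Merge two annotators' interval labels
#'
#' The consensus ground truth averages the two annotators' endpoints,
#' rounding half away from zero. Intervals must describe the same
#' event occurrence in the same video.
#'
#' @param a,b length-2 vectors `c(start, end)` or 1-row data.frames
#'   with `start_frame`, `end_frame` (and matching `video_id`).
#' @return the merged interval in the same form as `a`.
#' @examples
#' mergeAnnotations(c(10, 20), c(12, 24))  # c(11, 22)
#' @export
mergeAnnotations <- function(a, b) {
  if (is.data.frame(a)) {
    if (!is.null(a$video_id) && !is.null(b$video_id) &&
        !identical(a$video_id, b$video_id))
      stopf("cannot merge annotations from different videos ('%s' vs '%s')",
            a$video_id, b$video_id)
    a$start_frame <- as.integer(roundHalfUp((a$start_frame + b$start_frame) / 2))
    a$end_frame <- as.integer(roundHalfUp((a$end_frame + b$end_frame) / 2))
    return(a)
  }
  as.integer(roundHalfUp((a + b) / 2))
}

#' Fraction of videos with every occurrence missed
#'
#' A video counts as missed when its [MatchResult-class] has no TP
#' pair at all. Rendered as a percent rounded half-up to 1 decimal.
#'
#' @param perVideoResults list of [MatchResult-class] objects, one per
#'   video.
#' @return list with `missed`, `nVideos`, `rate` (proportion) and
#'   `rate_pct`.
#' @examples
#' # 18 of 215 videos without any detected occurrence -> 8.4%
#' @export
missRate <- function(perVideoResults) {
  stopifnot(length(perVideoResults) >= 1L)
  missed <- sum(vapply(perVideoResults,
                       function(m) nrow(m@tpPairs) == 0L, logical(1)))
  n <- length(perVideoResults)
  list(missed = missed, nVideos = n, rate = missed / n,
       rate_pct = roundHalfUp(100 * missed / n, 1))
}

#' Corpus-level evaluation across videos
#'
#' Matches detections to ground truth per video and pools TP/FP/FN
#' counts (micro-averaging) into precision, recall, F1, mean detection
#' time error and miss rate.
#'
#' @param dets detection data.frame (`video_id`, `start_frame`,
#'   `end_frame`, `confidence`).
#' @param gts ground-truth data.frame (`video_id`, `start_frame`,
#'   `end_frame`). Videos present here but absent from `dets` count
#'   all their occurrences as FN.
#' @param iouTh IOU threshold (default 0.3).
#' @param fps frame rate (default 15).
#' @return list with the pooled `metrics` ([precisionRecallF1()]
#'   output), `timeErrorS`, `missRate`, and the per-video
#'   [MatchResult-class] list.
#' @export
evaluateDetections <- function(dets, gts, iouTh = 0.3, fps = 15) {
  vids <- unique(gts$video_id)
  results <- lapply(vids, function(v) {
    matchDetections(dets[dets$video_id == v, , drop = FALSE],
                    gts[gts$video_id == v, , drop = FALSE],
                    iouTh = iouTh, fps = fps)
  })
  names(results) <- vids
  # detections for videos without any ground truth are pure FPs
  extra <- dets[!dets$video_id %in% vids, , drop = FALSE]
  TP <- sum(vapply(results, function(m) nrow(m@tpPairs), numeric(1)))
  FP <- sum(vapply(results, function(m) nrow(m@fp), numeric(1))) + nrow(extra)
  FN <- sum(vapply(results, function(m) nrow(m@fn), numeric(1)))
  allPairs <- do.call(rbind, lapply(results, function(m) m@tpPairs))
  te <- if (!is.null(allPairs) && nrow(allPairs) > 0)
    mean(allPairs$time_error_s) else NaN
  list(metrics = suppressWarnings(precisionRecallF1(TP, FP, FN)),
       timeErrorS = te,
       missRate = missRate(results),
       perVideo = results)
}
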