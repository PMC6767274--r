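#' Sliding-window classifier scores over an untrimmed video
#'
#' Scores 20-frame windows placed every `stride` frames from the start
#' of the sequence; the last window is clamped so it ends at the final
#' frame. Window/stride of 20/5 give a dense search at moderate
#' inference cost.
#'
#' @param seq a [FrameSequence-class] with at least `window` frames.
#' @param net trained network (result of [trainNetwork()] or a bare
#'   network object).
#' @param window window length in frames (default 20).
#' @param stride window stride in frames (default 5).
#' @param size spatial size clips are resized to (must match the
#'   network's `inputSize`).
#' @return data.frame with `window_start` (0-based) and `score`.
#' @export
windowScores <- function(seq, net, window = 20L, stride = 5L, size = NULL) {
  stopifnot(is(seq, "FrameSequence"))
  T0 <- nFrames(seq)
  if (T0 < window)
    stopf("sequence of %d frames is shorter than the window (%d)", T0, window)
  nn <- if (!is.null(net$net)) net$net else net
  if (is.null(size)) size <- nn$cfg$inputSize
  starts <- seq(0L, T0 - window, by = stride)
  if (tail(starts, 1L) != T0 - window)
    starts <- c(starts, T0 - window)  # clamp final window to the end
  clips <- lapply(starts, function(s) extractClip(seq, s, "rgb", size = size))
  data.frame(window_start = as.integer(starts),
             score = classifyClips(net, clips))
}

#' Per-frame scores from window scores
#'
#' Each frame's score is the mean of the scores of all windows
#' covering it (an unbiased, order-independent mapping); frames beyond
#' the last window inherit the nearest window's score.
#'
#' @param ws data.frame from [windowScores()].
#' @param T number of frames in the sequence.
#' @param window window length used when scoring.
#' @return numeric score vector of length `T`.
#' @export
frameScores <- function(ws, T, window = 20L) {
  if (nrow(ws) == 0L) stopf("no window scores given")
  s <- numeric(T)
  cnt <- numeric(T)
  for (i in seq_len(nrow(ws))) {
    idx <- (ws$window_start[i] + 1L):min(ws$window_start[i] + window, T)
    s[idx] <- s[idx] + ws$score[i]
    cnt[idx] <- cnt[idx] + 1
  }
  covered <- cnt > 0
  s[covered] <- s[covered] / cnt[covered]
  if (any(!covered)) {
    ci <- which(covered)
    for (i in which(!covered)) s[i] <- s[ci[which.min(abs(ci - i))]]
  }
  s
}

#' Moving-average smoothing of per-frame scores
#'
#' Centered moving average of odd width with edge replication; width 1
#' is the identity. Applied before thresholding to suppress isolated
#' mis-classifications.
#'
#' @param s per-frame scores.
#' @param width odd window width (default 5).
#' @return smoothed scores, same length.
#' @examples
#' smoothScores(c(0, 0, 1, 0, 0), width = 3)
#' @export
smoothScores <- function(s, width = 5L) {
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L)
    stopf("smoothing width must be odd and >= 1, got %d", width)
  if (width == 1L) return(s)
  h <- width %/% 2L
  padded <- c(rep(s[1], h), s, rep(s[length(s)], h))
  as.numeric(stats::filter(padded, rep(1 / width, width), sides = 2))[
    (h + 1L):(h + length(s))]
}

#' Extract detection intervals from smoothed frame scores
#'
#' Maximal runs of frames whose score strictly exceeds `scoreth`
#' become detections when their length strictly exceeds `frameth`
#' frames; a run still open at the end of the video is closed at the
#' last frame. The confidence of a detection is the mean score over
#' the run plus a small length bonus `lam * runLength`, so longer
#' equally confident runs rank higher in confidence-ordered
#' evaluation.
#'
#' @param s smoothed per-frame scores.
#' @param scoreth frame-marking threshold (default 0.5).
#' @param frameth minimum run length in frames, exclusive (default 5).
#' @param lam length-bonus weight in the confidence (default 0.001).
#' @return data.frame of 0-based inclusive `start_frame`, `end_frame`,
#'   `confidence`, sorted by `start_frame` (possibly empty).
#' @export
extractIntervals <- function(s, scoreth = 0.5, frameth = 5L, lam = 0.001) {
  stopifnot(all(is.finite(s)))
  above <- s > scoreth
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > frameth
  if (!any(keep))
    return(data.frame(start_frame = integer(), end_frame = integer(),
                      confidence = numeric()))
  st <- starts[keep]; en <- ends[keep]
  conf <- mapply(function(a, b) mean(s[a:b]) + lam * (b - a + 1L), st, en)
  data.frame(start_frame = as.integer(st - 1L),
             end_frame = as.integer(en - 1L),
             confidence = as.numeric(conf))
}

#' Pad detection intervals for clinician review
#'
#' Extends each interval by `pad` frames on both sides (clamped to the
#' video), compensating for detection time error when exporting review
#' segments. Confidences are unchanged and overlapping extended
#' intervals are not merged; evaluation always uses the unextended
#' intervals.
#'
#' @param d detection data.frame from [extractIntervals()].
#' @param pad frames added on each side (default 10).
#' @param T number of frames in the video.
#' @return the padded data.frame.
#' @export
extendIntervals <- function(d, pad = 10L, T) {
  stopifnot(pad >= 0)
  if (nrow(d) == 0L) return(d)
  d$start_frame <- pmax(d$start_frame - as.integer(pad), 0L)
  d$end_frame <- pmin(d$end_frame + as.integer(pad), as.integer(T) - 1L)
  d
}

#' End-to-end detection on one untrimmed video
#'
#' Composes [windowScores()], [frameScores()], [smoothScores()] and
#' [extractIntervals()].
#'
#' @inheritParams windowScores
#' @param scoreth,frameth,lam interval extraction parameters.
#' @param smoothWidth smoothing width (default 5).
#' @return data.frame of detections with a `video_id` column.
#' @export
detectEvents <- function(seq, net, window = 20L, stride = 5L,
                         scoreth = 0.5, frameth = 5L, lam = 0.001,
                         smoothWidth = 5L, size = NULL) {
  ws <- windowScores(seq, net, window = window, stride = stride, size = size)
  fs <- frameScores(ws, nFrames(seq), window = window)
  sm <- smoothScores(fs, width = smoothWidth)
  d <- extractIntervals(sm, scoreth = scoreth, frameth = frameth, lam = lam)
  if (nrow(d) > 0L) d$video_id <- sourceId(seq)
  else d$video_id <- character()
  d
}
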