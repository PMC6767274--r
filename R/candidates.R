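#' Central region of a frame
#'
#' The pharynx sits mid-frame in a lateral VFSS view, so motion voting
#' only looks at an axis-aligned box covering the central `fraction` of
#' each dimension. Bounds are 0-based inclusive row/column indices:
#' offset `floor((1 - fraction) * extent / 2)` on each side.
#'
#' @param h,w frame height and width in pixels.
#' @param fraction fraction of each dimension covered (default 0.5).
#' @return list with 0-based inclusive `row0,row1,col0,col1`.
#' @examples
#' centerRegion(224, 224, 0.5)  # rows/cols 56..167
#' @export
centerRegion <- function(h, w, fraction = 0.5) {
  if (h <= 0 || w <= 0) stopf("frame dimensions must be positive")
  if (fraction <= 0 || fraction > 1)
    stopf("fraction must be in (0, 1]")
  offR <- floor((1 - fraction) * h / 2)
  offC <- floor((1 - fraction) * w / 2)
  nR <- max(1L, round(fraction * h))
  nC <- max(1L, round(fraction * w))
  list(row0 = as.integer(offR), row1 = as.integer(min(h - 1, offR + nR - 1)),
       col0 = as.integer(offC), col1 = as.integer(min(w - 1, offC + nC - 1)))
}

#' Vote for frames with strong central vertical motion
#'
#' For each flow step t whose maximum absolute normalized vertical (Y)
#' component inside the central region exceeds `fth`, one vote is added
#' to the tally of step t and its eight nearest steps (radius 4 on each
#' side, clipped at the sequence ends). With unit votes and radius 4 a
#' tally entry can reach at most 9.
#'
#' @param m a normalized [MotionMap-class].
#' @param fth flow trigger threshold on the `[-1, 1]` scale
#'   (default 0.4, i.e. 4 px/frame before normalization).
#' @param region central region bounds from [centerRegion()];
#'   computed from the flow dimensions and `fraction` when `NULL`.
#' @param radius vote neighbourhood radius (default 4: the frame plus
#'   its eight nearest frames).
#' @param fraction central-region fraction used when `region` is NULL.
#' @return numeric vote tally, one entry per flow step.
#' @export
voteFrames <- function(m, fth = 0.4, region = NULL, radius = 4L,
                       fraction = 0.5) {
  stopifnot(is(m, "MotionMap"))
  if (!m@normalized)
    stopf("voteFrames requires a normalized MotionMap")
  d <- dim(m@flow)
  if (is.null(region)) region <- centerRegion(d[2], d[3], fraction)
  rows <- (region$row0:region$row1) + 1L
  cols <- (region$col0:region$col1) + 1L
  nT <- d[1]
  votes <- numeric(nT)
  for (t in seq_len(nT)) {
    peak <- max(abs(m@flow[t, rows, cols, 2]))
    if (peak > fth) {
      lo <- max(1L, t - radius)
      hi <- min(nT, t + radius)
      votes[lo:hi] <- votes[lo:hi] + 1
    }
  }
  votes
}

#' Select up to five non-overlapping candidate clips from a vote tally
#'
#' Frames are visited in descending vote order (ties broken by the
#' earlier frame). A frame t is accepted as a candidate peak when its
#' tally strictly exceeds `vth` and t does not fall inside any
#' previously accepted candidate's 20-frame span. Each accepted peak
#' yields a clip starting at `t - 10`, clamped so the whole clip lies
#' within the sequence. Selection stops after `maxCandidates`
#' acceptances or when the tally is exhausted.
#'
#' Vote tally indices are flow-step indices; peak step t maps to video
#' frame t (the earlier frame of the pair).
#'
#' @param tally numeric vote tally from [voteFrames()].
#' @param vth vote threshold (default 2.5; with unit votes acceptance
#'   therefore needs a tally of at least 3).
#' @param maxCandidates maximum number of candidates (default 5).
#' @param clipLen candidate clip length in frames (default 20).
#' @param seqLen number of frames in the parent sequence; must be at
#'   least `clipLen`.
#' @return data.frame with 0-based inclusive `start_frame`,
#'   `end_frame`, `peak_frame`, and `vote_score`, sorted by
#'   `start_frame`. Zero rows when nothing exceeds the threshold.
#' @export
selectCandidates <- function(tally, vth = 2.5, maxCandidates = 5L,
                             clipLen = 20L, seqLen) {
  if (missing(seqLen)) stopf("seqLen is required")
  if (seqLen < clipLen)
    stopf("sequence of %d frames is shorter than the clip length %d",
          seqLen, clipLen)
  half <- clipLen %/% 2L
  ord <- order(-tally, seq_along(tally))  # descending, earlier frame first
  acc <- list()
  for (i in ord) {
    if (length(acc) >= maxCandidates) break
    if (tally[i] <= vth) break  # sorted: nothing later can exceed vth
    t0 <- i - 1L                # 0-based flow-step / frame index
    inside <- vapply(acc, function(a) t0 >= a$start && t0 <= a$end, logical(1))
    if (any(inside)) next
    start <- as.integer(min(max(t0 - half, 0L), seqLen - clipLen))
    acc[[length(acc) + 1L]] <- list(start = start, end = start + clipLen - 1L,
                                    peak = as.integer(t0),
                                    score = as.numeric(tally[i]))
  }
  if (length(acc) == 0L)
    return(data.frame(start_frame = integer(), end_frame = integer(),
                      peak_frame = integer(), vote_score = numeric()))
  df <- data.frame(
    start_frame = vapply(acc, `[[`, integer(1), "start"),
    end_frame = vapply(acc, `[[`, integer(1), "end"),
    peak_frame = vapply(acc, `[[`, integer(1), "peak"),
    vote_score = vapply(acc, `[[`, numeric(1), "score"))
  df <- df[order(df$start_frame), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Harvest candidate clips from an untrimmed sequence
#'
#' Composes the full candidate-generation stage: TV-L1 flow,
#' normalization, central vertical-motion voting, candidate selection,
#' and clip extraction. Returns the candidate interval table plus the
#' extracted clip tensors for the requested streams.
#'
#' @param seq a [FrameSequence-class] (nominally at 15 FPS).
#' @param fth,vth,radius,fraction,maxCandidates voting/selection
#'   parameters, see [voteFrames()] and [selectCandidates()].
#' @param streams which clip streams to extract (`"rgb"`, `"flow"`, or
#'   both). An empty character vector skips extraction.
#' @param size spatial clip size (default 224).
#' @param flowParams TV-L1 parameters from [tvl1Params()].
#' @param flow optional precomputed unnormalized [MotionMap-class] for
#'   `seq` (skips the flow computation).
#' @return list with `candidates` (the interval data.frame), `tally`,
#'   and `clips` (a list per candidate holding the requested
#'   [Clip-class] objects).
#' @export
harvestTrainingClips <- function(seq, fth = 0.4, vth = 2.5, radius = 4L,
                                 fraction = 0.5, maxCandidates = 5L,
                                 streams = "rgb", size = 224L,
                                 flowParams = tvl1Params(), flow = NULL) {
  stopifnot(is(seq, "FrameSequence"))
  if (is.null(flow)) flow <- computeFlow(seq, flowParams)
  nm <- if (isNormalized(flow)) flow else normalizeFlow(flow)
  tally <- voteFrames(nm, fth = fth, radius = radius, fraction = fraction)
  cand <- selectCandidates(tally, vth = vth, maxCandidates = maxCandidates,
                           seqLen = nFrames(seq))
  clips <- vector("list", nrow(cand))
  Tf <- dim(nm@flow)[1]
  for (i in seq_len(nrow(cand))) {
    cl <- list()
    if ("rgb" %in% streams)
      cl$rgb <- extractClip(seq, cand$start_frame[i], "rgb", size = size)
    if ("flow" %in% streams) {
      fs <- min(cand$start_frame[i], Tf - 20L)  # flow has one fewer step
      cl$flow <- extractClip(NULL, fs, "flow", size = size, flow = nm)
    }
    clips[[i]] <- cl
  }
  cand$video_id <- rep(sourceId(seq), nrow(cand))
  list(candidates = cand, tally = tally, clips = clips)
}
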