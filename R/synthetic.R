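#' Specification for a synthetic fluoroscopy-like video
#'
#' The generator emulates the statistical structure the cascade
#' assumes in lateral VFSS recordings: a static high-contrast
#' background (a bright vertical column mimicking the cervical spine
#' off-center over a darker soft-tissue field, plus low-frequency
#' texture), one or more brief swallowing events in which a bright
#' elliptical bolus blob enters the upper-center region and descends
#' through the central image region, and distractor motions that move
#' pixels without being events: whole-frame horizontal head
#' translation, small-amplitude vertical oscillation ("coughing"-style
#' jitter with zero net displacement), and per-frame sensor noise.
#'
#' Bolus transit is modeled as an accelerating descent: the
#' instantaneous vertical speed ramps linearly from 0 to twice the
#' drawn mean speed over the event (a ballistic profile), so the event
#' reliably crosses the flow-vote threshold in its second half while
#' its mean speed stays in `eventSpeedRange`. All magnitudes are in
#' pixels per frame, so the flow-normalization threshold arithmetic
#' (speed / 10 vs `fth`) is analytically predictable.
#'
#' Events are pairwise separated by at least 20 frames.
#'
#' @param seed RNG seed; generation is fully deterministic given the
#'   spec.
#' @param durationFrames video length in frames (default 105, i.e. 7 s
#'   at 15 FPS — a typical trimmed swallow segment, and long enough
#'   that even three maximum-length events fit with the required
#'   separations).
#' @param fps frame rate metadata (default 15).
#' @param nEvents number of swallowing events (default 2).
#' @param eventDurationRange event length range in frames
#'   (default 8–20, i.e. roughly 0.5–1.3 s).
#' @param eventSpeedRange mean vertical speed range in px/frame
#'   (default 3–8).
#' @param distractors list with `horizontalShift` (px/frame head
#'   translation during one go-and-return episode; 0 disables),
#'   `oscillation` (peak vertical jitter velocity in px/frame; keep
#'   below 4 so it stays under the vote threshold, raise above for
#'   hard negatives) and `staticNoise` (Gaussian sd of sensor noise).
#' @param backgroundContrast brightness of the spine column over the
#'   soft-tissue field (default 0.5).
#' @param frameSize `c(H, W)` (default `c(224, 224)`).
#' @param eventsOffCenter if `TRUE`, events descend outside the
#'   central region (a known-miss fixture for the candidate stage).
#' @param sourceId identifier for the generated sequence.
#' @return a `SynthSpec` list.
#' @export
synthSpec <- function(seed = 1L, durationFrames = 105L, fps = 15,
                      nEvents = 2L, eventDurationRange = c(8L, 20L),
                      eventSpeedRange = c(3, 8),
                      distractors = list(horizontalShift = 5,
                                         oscillation = 1.5,
                                         staticNoise = 0.01),
                      backgroundContrast = 0.5,
                      frameSize = c(224L, 224L),
                      eventsOffCenter = FALSE,
                      sourceId = sprintf("synth_%d", seed)) {
  d <- list(horizontalShift = 5, oscillation = 1.5, staticNoise = 0.01)
  d[names(distractors)] <- distractors
  structure(list(seed = as.integer(seed),
                 durationFrames = as.integer(durationFrames), fps = fps,
                 nEvents = as.integer(nEvents),
                 eventDurationRange = as.integer(eventDurationRange),
                 eventSpeedRange = eventSpeedRange, distractors = d,
                 backgroundContrast = backgroundContrast,
                 frameSize = as.integer(frameSize),
                 eventsOffCenter = eventsOffCenter, sourceId = sourceId),
            class = "SynthSpec")
}

# subpixel whole-frame shift with replicated borders (bilinear);
# out[r, c] = m[r + dy, c + dx]
.shiftMatrix <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  r <- pmin(pmax(seq_len(H) + dy, 1), H)
  c <- pmin(pmax(seq_len(W) + dx, 1), W)
  r0 <- floor(r); r1 <- pmin(r0 + 1, H); fr <- r - r0
  c0 <- floor(c); c1 <- pmin(c0 + 1, W); fc <- c - c0
  FR <- matrix(fr, H, W); FC <- matrix(fc, H, W, byrow = TRUE)
  (1 - FR) * (1 - FC) * m[r0, c0] + (1 - FR) * FC * m[r0, c1] +
    FR * (1 - FC) * m[r1, c0] + FR * FC * m[r1, c1]
}

# place nEvents intervals of the given durations with >= 20-frame
# separations and a 1-frame margin at both video ends; constructive
# (slack distributed by sorted uniform draws), so placement never
# needs rejection retries and errors exactly when the events cannot
# fit
.placeEvents <- function(nE, durs, T) {
  if (nE == 0L) return(integer())
  slack <- T - 2L - sum(durs) - 21L * (nE - 1L)
  if (slack < 0L)
    stopf("cannot place %d separated events (total %d frames) in %d frames",
          nE, sum(durs), T)
  u <- sort(sample.int(slack + 1L, nE, replace = TRUE) - 1L)
  starts <- integer(nE)
  prevEnd <- 1L
  for (i in seq_len(nE)) {
    gap <- if (i == 1L) u[1L] else 21L + (u[i] - u[i - 1L])
    starts[i] <- prevEnd + gap + 1L
    prevEnd <- starts[i] + durs[i] - 1L
  }
  starts
}

#' Generate a synthetic fluoroscopy video with ground truth
#'
#' See [synthSpec()] for the scene model. Fully deterministic given
#' the spec (the caller's RNG state is untouched).
#'
#' @param spec a [synthSpec()].
#' @return list with `seq` (a [FrameSequence-class]),
#'   `groundTruth` (data.frame `video_id,start_frame,end_frame`,
#'   0-based inclusive), and `eventPaths` (per event, the blob center
#'   row per frame).
#' @export
generateVideo <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  H <- spec$frameSize[1]; W <- spec$frameSize[2]
  T <- spec$durationFrames
  sc <- H / 224
  withSeed(spec$seed, {
    # static background: soft-tissue field + bright spine column +
    # low-frequency texture the flow solver can anchor to
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    spineC <- 0.66 * W
    bg <- 0.22 +
      spec$backgroundContrast * exp(-0.5 * ((cc - spineC) / (0.045 * W))^2) +
      0.06 * sin(2 * pi * rr / (0.31 * H)) * cos(2 * pi * cc / (0.23 * W)) +
      0.04 * sin(2 * pi * (rr + cc) / (0.17 * H))
    # faint mandible line in the upper left
    bg <- bg + 0.08 * exp(-0.5 * ((rr - 0.3 * H - 0.2 * (cc - W / 2)) /
                                    (0.02 * H))^2)

    durs <- if (spec$nEvents > 0)
      sample(spec$eventDurationRange[1]:spec$eventDurationRange[2],
             spec$nEvents, replace = TRUE) else integer()
    starts <- .placeEvents(spec$nEvents, durs, T)
    speeds <- if (spec$nEvents > 0)
      runif(spec$nEvents, spec$eventSpeedRange[1], spec$eventSpeedRange[2])
    else numeric()
    xc0 <- if (spec$eventsOffCenter) 0.12 * W else
      W / 2 + runif(max(spec$nEvents, 1), -0.05, 0.05) * W

    # distractor schedules
    dx <- numeric(T); dy <- numeric(T)
    hs <- spec$distractors$horizontalShift
    if (hs > 0 && T >= 30L) {
      # one go-and-return head translation away from events
      busy <- rep(FALSE, T)
      for (i in seq_along(starts))
        busy[max(1, starts[i] - 10):min(T, starts[i] + durs[i] + 10)] <- TRUE
      cand <- which(!busy[1:(T - 12L)])
      cand <- cand[cand > 1]
      if (length(cand) > 0) {
        s0 <- sample(cand, 1)
        prof <- c(seq(0, hs * 5, by = hs), seq(hs * 5 - hs, hs, by = -hs))
        idx <- s0 + seq_along(prof) - 1L
        ok <- idx <= T
        dx[idx[ok]] <- prof[ok]
      }
    }
    osc <- spec$distractors$oscillation
    if (osc > 0) {
      period <- 8
      amp <- osc * period / (2 * pi)  # peak velocity ~= osc px/frame
      dy <- amp * sin(2 * pi * seq_len(T) / period)
    }

    frames <- array(0, c(T, H, W, 1L))
    sigY <- 10 * sc; sigX <- 6.5 * sc
    for (t in seq_len(T)) {
      f <- if (dx[t] != 0 || dy[t] != 0) .shiftMatrix(bg, dy[t], dx[t]) else bg
      for (i in seq_along(starts)) {
        i0 <- t - starts[i]  # 0-based frame index within the event
        if (i0 >= 0 && i0 < durs[i]) {
          u <- if (durs[i] > 1) i0 / (durs[i] - 1) else 1
          yc <- 0.12 * H + speeds[i] * durs[i] * u^2
          xc <- xc0[min(i, length(xc0))]
          f <- f + 0.55 * exp(-0.5 * (((rr - yc) / sigY)^2 +
                                        ((cc - xc) / sigX)^2))
        }
      }
      if (spec$distractors$staticNoise > 0)
        f <- f + matrix(rnorm(H * W, 0, spec$distractors$staticNoise), H, W)
      frames[t, , , 1] <- pmin(pmax(f, 0), 1)
    }

    gt <- data.frame(video_id = rep(spec$sourceId, spec$nEvents),
                     start_frame = as.integer(starts - 1L),
                     end_frame = as.integer(starts + durs - 2L))
    paths <- lapply(seq_along(starts), function(i) {
      u <- if (durs[i] > 1) (0:(durs[i] - 1)) / (durs[i] - 1) else 1
      0.12 * H + speeds[i] * durs[i] * u^2
    })
    list(seq = FrameSequence(frames, fps = spec$fps,
                             sourceId = spec$sourceId),
         groundTruth = gt, eventPaths = paths)
  })
}

#' Sample negative (non-event) 20-frame windows
#'
#' Picks window starts whose 20-frame span stays at least `minGap`
#' frames away from every ground-truth event — background, noise and
#' distractor motion only.
#'
#' @param seq a [FrameSequence-class].
#' @param gt ground-truth data.frame for `seq`.
#' @param n number of windows wanted (fewer are returned when the
#'   video has little free room).
#' @param minGap minimum distance to any event in frames.
#' @return integer vector of 0-based window starts.
#' @export
sampleNegativeWindows <- function(seq, gt, n, minGap = 10L) {
  T0 <- nFrames(seq)
  ok <- rep(TRUE, T0 - 19L)
  for (i in seq_len(nrow(gt))) {
    lo <- max(1L, gt$start_frame[i] - minGap - 19L + 1L)
    hi <- min(T0 - 19L, gt$end_frame[i] + minGap + 1L)
    if (lo <= hi) ok[lo:hi] <- FALSE
  }
  starts <- which(ok) - 1L
  if (length(starts) == 0L) return(integer())
  starts[round(seq(1, length(starts), length.out = min(n, length(starts))))]
}

#' Generate a labeled clip dataset
#'
#' Positives are 20-frame windows centered on synthetic swallowing
#' events; negatives are 20-frame windows over distractor motion
#' (half vertical-oscillation "coughing", half horizontal head
#' translation) or static noisy background. Class-balanced and fully
#' seeded: the same seed reproduces the identical dataset.
#'
#' @param nPos,nNeg numbers of positive and negative clips (>= 1).
#' @param seed RNG seed.
#' @param size spatial clip size (default 224).
#' @param streams clip streams to return (`"rgb"` and/or `"flow"`).
#' @param frameSize frame size of the underlying synthetic videos.
#' @param flowParams TV-L1 parameters, used when `"flow"` is
#'   requested.
#' @return list with `clips` (list of per-clip lists holding the
#'   requested [Clip-class] objects) and `labels`
#'   (`"pharyngeal"` / `"other"`).
#' @export
generateClipDataset <- function(nPos, nNeg, seed = 1L, size = 224L,
                                streams = "rgb",
                                frameSize = c(224L, 224L),
                                flowParams = tvl1Params()) {
  stopifnot(nPos >= 1L, nNeg >= 1L)
  mk <- function(i, positive) {
    s <- synthSpec(seed = seed * 10000L + i,
                   durationFrames = 48L,
                   nEvents = if (positive) 1L else 0L,
                   frameSize = frameSize,
                   distractors = if (positive)
                     list(horizontalShift = 0, oscillation = 1.5,
                          staticNoise = 0.01)
                   else if (i %% 2L == 0L)
                     list(horizontalShift = 5, oscillation = 1.5,
                          staticNoise = 0.01)
                   else
                     list(horizontalShift = 0, oscillation = 3,
                          staticNoise = 0.01),
                   sourceId = sprintf("clip_%s_%d",
                                      if (positive) "pos" else "neg", i))
    g <- generateVideo(s)
    T0 <- nFrames(g$seq)
    start <- if (positive) {
      mid <- (g$groundTruth$start_frame[1] + g$groundTruth$end_frame[1]) %/% 2
      min(max(mid - 10L, 0L), T0 - 20L)
    } else {
      withSeed(seed * 20000L + i, sample.int(T0 - 19L, 1L) - 1L)
    }
    cl <- list()
    if ("rgb" %in% streams)
      cl$rgb <- extractClip(g$seq, start, "rgb", size = size)
    if ("flow" %in% streams) {
      sub <- new("FrameSequence",
                 frames = frames(g$seq)[(start + 1L):(start + 21L), , , ,
                                        drop = FALSE],
                 fps = fps(g$seq), sourceId = sourceId(g$seq))
      nm <- normalizeFlow(computeFlow(sub, flowParams))
      cl$flow <- extractClip(NULL, 0L, "flow", size = size, flow = nm)
    }
    cl
  }
  clips <- c(lapply(seq_len(nPos), mk, positive = TRUE),
             lapply(seq_len(nNeg), mk, positive = FALSE))
  list(clips = clips,
       labels = c(rep("pharyngeal", nPos), rep("other", nNeg)))
}
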