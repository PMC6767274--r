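#' FrameSequence: an ordered stack of video frames
#'
#' Container for the raw unit every stage of the cascade consumes: a
#' `T x H x W x C` array of frames (pixel values on the `[0, 1]` real
#' scale), the frame rate, and an identifier for the source recording.
#' Grayscale fluoroscopy has `C = 1`; 3-channel input is accepted and
#' converted to grayscale where flow is computed.
#'
#' @slot frames numeric array `T x H x W x C`, values in `[0, 1]`.
#' @slot fps frames per second (positive).
#' @slot sourceId identifier of the source recording.
#' @export
setClass("FrameSequence",
  representation(frames = "array", fps = "numeric", sourceId = "character"),
  validity = function(object) {
    d <- dim(object@frames)
    if (length(d) != 4L)
      return("frames must be a T x H x W x C array")
    if (d[1] < 1L) return("need at least one frame")
    if (!d[4] %in% c(1L, 3L)) return("channel count must be 1 or 3")
    if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
      return("fps must be a single positive number")
    TRUE
  })

#' MotionMap: dense optical flow for a frame sequence
#'
#' Per consecutive frame pair, a 2-component displacement field
#' (`X` horizontal, `Y` vertical with positive Y pointing down the
#' image), stored as a `(T-1) x H x W x 2` array. Raw flow is in
#' pixels; after [normalizeFlow()] every component lies in `[-1, 1]`
#' and `normalized` is `TRUE`.
#'
#' @slot flow numeric array `(T-1) x H x W x 2`.
#' @slot normalized whether truncation/scaling has been applied.
#' @slot sourceId identifier of the source recording.
#' @export
setClass("MotionMap",
  representation(flow = "array", normalized = "logical",
                 sourceId = "character"),
  validity = function(object) {
    d <- dim(object@flow)
    if (length(d) != 4L || d[4] != 2L)
      return("flow must be a (T-1) x H x W x 2 array")
    if (d[1] < 1L) return("need at least one flow step")
    if (isTRUE(object@normalized) &&
        any(abs(object@flow) > 1 + 1e-12, na.rm = TRUE))
      return("normalized flow components must lie in [-1, 1]")
    TRUE
  })

#' Clip: a fixed-length window cut from a FrameSequence
#'
#' A 20-frame window resized to the network input resolution. The
#' `rgb` stream has 3 channels (grayscale replicated); the `flow`
#' stream has 2 (the X/Y flow components).
#'
#' @slot frames numeric array `L x H' x W' x C` with `L = 20`.
#' @slot startFrame 0-based index of the window start in the parent
#'   sequence.
#' @slot stream `"rgb"` or `"flow"`.
#' @export
setClass("Clip",
  representation(frames = "array", startFrame = "integer",
                 stream = "character"),
  validity = function(object) {
    d <- dim(object@frames)
    if (length(d) != 4L) return("frames must be L x H' x W' x C")
    if (d[1] != 20L) return("clip length must be exactly 20 frames")
    if (!object@stream %in% c("rgb", "flow"))
      return("stream must be 'rgb' or 'flow'")
    wantC <- if (object@stream == "rgb") 3L else 2L
    if (d[4] != wantC)
      return(sprintf("stream '%s' requires %d channels, got %d",
                     object@stream, wantC, d[4]))
    if (object@startFrame < 0L) return("startFrame must be >= 0")
    TRUE
  })

#' MatchResult: TP/FP/FN/ignored partition of detections
#'
#' Output of [matchDetections()]: the confidence-ordered greedy
#' assignment of predicted detection intervals to ground-truth
#' intervals under the temporal-IOU criterion. Every detection lands in
#' exactly one of `tpPairs` / `fp` / `ignored`; every ground truth is
#' claimed by at most one detection, and unclaimed ones make up `fn`.
#'
#' @slot tpPairs data.frame of matched pairs (detection and ground
#'   truth endpoints, confidence, IOU, per-pair time error in seconds).
#' @slot fp data.frame of unmatched detections.
#' @slot fn data.frame of unmatched ground truths.
#' @slot ignored data.frame of detections whose only overlapping ground
#'   truths were already claimed by higher-confidence detections.
#' @export
setClass("MatchResult",
  representation(tpPairs = "data.frame", fp = "data.frame",
                 fn = "data.frame", ignored = "data.frame"),
  validity = function(object) {
    TRUE
  })

#' @describeIn FrameSequence number of frames, height, width, channels
#' @param x a `FrameSequence`
#' @export
setMethod("dim", "FrameSequence", function(x) dim(x@frames))

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameSequence '%s': %d frames, %dx%d, %d channel(s), %.6g FPS\n",
              object@sourceId, d[1], d[2], d[3], d[4], object@fps))
})

setMethod("show", "MotionMap", function(object) {
  d <- dim(object@flow)
  cat(sprintf("MotionMap '%s': %d flow steps, %dx%d, %s\n",
              object@sourceId, d[1], d[2], d[3],
              if (object@normalized) "normalized to [-1, 1]" else "raw pixels"))
})

setMethod("show", "Clip", function(object) {
  d <- dim(object@frames)
  cat(sprintf("Clip (%s stream): %d frames %dx%d, start frame %d\n",
              object@stream, d[1], d[2], d[3], object@startFrame))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: %d TP, %d FP, %d FN, %d ignored\n",
              nrow(object@tpPairs), nrow(object@fp), nrow(object@fn),
              nrow(object@ignored)))
})

#' Accessors for the core classes
#'
#' `frames()` returns the frame array of a [FrameSequence-class] or
#' [Clip-class]; `fps()` its frame rate; `sourceId()` its identifier;
#' `flowField()` the flow array of a [MotionMap-class];
#' `isNormalized()` whether a motion map has been truncated/scaled;
#' `nFrames()` the number of frames.
#'
#' @param object the object to access.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "FrameSequence", function(object) object@frames)
#' @rdname accessors
#' @export
setMethod("frames", "Clip", function(object) object@frames)

#' @rdname accessors
#' @export
setGeneric("fps", function(object) standardGeneric("fps"))
#' @rdname accessors
#' @export
setMethod("fps", "FrameSequence", function(object) object@fps)

#' @rdname accessors
#' @export
setGeneric("sourceId", function(object) standardGeneric("sourceId"))
#' @rdname accessors
#' @export
setMethod("sourceId", "FrameSequence", function(object) object@sourceId)
#' @rdname accessors
#' @export
setMethod("sourceId", "MotionMap", function(object) object@sourceId)

#' @rdname accessors
#' @export
setGeneric("flowField", function(object) standardGeneric("flowField"))
#' @rdname accessors
#' @export
setMethod("flowField", "MotionMap", function(object) object@flow)

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setMethod("isNormalized", "MotionMap", function(object) object@normalized)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "FrameSequence", function(object) dim(object@frames)[1])

#' @rdname accessors
#' @export
setGeneric("tpPairs", function(object) standardGeneric("tpPairs"))
#' @rdname accessors
#' @export
setMethod("tpPairs", "MatchResult", function(object) object@tpPairs)

#' Construct a FrameSequence
#'
#' @param frames `T x H x W x C` numeric array in `[0, 1]`, or a
#'   `T x H x W` array which is treated as single-channel.
#' @param fps frames per second.
#' @param sourceId identifier for the recording.
#' @return a [FrameSequence-class].
#' @examples
#' fs <- FrameSequence(array(0, c(4, 8, 8, 1)), fps = 15)
#' nFrames(fs)
#' @export
FrameSequence <- function(frames, fps = 15, sourceId = "unnamed") {
  if (length(dim(frames)) == 3L)
    dim(frames) <- c(dim(frames), 1L)
  new("FrameSequence", frames = frames, fps = as.numeric(fps),
      sourceId = sourceId)
}
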