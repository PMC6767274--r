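#' Default TV-L1 solver parameters
#'
#' The solver uses the widely adopted defaults of the duality-based
#' TV-L1 scheme: time step `tau = 0.25`, data attachment weight
#' `lambda = 0.15` (calibrated for a 0..255 intensity scale; frames are
#' rescaled internally), relaxation `theta = 0.3`, a 5-level pyramid
#' with downscale factor 0.5, 5 warps per level, stopping tolerance
#' `epsilon = 0.01` and at most `maxiter` fixed-point iterations per
#' warp (10 by default — 50 sweeps per pyramid level across the 5
#' warps, a standard practical operating point for this solver).
#'
#' @param tau,lambda,theta,nscales,zoom,warps,epsilon,maxiter solver
#'   parameters, see above.
#' @return a named list of parameters for [computeFlow()].
#' @export
tvl1Params <- function(tau = 0.25, lambda = 0.15, theta = 0.3,
                       nscales = 5L, zoom = 0.5, warps = 5L,
                       epsilon = 0.01, maxiter = 10L) {
  list(tau = tau, lambda = lambda, theta = theta, nscales = as.integer(nscales),
       zoom = zoom, warps = as.integer(warps), epsilon = epsilon,
       maxiter = as.integer(maxiter))
}

#' Dense TV-L1 optical flow between consecutive frames
#'
#' Computes a dense two-component displacement field (in pixels, at the
#' native frame resolution) for every consecutive frame pair of a
#' sequence, using total-variation regularized L1 optical flow.
#' 3-channel input is converted to grayscale by the standard luma
#' weighting first. The vertical (Y) component is positive for motion
#' DOWN the image, so a descending bolus produces positive Y flow.
#'
#' The result is deterministic given the solver parameters.
#'
#' @param seq a [FrameSequence-class] with at least 2 frames.
#' @param params solver parameters from [tvl1Params()].
#' @return an unnormalized [MotionMap-class] with one flow step per
#'   consecutive frame pair.
#' @seealso [normalizeFlow()] for the truncation/scaling applied before
#'   voting and the flow clip stream.
#' @export
computeFlow <- function(seq, params = tvl1Params()) {
  stopifnot(is(seq, "FrameSequence"))
  d <- dim(seq@frames)
  if (d[1] < 2L)
    stopf("optical flow needs at least 2 frames, got %d", d[1])
  fr <- seq@frames
  if (d[4] == 3L) fr <- toGray(fr)
  flow <- array(0, c(d[1] - 1L, d[2], d[3], 2L))
  for (t in seq_len(d[1] - 1L)) {
    I0 <- matrix(fr[t, , , 1], d[2], d[3])
    I1 <- matrix(fr[t + 1L, , , 1], d[2], d[3])
    uv <- .tvl1_flow_cpp(I0, I1, params$tau, params$lambda, params$theta,
                         params$nscales, params$zoom, params$warps,
                         params$epsilon, params$maxiter)
    flow[t, , , 1] <- uv$u   # X: horizontal, positive rightward
    flow[t, , , 2] <- uv$v   # Y: vertical, positive down the image
  }
  new("MotionMap", flow = flow, normalized = FALSE, sourceId = seq@sourceId)
}

#' Truncate and scale flow to [-1, 1]
#'
#' Each flow component `v` is replaced by `clamp(v, -10, 10) / 10`, so
#' a vertical displacement of 10 px/frame or more saturates at 1. This
#' is the scale on which the voting threshold `fth = 0.4` (i.e. 4
#' px/frame) and the flow clip stream operate. Applying it twice would
#' silently shrink values, so a normalized input is refused.
#'
#' @param m an unnormalized [MotionMap-class].
#' @param truncation truncation limit in pixels (default 10).
#' @return a normalized [MotionMap-class].
#' @examples
#' m <- new("MotionMap", flow = array(c(15, 0, -4, 2), c(1, 2, 2, 2)),
#'          normalized = FALSE, sourceId = "x")
#' range(flowField(normalizeFlow(m)))
#' @export
normalizeFlow <- function(m, truncation = 10) {
  stopifnot(is(m, "MotionMap"))
  if (m@normalized)
    stopf("MotionMap is already normalized; refusing to scale twice")
  f <- pmin(pmax(m@flow, -truncation), truncation) / truncation
  new("MotionMap", flow = f, normalized = TRUE, sourceId = m@sourceId)
}

#' Cache a MotionMap on disk
#'
#' Flow is by far the most expensive stage, so motion maps can be
#' cached keyed by their source id and reloaded instead of recomputed.
#'
#' @param m a [MotionMap-class].
#' @param dir cache directory.
#' @param sourceId id to load.
#' @return `saveMotionMap`: the file path, invisibly;
#'   `loadMotionMap`: the [MotionMap-class] or `NULL` if absent.
#' @export
saveMotionMap <- function(m, dir) {
  stopifnot(is(m, "MotionMap"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, paste0(m@sourceId, "_flow.rds"))
  saveRDS(m, p)
  invisible(p)
}

#' @rdname saveMotionMap
#' @export
loadMotionMap <- function(dir, sourceId) {
  p <- file.path(dir, paste0(sourceId, "_flow.rds"))
  if (!file.exists(p)) return(NULL)
  readRDS(p)
}
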