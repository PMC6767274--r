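#' Read an untrimmed video as a FrameSequence
#'
#' Reads a directory of lexically ordered PNG (or JPEG-named, if
#' decodable by EBImage) still frames and resamples it to `targetFps`
#' by uniform index subsampling: for an integer rate ratio `k` every
#' k-th frame is kept; otherwise the nearest source index is selected
#' for each target time point. Clinical fluoroscopy is recorded at 30
#' FPS and all processing here runs at 15 FPS, i.e. every second frame.
#'
#' Container formats (MP4/AVI) require an external decode step; export
#' the container to a PNG frame directory first (e.g. with ffmpeg) —
#' passing a container file raises an error saying so.
#'
#' @param path directory of numbered still frames.
#' @param targetFps desired frame rate; `sourceFps` if missing.
#' @param sourceFps frame rate of the stored frames (default 30).
#' @return a [FrameSequence-class] at `targetFps`.
#' @examples
#' d <- tempfile(); dir.create(d)
#' for (i in 1:6) png::writePNG(matrix(i / 6, 4, 4),
#'   file.path(d, sprintf("f%03d.png", i)))
#' fs <- readVideo(d, targetFps = 15, sourceFps = 30)
#' nFrames(fs)  # 3: every second frame kept
#' @export
readVideo <- function(path, targetFps = NULL, sourceFps = 30) {
  if (!file.exists(path))
    stopf("cannot read video input: '%s' does not exist", path)
  if (!dir.exists(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("mp4", "avi", "mov", "mkv"))
      stopf(paste0("'%s': container video formats are not decoded here; ",
                   "export the video to a directory of PNG frames first"),
            path)
    stopf("'%s' is not a frame directory", path)
  }
  files <- list.files(path, pattern = "\\.(png|PNG|jpg|jpeg|JPG)$",
                      full.names = TRUE)
  files <- sort(files)
  if (length(files) == 0L)
    stopf("no frames decoded from '%s'", path)
  imgs <- lapply(files, function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
    else EBImage::imageData(EBImage::readImage(f))
  })
  d1 <- dim(imgs[[1]])
  C <- if (length(d1) == 2L) 1L else d1[3]
  if (C == 4L) C <- 3L  # drop alpha
  T0 <- length(imgs)
  a <- array(0, c(T0, d1[1], d1[2], C))
  for (i in seq_len(T0)) {
    im <- imgs[[i]]
    if (length(dim(im)) == 2L) a[i, , , 1] <- im
    else a[i, , , ] <- im[, , seq_len(C)]
  }
  fs <- FrameSequence(a, fps = sourceFps, sourceId = basename(path))
  if (is.null(targetFps)) targetFps <- sourceFps
  resampleFrames(fs, targetFps)
}

#' Resample a FrameSequence to a target frame rate
#'
#' Uniform index subsampling: kept source indices are
#' `round(j * sourceFps / targetFps)` for `j = 0, 1, ...` (0-based),
#' which reduces to keeping every k-th frame when the rate ratio is an
#' integer k. Upsampling is refused — resampling never emits more
#' frames than the source has.
#'
#' @param seq a [FrameSequence-class].
#' @param targetFps target frame rate, `<= fps(seq)`.
#' @return a resampled [FrameSequence-class] with `fps = targetFps`.
#' @export
resampleFrames <- function(seq, targetFps) {
  stopifnot(is(seq, "FrameSequence"))
  if (targetFps <= 0) stopf("targetFps must be positive")
  if (targetFps > seq@fps + 1e-9)
    stopf("cannot upsample from %g to %g FPS", seq@fps, targetFps)
  if (abs(targetFps - seq@fps) < 1e-9) return(seq)
  T0 <- dim(seq@frames)[1]
  ratio <- seq@fps / targetFps
  # nearest source index for each target time point
  j <- 0:(T0 - 1L)
  src <- as.integer(round(j * ratio))
  src <- src[src <= T0 - 1L]
  src <- unique(src)
  new("FrameSequence", frames = seq@frames[src + 1L, , , , drop = FALSE],
      fps = as.numeric(targetFps), sourceId = seq@sourceId)
}

#' Write a FrameSequence as a lossless PNG frame directory
#'
#' Writing then re-reading at the same FPS reproduces pixel values
#' (up to 16-bit PNG quantization).
#'
#' @param seq a [FrameSequence-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFrames <- function(seq, dir) {
  stopifnot(is(seq, "FrameSequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(seq@frames)
  for (i in seq_len(d[1])) {
    fr <- seq@frames[i, , , ]
    if (d[4] == 1L) dim(fr) <- d[2:3]
    png::writePNG(pmin(pmax(fr, 0), 1),
                  file.path(dir, sprintf("frame_%06d.png", i - 1L)))
  }
  invisible(dir)
}

#' Extract a fixed 20-frame clip from a sequence or motion map
#'
#' Cuts frames `startFrame .. startFrame + 19` (0-based, inclusive) and
#' resizes each frame bilinearly to `size x size`. The `rgb` stream
#' replicates a single grayscale channel to 3 channels; the `flow`
#' stream requires a normalized [MotionMap-class] as `flow` and yields
#' the 2 flow components (values are already dimensionless after
#' normalization, so resizing does not rescale magnitudes).
#'
#' @param seq a [FrameSequence-class] (for `stream = "rgb"`).
#' @param startFrame 0-based start index; the window must fit:
#'   `startFrame + 20 <= T`.
#' @param stream `"rgb"` or `"flow"`.
#' @param size target spatial size (default 224, the network input).
#' @param flow a normalized [MotionMap-class], required for the flow
#'   stream. Flow step t pairs frames (t, t+1), so the window covers
#'   flow steps `startFrame .. startFrame + 19`.
#' @return a [Clip-class].
#' @export
extractClip <- function(seq, startFrame, stream = c("rgb", "flow"),
                        size = 224L, flow = NULL) {
  stream <- match.arg(stream)
  startFrame <- as.integer(startFrame)
  L <- 20L
  if (stream == "rgb") {
    stopifnot(is(seq, "FrameSequence"))
    T0 <- dim(seq@frames)[1]
    if (startFrame < 0L || startFrame + L > T0)
      stopf("clip window [%d, %d] exceeds sequence of %d frames",
            startFrame, startFrame + L - 1L, T0)
    d <- dim(seq@frames)
    out <- array(0, c(L, size, size, 3L))
    for (i in seq_len(L)) {
      fr <- seq@frames[startFrame + i, , , , drop = TRUE]
      if (d[4] == 3L) {
        for (ch in 1:3)
          out[i, , , ch] <- resizeMatrix(fr[, , ch], size, size)
      } else {
        g <- resizeMatrix(matrix(fr, d[2], d[3]), size, size)
        for (ch in 1:3) out[i, , , ch] <- g
      }
    }
  } else {
    if (is.null(flow)) stopf("flow stream requires a MotionMap")
    stopifnot(is(flow, "MotionMap"))
    if (!flow@normalized)
      stopf("flow stream clips must come from a normalized MotionMap")
    Tf <- dim(flow@flow)[1]
    if (startFrame < 0L || startFrame + L > Tf)
      stopf("clip window [%d, %d] exceeds %d flow steps",
            startFrame, startFrame + L - 1L, Tf)
    out <- array(0, c(L, size, size, 2L))
    for (i in seq_len(L))
      for (ch in 1:2)
        out[i, , , ch] <- resizeMatrix(flow@flow[startFrame + i, , , ch],
                                       size, size)
  }
  new("Clip", frames = out, startFrame = startFrame, stream = stream)
}

#' Read / write event interval tables
#'
#' The shared interval dialect used for candidates, detections and
#' ground truth: CSV with columns `video_id,start_frame,end_frame`
#' (plus `confidence` for detections), or an equivalent JSON
#' list-of-objects. Format is chosen by file extension.
#'
#' @param path file to read or write (`.csv` or `.json`).
#' @param intervals data.frame with at least
#'   `video_id,start_frame,end_frame`.
#' @return `readIntervals`: a data.frame; `writeIntervals`: `path`,
#'   invisibly.
#' @export
readIntervals <- function(path) {
  if (!file.exists(path)) stopf("interval file '%s' does not exist", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path, simplifyDataFrame = TRUE))
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("video_id", "start_frame", "end_frame")
  if (!all(need %in% names(df)))
    stopf("interval table must have columns %s", paste(need, collapse = ","))
  df$start_frame <- as.integer(df$start_frame)
  df$end_frame <- as.integer(df$end_frame)
  df
}

#' @rdname readIntervals
#' @export
writeIntervals <- function(intervals, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(intervals, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(intervals, path, row.names = FALSE)
  }
  invisible(path)
}
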