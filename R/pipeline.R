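#' Default pipeline configuration
#'
#' One structured configuration carries every stage default: the
#' candidate-stage thresholds (`fth = 0.4`, `vth = 2.5`, central
#' fraction 0.5, vote radius 4), the sliding-window detector
#' (window 20, stride 5, `scoreth = 0.5`, `frameth = 5`,
#' `lambda = 0.001`, smoothing width 5, review padding 10), the
#' evaluation protocol (IOU threshold 0.3, 15 FPS), the network
#' configuration and the training schedule.
#'
#' @return nested named list of defaults.
#' @export
defaultConfig <- function() {
  list(
    candidates = list(fth = 0.4, vth = 2.5, center_fraction = 0.5,
                      radius = 4L, max_candidates = 5L),
    detect = list(window = 20L, stride = 5L, scoreth = 0.5, frameth = 5L,
                  lambda = 0.001, smooth_width = 5L, pad = 10L),
    eval = list(iou_th = 0.3, fps = 15),
    network = list(variant = "proposed", stream = "rgb",
                   width_scale = 1, input_size = 224L),
    train = list(initial_lr = 0.1, batch_size = 6L,
                 total_iterations = 300L, warmup_iterations = 30L,
                 seed = 1L),
    flow = list(tau = 0.25, lambda = 0.15, theta = 0.3, nscales = 5L,
                zoom = 0.5, warps = 5L, epsilon = 0.01, maxiter = 10L),
    synth = list(n_videos = 5L, n_events = 2L, duration = 105L,
                 seed = 1L)
  )
}

#' Desk-scale study configuration
#'
#' The configuration used by the package's reference synthetic study:
#' identical to [defaultConfig()] except that the classifier runs at
#' reduced width (`width_scale = 0.25`) and input resolution
#' (48 x 48), which preserves the architecture's structure while
#' keeping a full train-and-detect run tractable on one CPU core.
#' Candidate generation, detection and evaluation parameters are
#' untouched.
#'
#' @return nested named list of configuration values.
#' @export
studyConfig <- function() {
  cfg <- defaultConfig()
  cfg$network$width_scale <- 0.25
  cfg$network$input_size <- 48L
  cfg
}

#' Read / write a pipeline configuration
#'
#' YAML round-trips: serialize -> parse -> serialize is byte-identical.
#'
#' @param path YAML file.
#' @param cfg configuration list.
#' @return `readConfig`: the configuration list; `writeConfig`:
#'   `path`, invisibly.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  yaml::read_yaml(path)
}

#' @rdname readConfig
#' @export
writeConfig <- function(cfg, path) {
  writeLines(yaml::as.yaml(cfg), path)
  invisible(path)
}

#' Label candidate clips against ground truth
#'
#' A candidate is labeled `"pharyngeal"` when its 20-frame span covers
#' at least `minCover` of some ground-truth event, `"other"`
#' otherwise — the labeling rule used to turn harvested candidates
#' into classifier training data.
#'
#' @param cand candidate data.frame (`start_frame`, `end_frame`).
#' @param gt ground-truth data.frame for the same video.
#' @param minCover minimum covered fraction of the event (default
#'   0.5).
#' @return `cand` with a `label` column.
#' @export
labelCandidates <- function(cand, gt, minCover = 0.5) {
  lab <- rep("other", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    for (j in seq_len(nrow(gt))) {
      ov <- min(cand$end_frame[i], gt$end_frame[j]) -
        max(cand$start_frame[i], gt$start_frame[j]) + 1L
      len <- gt$end_frame[j] - gt$start_frame[j] + 1L
      if (ov / len >= minCover) { lab[i] <- "pharyngeal"; break }
    }
  }
  cand$label <- lab
  cand
}

#' Fraction of events covered by at least one candidate
#'
#' @param cand candidate data.frame with `video_id`.
#' @param gt ground-truth data.frame with `video_id`.
#' @return fraction of ground-truth events overlapped (by at least
#'   one frame) by a candidate from the same video.
#' @export
candidateRecall <- function(cand, gt) {
  if (nrow(gt) == 0L) return(NaN)
  hit <- vapply(seq_len(nrow(gt)), function(j) {
    cv <- cand[cand$video_id == gt$video_id[j], , drop = FALSE]
    any(cv$start_frame <= gt$end_frame[j] & cv$end_frame >= gt$start_frame[j])
  }, logical(1))
  mean(hit)
}

#' Run the full cascade on synthetic data
#'
#' The package's reference end-to-end study: generates seeded
#' synthetic training and test videos, harvests candidate clips by
#' flow voting, labels them against the synthetic ground truth
#' (supplementing with sampled non-event windows so both classes are
#' populated), trains the clip classifier, detects events on the test
#' videos with the sliding window, and evaluates with the
#' temporal-IOU protocol. Also reports held-out clip accuracy on an
#' independently generated balanced clip set.
#'
#' @param seed master seed for the run.
#' @param nTrain,nTest numbers of training and test videos.
#' @param cfg configuration list ([defaultConfig()] layout).
#' @param verbose print per-stage progress.
#' @return list with `candidateRecall`, `clipAccuracy`, `metrics`
#'   (pooled [precisionRecallF1()] output), `timeErrorS`, `missRate`,
#'   `detections`, `groundTruth`, `candidates`, `lossTrace`, `model`.
#' @export
runSyntheticStudy <- function(seed = 1L, nTrain = 20L, nTest = 5L,
                              cfg = defaultConfig(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  fp <- do.call(tvl1Params, cfg$flow)
  netcfg <- networkConfig(cfg$network$variant, cfg$network$stream,
                          widthScale = cfg$network$width_scale,
                          inputSize = cfg$network$input_size)
  size <- netcfg$inputSize

  # --- training videos: harvest + label candidates -----------------
  say("generating %d training videos and harvesting candidates", nTrain)
  # 1-3 events per video, capped at what always fits the duration
  # (worst case: 20-frame events with 20-frame separations)
  maxE <- max(1L, (cfg$synth$duration - 2L + 21L) %/% 41L)
  trainClips <- list(); trainLabels <- character()
  candAll <- NULL; gtTrain <- NULL
  for (v in seq_len(nTrain)) {
    sp <- synthSpec(seed = seed * 1000L + v,
                    durationFrames = cfg$synth$duration,
                    nEvents = min(1L + (seed + v) %% 3L, maxE),
                    sourceId = sprintf("train_%d_%d", seed, v))
    g <- generateVideo(sp)
    h <- harvestTrainingClips(g$seq, fth = cfg$candidates$fth,
                              vth = cfg$candidates$vth,
                              radius = cfg$candidates$radius,
                              fraction = cfg$candidates$center_fraction,
                              maxCandidates = cfg$candidates$max_candidates,
                              streams = "rgb", size = size, flowParams = fp)
    cand <- labelCandidates(h$candidates, g$groundTruth)
    candAll <- rbind(candAll, cand)
    gtTrain <- rbind(gtTrain, g$groundTruth)
    for (i in seq_len(nrow(cand))) {
      trainClips[[length(trainClips) + 1L]] <- h$clips[[i]]$rgb
      trainLabels <- c(trainLabels, cand$label[i])
    }
    # non-event windows as additional negatives (distractors/background)
    for (s in sampleNegativeWindows(g$seq, g$groundTruth, 2L)) {
      trainClips[[length(trainClips) + 1L]] <-
        extractClip(g$seq, s, "rgb", size = size)
      trainLabels <- c(trainLabels, "other")
    }
  }
  rec <- candidateRecall(candAll, gtTrain)
  say("candidate recall on training events: %.3f (%d candidates)",
      rec, nrow(candAll))

  # --- train the classifier ----------------------------------------
  sched <- trainSchedule(totalIterations = cfg$train$total_iterations,
                         warmupIterations = cfg$train$warmup_iterations,
                         initialLR = cfg$train$initial_lr,
                         batchSize = cfg$train$batch_size,
                         seed = seed)
  net <- buildNetwork(netcfg, seed = seed)
  say("training %s/%s for %d iterations (%d clips)",
      netcfg$variant, netcfg$stream, sched$totalIterations,
      length(trainClips))
  tr <- trainNetwork(net, trainClips, trainLabels, sched)

  # --- held-out clip accuracy --------------------------------------
  nHold <- cfg$synth$holdout_per_class
  if (is.null(nHold)) nHold <- 20L
  held <- generateClipDataset(nHold, nHold, seed = seed + 500L, size = size)
  scores <- classifyClips(tr, lapply(held$clips, `[[`, "rgb"))
  acc <- mean((scores > 0.5) == (held$labels == "pharyngeal"))
  say("held-out clip accuracy: %.3f", acc)

  # --- detection on test videos ------------------------------------
  dets <- NULL; gtTest <- NULL
  for (v in seq_len(nTest)) {
    sp <- synthSpec(seed = seed * 1000L + 600L + v,
                    durationFrames = cfg$synth$duration,
                    nEvents = min(1L + (seed + v) %% 3L, maxE),
                    sourceId = sprintf("test_%d_%d", seed, v))
    g <- generateVideo(sp)
    d <- detectEvents(g$seq, tr, window = cfg$detect$window,
                      stride = cfg$detect$stride,
                      scoreth = cfg$detect$scoreth,
                      frameth = cfg$detect$frameth,
                      lam = cfg$detect$lambda,
                      smoothWidth = cfg$detect$smooth_width, size = size)
    dets <- rbind(dets, d)
    gtTest <- rbind(gtTest, g$groundTruth)
  }
  if (is.null(dets))
    dets <- data.frame(video_id = character(), start_frame = integer(),
                       end_frame = integer(), confidence = numeric())
  ev <- evaluateDetections(dets, gtTest, iouTh = cfg$eval$iou_th,
                           fps = cfg$eval$fps)
  say("detection: P=%.3f R=%.3f F1=%.3f",
      ev$metrics$precision, ev$metrics$recall, ev$metrics$f1)

  list(candidateRecall = rec, clipAccuracy = acc,
       metrics = ev$metrics, timeErrorS = ev$timeErrorS,
       missRate = ev$missRate, detections = dets, groundTruth = gtTest,
       candidates = candAll, lossTrace = tr$loss, model = tr)
}

#' Run the cascade end-to-end into a run directory
#'
#' Thin orchestration over [runSyntheticStudy()]: executes the study
#' under the resolved configuration and writes candidates, detections,
#' ground truth, a metrics JSON, the resolved configuration and a run
#' manifest (config hash and seeds) beside each other.
#'
#' @param cfg configuration list ([defaultConfig()] layout).
#' @param outDir output directory (created).
#' @param seed master seed.
#' @param nTrain,nTest study sizes.
#' @param verbose print per-stage progress.
#' @return the [runSyntheticStudy()] result, invisibly; files in
#'   `outDir`.
#' @export
runPipeline <- function(cfg = defaultConfig(), outDir, seed = 1L,
                        nTrain = 20L, nTest = 5L, verbose = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  res <- runSyntheticStudy(seed = seed, nTrain = nTrain, nTest = nTest,
                           cfg = cfg, verbose = verbose)
  writeIntervals(res$candidates, file.path(outDir, "candidates.csv"))
  writeIntervals(res$detections, file.path(outDir, "detections.csv"))
  writeIntervals(res$groundTruth, file.path(outDir, "ground_truth.csv"))
  writeConfig(cfg, file.path(outDir, "config.yaml"))
  metrics <- list(candidate_recall = res$candidateRecall,
                  clip_accuracy = res$clipAccuracy,
                  precision = res$metrics$precision,
                  recall = res$metrics$recall,
                  f1 = res$metrics$f1,
                  time_error_s = res$timeErrorS,
                  miss_rate = res$missRate$rate,
                  TP = res$metrics$TP, FP = res$metrics$FP,
                  FN = res$metrics$FN)
  jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = seed, n_train = nTrain, n_test = nTest,
                   config_sha = digestConfig(cfg),
                   elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(res)
}

#' Stable hash of a configuration
#'
#' @param cfg configuration list.
#' @return hex string identifying the resolved configuration.
#' @export
digestConfig <- function(cfg) {
  s <- yaml::as.yaml(cfg)
  # small polynomial rolling hash over the serialized config
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
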