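test_that("generation is deterministic and leaves the session RNG alone", {
  sp <- synthSpec(seed = 12, durationFrames = 70, nEvents = 2,
                  frameSize = c(64, 64))
  set.seed(1); before <- runif(1)
  g1 <- generateVideo(sp)
  g2 <- generateVideo(sp)
  expect_identical(frames(g1$seq), frames(g2$seq))
  expect_identical(g1$groundTruth, g2$groundTruth)
  set.seed(1)
  expect_identical(runif(1), before)  # caller RNG untouched
  # a different seed gives different pixels
  g3 <- generateVideo(synthSpec(seed = 13, durationFrames = 70,
                                nEvents = 2, frameSize = c(64, 64)))
  expect_false(identical(frames(g1$seq), frames(g3$seq)))
})

test_that("a distractor-free eventless video is static up to sensor noise", {
  sp <- synthSpec(seed = 3, durationFrames = 12, nEvents = 0,
                  frameSize = c(64, 64),
                  distractors = list(horizontalShift = 0, oscillation = 0,
                                     staticNoise = 0.01))
  g <- generateVideo(sp)
  fr <- frames(g$seq)
  dmax <- max(abs(fr[-1, , , ] - fr[-12, , , ]))
  expect_lt(dmax, 8 * 0.01)  # bounded by a few noise sigmas
  expect_equal(nrow(g$groundTruth), 0L)
})

test_that("ground truth intervals respect the drawn geometry", {
  for (sd in 1:6) {
    sp <- synthSpec(seed = sd, nEvents = 3L)
    g <- generateVideo(sp)
    gt <- g$groundTruth
    expect_equal(nrow(gt), 3L)
    len <- gt$end_frame - gt$start_frame + 1L
    expect_true(all(len >= 8L & len <= 20L))
    # pairwise separation of at least 20 frames
    gaps <- gt$start_frame[-1] - gt$end_frame[-3]
    expect_true(all(gaps > 20L))
    expect_true(all(gt$start_frame >= 0L &
                    gt$end_frame < sp$durationFrames))
    # each event path descends monotonically through the frame
    for (p in g$eventPaths) expect_true(all(diff(p) >= 0))
  }
  # impossible packing errors out rather than overlapping events
  expect_error(generateVideo(synthSpec(seed = 1, durationFrames = 30,
                                       nEvents = 3)), "cannot place")
})

test_that("a fast event drives normalized central Y flow past the vote threshold", {
  sp <- synthSpec(seed = 41, durationFrames = 36, nEvents = 1,
                  eventSpeedRange = c(5, 8),
                  distractors = list(horizontalShift = 0, oscillation = 0,
                                     staticNoise = 0.005))
  g <- generateVideo(sp)
  nm <- normalizeFlow(computeFlow(g$seq))
  fl <- flowField(nm)
  reg <- centerRegion(224, 224, 0.5)
  gt <- g$groundTruth
  steps <- (gt$start_frame:min(gt$end_frame, dim(fl)[1] - 1)) + 1L
  mx <- vapply(steps, function(t)
    max(abs(fl[t, (reg$row0:reg$row1) + 1L, (reg$col0:reg$col1) + 1L, 2])),
    numeric(1))
  expect_gte(mean(mx > 0.4), 0.5)  # at least half the event steps trigger
})

test_that("off-center events are invisible to central voting", {
  sp <- synthSpec(seed = 19, durationFrames = 50, nEvents = 1,
                  eventSpeedRange = c(5, 8), eventsOffCenter = TRUE,
                  distractors = list(horizontalShift = 0, oscillation = 0,
                                     staticNoise = 0.005))
  g <- generateVideo(sp)
  tal <- voteFrames(normalizeFlow(computeFlow(g$seq)))
  expect_equal(nrow(selectCandidates(tal, seqLen = nFrames(g$seq))), 0L)
})

test_that("clip datasets are balanced, labeled and reproducible", {
  ds <- generateClipDataset(4, 4, seed = 9, size = 24,
                            frameSize = c(64, 64))
  expect_length(ds$clips, 8L)
  expect_equal(table(ds$labels)[["pharyngeal"]], 4L)
  expect_equal(table(ds$labels)[["other"]], 4L)
  expect_equal(dim(frames(ds$clips[[1]]$rgb)), c(20L, 24L, 24L, 3L))
  ds2 <- generateClipDataset(4, 4, seed = 9, size = 24,
                             frameSize = c(64, 64))
  expect_identical(frames(ds$clips[[3]]$rgb), frames(ds2$clips[[3]]$rgb))
  expect_error(generateClipDataset(0, 4), "nPos")
})

test_that("negative window sampling stays clear of events", {
  g <- generateVideo(synthSpec(seed = 8, durationFrames = 105, nEvents = 2,
                               frameSize = c(64, 64)))
  st <- sampleNegativeWindows(g$seq, g$groundTruth, 5)
  for (s in st)
    for (j in seq_len(nrow(g$groundTruth)))
      expect_true(s + 19L < g$groundTruth$start_frame[j] - 10L ||
                  s > g$groundTruth$end_frame[j] + 10L)
})
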