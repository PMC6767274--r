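test_that("center region arithmetic follows the floor convention", {
  r <- centerRegion(224, 224, 0.5)
  expect_equal(unlist(r), c(row0 = 56, row1 = 167, col0 = 56, col1 = 167))
  full <- centerRegion(100, 60, 1)
  expect_equal(unlist(full), c(row0 = 0, row1 = 99, col0 = 0, col1 = 59))
  small <- centerRegion(10, 10, 0.5)
  expect_equal(unlist(small), c(row0 = 2, row1 = 6, col0 = 2, col1 = 6))
  expect_error(centerRegion(0, 10, 0.5), "positive")
  expect_error(centerRegion(10, 10, 0), "fraction")
})

# helper: a normalized MotionMap whose central max |Y| per step is given
tallyMap <- function(peaks) {
  nT <- length(peaks)
  fl <- array(0, c(nT, 20, 20, 2))
  for (t in seq_len(nT)) fl[t, 10, 10, 2] <- peaks[t]
  new("MotionMap", flow = fl, normalized = TRUE, sourceId = "t")
}

test_that("voting adds one vote on the frame and its eight neighbours", {
  expect_equal(voteFrames(tallyMap(rep(0, 30))), rep(0, 30))

  # single triggering step at t = 10 (0-based) -> votes on steps 6..14
  p <- rep(0, 30); p[11] <- 0.9
  v <- voteFrames(tallyMap(p))
  expect_equal(which(v == 1) - 1L, 6:14)
  expect_true(all(v[-(7:15)] == 0))

  # triggers at 10, 11, 12 -> plateau of 3 on 10..12, >= 2 on 8..14
  p3 <- rep(0, 30); p3[11:13] <- 0.9
  v3 <- voteFrames(tallyMap(p3))
  expect_equal(max(v3), 3)
  expect_true(all(v3[11:13] == 3))
  expect_true(all(v3[9:15] >= 2))

  # the threshold is strict and uses |Y|
  pneg <- rep(0, 30); pneg[5] <- -0.9; pneg[20] <- 0.4
  vneg <- voteFrames(tallyMap(pneg))
  expect_equal(sum(vneg > 0), 9)          # only the -0.9 step triggers
  expect_true(all(which(vneg == 1) %in% (1:9)))

  # edge clipping: trigger at the first step votes on steps 0..4 only
  pe <- rep(0, 30); pe[1] <- 0.9
  expect_equal(which(voteFrames(tallyMap(pe)) == 1) - 1L, 0:4)

  un <- new("MotionMap", flow = array(0, c(3, 4, 4, 2)),
            normalized = FALSE, sourceId = "u")
  expect_error(voteFrames(un), "normalized")
})

test_that("candidate selection honours vth, spans and the count cap", {
  expect_equal(nrow(selectCandidates(rep(0, 50), seqLen = 100)), 0L)

  # one plateau of 3 spanning steps 8..14 of a 100-frame video
  t1 <- rep(0, 99); t1[9:15] <- 3
  c1 <- selectCandidates(t1, seqLen = 100)
  expect_equal(nrow(c1), 1L)
  expect_true(c1$start_frame <= 8 && c1$end_frame >= 14)
  expect_equal(c1$end_frame - c1$start_frame + 1L, 20L)

  # unique tally peaks at steps 15 and 60 -> candidates [5,24], [50,69]
  t2 <- rep(0, 99); t2[16] <- 3; t2[61] <- 3
  t2[c(14, 15, 17, 18, 59, 60, 62, 63)] <- 2
  c2 <- selectCandidates(t2, seqLen = 100)
  expect_equal(nrow(c2), 2L)
  expect_equal(c2$start_frame, c(5L, 50L))
  expect_equal(c2$end_frame, c(24L, 69L))
  # with a wide plateau the earliest plateau step is the peak
  t2b <- rep(0, 99); t2b[12:20] <- 3
  c2b <- selectCandidates(t2b, seqLen = 100)
  expect_equal(c2b$peak_frame, 11L)

  # vth is strict: a tally of exactly 2.5 (or value 2 with default) fails
  t3 <- rep(0, 60); t3[10:14] <- 2.5
  expect_equal(nrow(selectCandidates(t3, seqLen = 60)), 0L)

  # boundary clamping keeps clips inside the sequence
  t4 <- rep(0, 39); t4[1:5] <- 4; t4[35:39] <- 4
  c4 <- selectCandidates(t4, seqLen = 40)
  expect_true(all(c4$start_frame >= 0 & c4$end_frame <= 39))
})

test_that("candidate selection matches the exhaustive reference", {
  set.seed(2024)
  for (rep in 1:200) {
    n <- sample(20:50, 1)
    tally <- sample(0:9, n, replace = TRUE)
    seqLen <- n + sample(0:10, 1)
    got <- selectCandidates(tally, seqLen = seqLen)
    want <- oracleSelectCandidates(tally, seqLen = seqLen)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start_frame, as.integer(want[, 1]))
      expect_equal(got$end_frame, as.integer(want[, 2]))
    }
    # invariants: at most five, and no accepted peak lies inside a
    # span accepted before it (acceptance order: tally desc, then
    # earlier peak)
    expect_lte(nrow(got), 5L)
    if (nrow(got) > 1) {
      ord <- order(-got$vote_score, got$peak_frame)
      for (a in seq_along(ord))
        for (b in seq_len(a - 1L)) {
          i <- ord[a]; j <- ord[b]
          expect_false(got$peak_frame[i] >= got$start_frame[j] &&
                       got$peak_frame[i] <= got$end_frame[j])
        }
    }
  }
})

test_that("harvesting finds a clean event and ignores horizontal motion", {
  # one clean downward event, no distractors
  g <- generateVideo(synthSpec(seed = 21, durationFrames = 60, nEvents = 1,
                               eventSpeedRange = c(5, 8), frameSize = c(112, 112),
                               distractors = list(horizontalShift = 0,
                                                  oscillation = 0,
                                                  staticNoise = 0.005)))
  h <- harvestTrainingClips(g$seq, streams = "rgb", size = 32)
  expect_equal(nrow(h$candidates), 1L)
  expect_true(h$candidates$start_frame <= g$groundTruth$end_frame &&
              h$candidates$end_frame >= g$groundTruth$start_frame)
  expect_equal(dim(frames(h$clips[[1]]$rgb)), c(20L, 32L, 32L, 3L))

  # a static video yields no candidates
  g0 <- generateVideo(synthSpec(seed = 22, durationFrames = 40, nEvents = 0,
                                frameSize = c(112, 112),
                                distractors = list(horizontalShift = 0,
                                                   oscillation = 0,
                                                   staticNoise = 0.005)))
  h0 <- harvestTrainingClips(g0$seq, streams = character())
  expect_equal(nrow(h0$candidates), 0L)

  # a large horizontal head shift contributes no votes on its own
  gh <- generateVideo(synthSpec(seed = 23, durationFrames = 60, nEvents = 0,
                                frameSize = c(112, 112),
                                distractors = list(horizontalShift = 6,
                                                   oscillation = 0,
                                                   staticNoise = 0.005)))
  hh <- harvestTrainingClips(gh$seq, streams = character())
  expect_equal(nrow(hh$candidates), 0L)
})
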