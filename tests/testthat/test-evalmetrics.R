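test_that("temporal IOU counts frames inclusively", {
  expect_equal(temporalIOU(c(10, 19), c(10, 19)), 1)
  expect_equal(temporalIOU(c(0, 9), c(20, 29)), 0)
  expect_equal(temporalIOU(c(0, 9), c(5, 14)), 5 / 15)
  expect_equal(temporalIOU(c(0, 9), c(9, 9)), 1 / 10)  # single shared frame
  # symmetry and bounds over random intervals
  set.seed(5)
  for (i in 1:50) {
    a <- sort(sample(0:50, 2)); b <- sort(sample(0:50, 2))
    v <- temporalIOU(a, b)
    expect_equal(v, temporalIOU(b, a))
    expect_gte(v, 0); expect_lte(v, 1)
    if (v == 1) expect_equal(a, b)
  }
})

test_that("greedy matching follows confidence and the ignored rule", {
  gt1 <- data.frame(start_frame = 10L, end_frame = 29L)
  d1 <- data.frame(start_frame = 10L, end_frame = 29L, confidence = 0.9)
  m1 <- matchDetections(d1, gt1)
  expect_equal(nrow(tpPairs(m1)), 1L)
  expect_equal(nrow(m1@fp), 0L)
  expect_equal(nrow(m1@fn), 0L)

  # two detections over one truth: the lower-confidence one is
  # ignored, not a false positive
  d2 <- data.frame(start_frame = c(10L, 12L), end_frame = c(29L, 31L),
                   confidence = c(0.9, 0.8))
  m2 <- matchDetections(d2, gt1)
  expect_equal(nrow(tpPairs(m2)), 1L)
  expect_equal(tpPairs(m2)$confidence, 0.9)
  expect_equal(nrow(m2@ignored), 1L)
  expect_equal(nrow(m2@fp), 0L)

  # three events, three overlapping detections -> 3 TPs; dropping one
  # detection leaves 2 TPs and 1 FN
  gt3 <- data.frame(start_frame = c(10L, 50L, 90L),
                    end_frame = c(25L, 65L, 105L))
  d3 <- data.frame(start_frame = c(12L, 48L, 92L),
                   end_frame = c(27L, 63L, 107L),
                   confidence = c(0.7, 0.95, 0.8))
  m3 <- matchDetections(d3, gt3)
  expect_equal(nrow(tpPairs(m3)), 3L)
  m3b <- matchDetections(d3[-2, ], gt3)
  expect_equal(nrow(tpPairs(m3b)), 2L)
  expect_equal(nrow(m3b@fn), 1L)

  # no overlap at all -> FP + FN
  d4 <- data.frame(start_frame = 200L, end_frame = 220L, confidence = 0.5)
  m4 <- matchDetections(d4, gt1)
  expect_equal(nrow(m4@fp), 1L)
  expect_equal(nrow(m4@fn), 1L)

  # mixed video ids are refused
  expect_error(matchDetections(
    data.frame(start_frame = 1L, end_frame = 5L, confidence = 1,
               video_id = "a"),
    data.frame(start_frame = 1L, end_frame = 5L, video_id = "b")),
    "one video")
})

test_that("matching agrees with the exhaustive reference on random instances", {
  set.seed(606)
  for (rep in 1:200) {
    inst <- randomMatchInstance()
    got <- matchDetections(inst$dets, inst$gts)
    want <- oracleMatchDetections(inst$dets, inst$gts)
    expect_equal(nrow(tpPairs(got)), want$tp)
    expect_equal(nrow(got@fp), want$fp)
    expect_equal(nrow(got@ignored), want$ignored)
    expect_equal(nrow(got@fn), want$fn)
    # conservation: every gt is TP or FN; every det is TP/FP/ignored
    expect_equal(nrow(tpPairs(got)) + nrow(got@fn), nrow(inst$gts))
    expect_equal(nrow(tpPairs(got)) + nrow(got@fp) + nrow(got@ignored),
                 nrow(inst$dets))
    # each ground truth claimed at most once
    if (nrow(tpPairs(got)) > 1)
      expect_false(any(duplicated(
        tpPairs(got)[, c("gt_start", "gt_end")])))
  }
})

test_that("precision/recall/F1 behave like a harmonic mean", {
  m <- precisionRecallF1(10, 0, 0)
  expect_equal(m$precision, 1); expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)
  set.seed(77)
  for (i in 1:50) {
    TP <- sample(1:100, 1); FP <- sample(0:100, 1); FN <- sample(0:100, 1)
    r <- precisionRecallF1(TP, FP, FN)
    expect_gte(r$f1, min(r$precision, r$recall) - 1e-12)
    expect_lte(r$f1, max(r$precision, r$recall) + 1e-12)
    expect_equal(r$f1, 2 * r$precision * r$recall /
                   (r$precision + r$recall))
  }
  expect_warning(u <- precisionRecallF1(0, 0, 5), "precision undefined")
  expect_true(is.nan(u$precision))
  expect_warning(precisionRecallF1(0, 5, 0), "recall undefined")
})

test_that("detection time error averages start/middle/end offsets", {
  tp <- data.frame(det_start = 10, det_end = 29, gt_start = 10, gt_end = 29)
  expect_equal(detectionTimeError(tp), 0)
  # uniform 3-frame shift: (3+3+3)/3/15 = 0.2 s
  tp2 <- data.frame(det_start = 10, det_end = 29, gt_start = 13, gt_end = 32)
  expect_equal(detectionTimeError(tp2), 0.2)
  # end-only error: middle shifts by half -> (0+3+6)/3/15 = 0.2 s
  tp3 <- data.frame(det_start = 10, det_end = 29, gt_start = 10, gt_end = 35)
  expect_equal(detectionTimeError(tp3), 0.2)
  # mean over pairs, and fps scaling
  both <- rbind(tp, tp2)
  expect_equal(detectionTimeError(both), 0.1)
  expect_equal(detectionTimeError(tp2, fps = 30), 0.1)
  expect_warning(e <- detectionTimeError(tp[0, ]), "undefined")
  expect_true(is.nan(e))
})

test_that("annotator merging averages endpoints with half-up rounding", {
  expect_equal(mergeAnnotations(c(10, 20), c(12, 24)), c(11L, 22L))
  expect_equal(mergeAnnotations(c(10, 20), c(10, 20)), c(10L, 20L))
  expect_equal(mergeAnnotations(c(10, 20), c(11, 21)), c(11L, 21L))
  a <- data.frame(video_id = "v", start_frame = 10L, end_frame = 20L)
  b <- data.frame(video_id = "v", start_frame = 13L, end_frame = 25L)
  m <- mergeAnnotations(a, b)
  expect_equal(m$start_frame, 12L)   # 11.5 rounds half-up
  expect_equal(m$end_frame, 23L)     # 22.5 rounds half-up
  b$video_id <- "w"
  expect_error(mergeAnnotations(a, b), "different videos")
})

test_that("miss rate counts videos without any matched occurrence", {
  hit <- matchDetections(
    data.frame(start_frame = 0L, end_frame = 19L, confidence = 1),
    data.frame(start_frame = 0L, end_frame = 19L))
  miss <- matchDetections(
    data.frame(start_frame = integer(), end_frame = integer(),
               confidence = numeric()),
    data.frame(start_frame = 0L, end_frame = 19L))
  expect_equal(missRate(list(hit, hit))$rate_pct, 0)
  r <- missRate(c(rep(list(hit), 7), list(miss)))
  expect_equal(r$rate_pct, 12.5)
  expect_equal(r$missed, 1L)
})

test_that("corpus evaluation pools counts across videos", {
  gts <- data.frame(video_id = c("a", "a", "b"),
                    start_frame = c(10L, 60L, 5L),
                    end_frame = c(25L, 75L, 20L))
  dets <- data.frame(video_id = c("a", "b", "b"),
                     start_frame = c(11L, 6L, 70L),
                     end_frame = c(26L, 21L, 90L),
                     confidence = c(0.9, 0.8, 0.7))
  ev <- evaluateDetections(dets, gts)
  expect_equal(ev$metrics$TP, 2)
  expect_equal(ev$metrics$FP, 1)
  expect_equal(ev$metrics$FN, 1)
  expect_equal(ev$missRate$missed, 0L)
  expect_gte(ev$timeErrorS, 0)
})
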