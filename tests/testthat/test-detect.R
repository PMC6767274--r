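test_that("window placement strides by 5 and clamps the last window", {
  net <- tinyNet("rgb")
  mk <- function(T) FrameSequence(array(runif(T * 24 * 24), c(T, 24, 24, 1)),
                                  fps = 15, sourceId = "w")
  set.seed(3)
  ws40 <- windowScores(mk(40), net, size = 16)
  expect_equal(ws40$window_start, c(0L, 5L, 10L, 15L, 20L))
  expect_true(all(ws40$score >= 0 & ws40$score <= 1))

  ws20 <- windowScores(mk(20), net, size = 16)
  expect_equal(ws20$window_start, 0L)

  # a non-multiple length gets a final clamped window
  ws23 <- windowScores(mk(23), net, size = 16)
  expect_equal(ws23$window_start, c(0L, 3L))

  expect_error(windowScores(mk(19), net, size = 16), "shorter")
})

test_that("frame scores average the covering windows", {
  ws <- data.frame(window_start = 0L, score = 0.8)
  expect_equal(frameScores(ws, 20), rep(0.8, 20))

  ws2 <- data.frame(window_start = c(0L, 5L), score = c(0.2, 0.6))
  fs2 <- frameScores(ws2, 25)
  expect_equal(fs2[1], 0.2)        # covered by window 0 only
  expect_equal(fs2[10], 0.4)       # covered by both
  expect_equal(fs2[25], 0.6)       # beyond window 0, inherits window 5
  # frames 21..24 (0-based 20..23) only in window 5
  expect_equal(fs2[21:24], rep(0.6, 4))

  # T=40, stride 5: frame 12 (0-based) is covered by windows 0, 5, 10
  set.seed(8)
  ws3 <- data.frame(window_start = seq(0L, 20L, by = 5L),
                    score = round(runif(5), 2))
  fs3 <- frameScores(ws3, 40)
  expect_equal(fs3[13], mean(ws3$score[1:3]))
})

test_that("smoothing is a centred moving average with edge replication", {
  expect_equal(smoothScores(rep(0.7, 10)), rep(0.7, 10))
  expect_equal(smoothScores(c(0, 0, 1, 0, 0), width = 3),
               c(0, 1 / 3, 1 / 3, 1 / 3, 0))
  x <- runif(20)
  expect_equal(smoothScores(x, width = 1), x)
  expect_error(smoothScores(x, width = 4), "odd")
})

test_that("interval extraction applies the strict run rules", {
  expect_equal(nrow(extractIntervals(rep(0.4, 50))), 0L)

  s <- rep(0.1, 50); s[11:30] <- 0.9
  d <- extractIntervals(s)
  expect_equal(d$start_frame, 10L)
  expect_equal(d$end_frame, 29L)
  expect_equal(d$confidence, 0.9 + 0.001 * 20)

  # a 4-frame run is rejected (4 <= frameth), a 6-frame run kept
  s2 <- rep(0, 30); s2[5:8] <- 0.9; s2[15:20] <- 0.9
  d2 <- extractIntervals(s2)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$start_frame, 14L)

  # exactly frameth frames is still rejected ("larger than")
  s3 <- rep(0, 30); s3[5:9] <- 0.9
  expect_equal(nrow(extractIntervals(s3)), 0L)

  # a run still open at the video end is closed at the last frame
  s4 <- rep(0, 30); s4[22:30] <- 0.8
  d4 <- extractIntervals(s4)
  expect_equal(d4$end_frame, 29L)

  # scores exactly at the threshold do not mark the frame
  s5 <- rep(0.5, 30)
  expect_equal(nrow(extractIntervals(s5)), 0L)
})

test_that("interval extraction matches a brute-force maximal-run scan", {
  set.seed(31)
  for (rep in 1:200) {
    T <- sample(10:200, 1)
    s <- round(runif(T), 2)
    th <- sample(c(0.3, 0.5, 0.7), 1)
    fth <- sample(2:6, 1)
    got <- extractIntervals(s, scoreth = th, frameth = fth)
    want <- oracleExtractIntervals(s, scoreth = th, frameth = fth)
    expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want)) {
      expect_equal(got$start_frame, as.integer(want[, 1]))
      expect_equal(got$end_frame, as.integer(want[, 2]))
      expect_equal(got$confidence, want[, 3])
    }
    # runs are maximal: the frames flanking each run are not above th
    for (k in seq_len(nrow(got))) {
      if (got$start_frame[k] > 0) expect_lte(s[got$start_frame[k]], th)
      if (got$end_frame[k] < T - 1) expect_lte(s[got$end_frame[k] + 2], th)
    }
  }
})

test_that("raising the threshold never detects more frames", {
  set.seed(17)
  s <- smoothScores(runif(150))
  prev <- Inf
  for (th in c(0.3, 0.45, 0.6, 0.75)) {
    d <- extractIntervals(s, scoreth = th, frameth = 0L)
    nframes <- sum(d$end_frame - d$start_frame + 1L)
    expect_lte(nframes, prev)
    prev <- nframes
  }
})

test_that("review padding extends and clamps without merging", {
  d <- data.frame(start_frame = c(50L, 5L), end_frame = c(70L, 20L),
                  confidence = c(0.9, 0.8))
  e <- extendIntervals(d, pad = 10, T = 200)
  expect_equal(e$start_frame, c(40L, 0L))
  expect_equal(e$end_frame, c(80L, 30L))
  expect_equal(e$confidence, d$confidence)
  expect_equal(extendIntervals(d, pad = 0, T = 200), d)
  # overlapping extended intervals stay separate rows
  d2 <- data.frame(start_frame = c(10L, 25L), end_frame = c(20L, 35L),
                   confidence = c(0.5, 0.6))
  expect_equal(nrow(extendIntervals(d2, pad = 10, T = 100)), 2L)
})
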