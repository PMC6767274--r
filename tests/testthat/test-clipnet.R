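test_that("cosine schedule ramps, peaks at warm-up end, and decays to 0", {
  s <- trainSchedule(totalIterations = 100, warmupIterations = 10,
                     initialLR = 0.1)
  expect_equal(cosineLR(10, s), 0.1)
  expect_equal(cosineLR(100, s), 0)
  expect_equal(cosineLR(55, s), 0.05)          # post-warmup midpoint
  expect_equal(cosineLR(0, s), 0)
  expect_equal(cosineLR(5, s), 0.05)           # linear ramp
  lrs <- vapply(0:100, cosineLR, numeric(1), sched = s)
  expect_true(all(lrs <= 0.1 + 1e-12))
  expect_true(all(diff(lrs[11:101]) <= 1e-12)) # monotone decay after warmup
  expect_error(trainSchedule(10, 10), "warmup")
})

test_that("parameter counting matches closed forms", {
  cu1 <- vfssdetect:::.newConvUnit(4L, 8L, c(1, 1, 1), c(1, 1, 1))
  # conv weights + bias: 4*8 + 8 = 40; batch-norm scale/shift add 2*8
  expect_equal(length(cu1$W) + length(cu1$b), 40L)
  cu3 <- vfssdetect:::.newConvUnit(2L, 4L, c(3, 3, 3), c(1, 1, 1))
  expect_equal(length(cu3$W) + length(cu3$b), 27 * 2 * 4 + 4)
  fake <- list(layers = list(cu1, cu3,
                             list(type = "linear", W = matrix(0, 8, 2),
                                  b = numeric(2))))
  expect_equal(countParameters(fake),
               (40 + 16) + (220 + 8) + 18)
})

test_that("module layout and capacity differ between the two variants", {
  cb <- networkConfig("baseline", "rgb")
  cp <- networkConfig("proposed", "rgb")
  expect_equal(cb$stageCounts, c(0L, 2L, 5L, 2L))
  expect_equal(cp$stageCounts, c(3L, 4L, 6L, 3L))
  ms <- inceptionModuleSpec(8, 4, 16, 4, 8, 8)
  expect_equal(ms$out, 8 + 16 + 8 + 8)

  # the proposed variant has strictly more modules and parameters
  # under ANY shared schedule, including reduced ones
  for (ws in c(0.1, 0.25)) {
    nb <- buildNetwork(networkConfig("baseline", "rgb", widthScale = ws,
                                     inputSize = 32), seed = 1)
    np <- buildNetwork(networkConfig("proposed", "rgb", widthScale = ws,
                                     inputSize = 32), seed = 1)
    expect_gt(countParameters(np), countParameters(nb))
  }
})

test_that("stream choice fixes the input channel count", {
  nf <- tinyNet("flow")
  expect_equal(nf$layers[[1]]$Cin, 2L)
  nr <- tinyNet("rgb")
  expect_equal(nr$layers[[1]]$Cin, 3L)
  # shape mismatches are refused with the expected geometry named
  expect_error(classifyClip(nf, tinyClip(1, C = 3L)), "does not match")
  expect_error(classifyClip(nr, tinyClip(1, inputSize = 12L)),
               "does not match")
})

test_that("classifier outputs are probabilities and deterministic", {
  net <- tinyNet("rgb")
  cl <- tinyClip(5)
  p1 <- classifyClip(net, cl)
  p2 <- classifyClip(net, cl)
  expect_identical(p1, p2)
  expect_gte(p1, 0); expect_lte(p1, 1)
  ps <- classifyClips(net, list(cl, tinyClip(6), tinyClip(7)), batchSize = 2)
  expect_true(all(ps >= 0 & ps <= 1))
  expect_equal(ps[1], p1, tolerance = 1e-9)
})

test_that("training reduces the loss and is reproducible from its seed", {
  set.seed(99)
  clips <- c(lapply(1:8, function(i) {
    a <- tinyClip(i) * 0.2
    a[8:14, 4:12, 6:10, ] <- a[8:14, 4:12, 6:10, ] + 0.7  # bright blob
    a
  }), lapply(9:16, function(i) tinyClip(i) * 0.2))
  labels <- rep(c("pharyngeal", "other"), each = 8)
  sched <- trainSchedule(totalIterations = 30, warmupIterations = 5,
                         seed = 7)
  net <- tinyNet("rgb")
  tr1 <- trainNetwork(net, clips, labels, sched)
  expect_length(tr1$loss, 30)
  expect_lt(mean(tail(tr1$loss, 5)), mean(head(tr1$loss, 5)))
  tr2 <- trainNetwork(net, clips, labels, sched)
  expect_identical(tr1$loss, tr2$loss)

  expect_error(trainNetwork(net, clips[1:8], labels[1:8], sched),
               "one class")
})

test_that("backpropagated gradients agree with finite differences", {
  cfg <- networkConfig("proposed", "rgb", widthScale = 0.02, inputSize = 12)
  net <- buildNetwork(cfg, seed = 3)
  set.seed(9)
  clips <- lapply(1:2, function(i) tinyClip(i, inputSize = 12L))
  y <- c(2L, 1L)
  stk <- vfssdetect:::.stackClips
  fw <- vfssdetect:::.forwardNet
  bw <- vfssdetect:::.backwardNet
  sm <- vfssdetect:::.softmax
  lossAt <- function(n) {
    st <- stk(clips)
    f <- fw(n, st$x, st$dims, training = TRUE)
    p <- sm(f$logits)
    -mean(log(p[cbind(y, 1:2)]))
  }
  st <- stk(clips)
  f <- fw(net, st$x, st$dims, training = TRUE)
  p <- sm(f$logits)
  dlog <- p; dlog[cbind(y, 1:2)] <- dlog[cbind(y, 1:2)] - 1
  dlog <- dlog / 2
  g <- bw(f$net, f$caches, dlog)
  eps <- 1e-5
  cases <- list(list(1L, "W", 5L), list(1L, "beta", 1L),
                list(3L, c("b3b", "W"), 7L), list(3L, c("pp", "gamma"), 2L))
  for (cs in cases) {
    li <- cs[[1]]; path <- cs[[2]]; idx <- cs[[3]]
    gv <- g[[li]]; for (pn in path) gv <- gv[[pn]]
    gv <- gv[idx]
    bump <- function(delta) {
      n2 <- net
      if (length(path) == 1) n2$layers[[li]][[path]][idx] <-
          n2$layers[[li]][[path]][idx] + delta
      else n2$layers[[li]][[path[1]]][[path[2]]][idx] <-
          n2$layers[[li]][[path[1]]][[path[2]]][idx] + delta
      lossAt(n2)
    }
    num <- (bump(eps) - bump(-eps)) / (2 * eps)
    expect_equal(gv, num, tolerance = 5e-2)
  }
})

test_that("checkpoints round-trip with their JSON sidecar", {
  net <- tinyNet("rgb")
  p <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(net, p)
  side <- jsonlite::fromJSON(paste0(tools::file_path_sans_ext(p), ".json"))
  expect_equal(side$nParameters, countParameters(net))
  back <- loadCheckpoint(p)
  expect_equal(classifyClip(back, tinyClip(3)), classifyClip(net, tinyClip(3)))
})
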