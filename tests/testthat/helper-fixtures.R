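# Shared fixture builders: everything is generated in code at test
# time; no stored binary data.

# two textured frames with a bright square translated by (dy, dx) px
squarePair <- function(dy, dx, H = 64L, W = 64L) {
  bg <- matrix(0.2, H, W) +
    0.05 * outer(sin(seq_len(H) / 5), cos(seq_len(W) / 7))
  f0 <- bg; f0[20:35, 25:40] <- 0.9
  f1 <- bg; f1[(20 + dy):(35 + dy), (25 + dx):(40 + dx)] <- 0.9
  a <- array(0, c(2L, H, W, 1L))
  a[1, , , 1] <- f0; a[2, , , 1] <- f1
  FrameSequence(a, fps = 15, sourceId = "squarepair")
}

# constant-gradient frame stack for index bookkeeping tests: frame i
# has constant value i / T
rampSequence <- function(T, H = 16L, W = 16L, fps = 30) {
  a <- array(rep(seq_len(T) / T, each = 1), c(T, H, W, 1L))
  for (i in seq_len(T)) a[i, , , 1] <- i / T
  FrameSequence(a, fps = fps, sourceId = "ramp")
}

# a tiny trainable network for plumbing tests
tinyNet <- function(stream = "rgb", inputSize = 16L, seed = 1L) {
  buildNetwork(networkConfig("proposed", stream, widthScale = 0.02,
                             inputSize = inputSize), seed = seed)
}

tinyClip <- function(seed, inputSize = 16L, C = 3L) {
  set.seed(seed)
  array(runif(20 * inputSize * inputSize * C),
        c(20L, inputSize, inputSize, C))
}
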