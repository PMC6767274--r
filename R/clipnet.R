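#' Network configuration for the 3D clip classifier
#'
#' Two architecture variants are available. The `baseline` is the
#' inflated Inception-V1 layout: a plain second stage (1x1x1 conv then
#' 3x3x3 conv) followed by 2, 5 and 2 inception modules in the later
#' stages. The `proposed` variant replaces the plain second stage with
#' inception modules and deepens every stage to a 3, 4, 6, 3 module
#' layout (the block pattern popularized by 50-layer residual
#' networks), concentrating extra capacity early where the small, fast
#' bolus motion is still spatially resolved.
#'
#' Channel widths are generated from a per-stage schedule with fixed
#' Inception-style branch proportions, scaled by `widthScale`;
#' `widthScale = 1` puts the proposed variant near 1.4 M parameters.
#' `inputSize` is the square spatial input resolution; the canonical
#' setting is 224 (20 x 224 x 224 clips), and reduced sizes support
#' desk-scale experiments.
#'
#' @param variant `"baseline"` or `"proposed"`.
#' @param stream `"rgb"` (3 input channels) or `"flow"` (2).
#' @param widthScale multiplier on all channel widths.
#' @param inputSize square spatial input size (default 224).
#' @param numClasses number of output classes (default 2).
#' @return a `NetworkConfig` list.
#' @export
networkConfig <- function(variant = c("proposed", "baseline"),
                          stream = c("rgb", "flow"),
                          widthScale = 1, inputSize = 224L,
                          numClasses = 2L) {
  variant <- match.arg(variant)
  stream <- match.arg(stream)
  structure(list(variant = variant, stream = stream,
                 widthScale = widthScale, inputSize = as.integer(inputSize),
                 numClasses = as.integer(numClasses),
                 stageCounts = if (variant == "proposed") c(3L, 4L, 6L, 3L)
                               else c(0L, 2L, 5L, 2L)),
            class = "NetworkConfig")
}

#' Inception module branch widths
#'
#' An inception module concatenates four branches: a 1x1x1 conv, two
#' 1x1x1 -> 3x3x3 stacks, and a 3x3x3 maxpool -> 1x1x1 conv. The
#' module output width is the sum of the four branch output widths.
#'
#' @param b1 1x1x1 branch output width.
#' @param b3r,b3 bottleneck and output width of the first 3x3x3 branch.
#' @param b5r,b5 bottleneck and output width of the second 3x3x3
#'   branch.
#' @param pp output width of the pool-projection branch.
#' @return a list with the widths and `out`, the module output width.
#' @export
inceptionModuleSpec <- function(b1, b3r, b3, b5r, b5, pp) {
  list(b1 = b1, b3r = b3r, b3 = b3, b5r = b5r, b5 = b5, pp = pp,
       out = b1 + b3 + b5 + pp)
}

# round to a positive multiple of 4
.r4 <- function(x) max(4L, as.integer(round(x / 4)) * 4L)

# Per-stage exit widths and branch proportions; module output widths
# are interpolated from the stage entry width to the stage exit.
.moduleSpecFromOut <- function(out) {
  inceptionModuleSpec(b1 = .r4(0.25 * out), b3r = .r4(0.2 * out),
                      b3 = .r4(0.4 * out), b5r = .r4(max(4, 0.2 * out / 3)),
                      b5 = .r4(0.2 * out), pp = .r4(0.15 * out))
}

#' Default channel schedule
#'
#' Stage exit widths (conv1 32, then 96 / 144 / 208 / 256, times
#' `widthScale`); module output widths interpolate linearly across each
#' stage. Both variants share the schedule, so their parameter counts
#' are directly comparable.
#'
#' @param cfg a [networkConfig()].
#' @return list with `conv1Width` and per-stage lists of
#'   [inceptionModuleSpec()]s (`NULL` second stage for the baseline,
#'   which uses a plain conv pair with `conv2Width`).
#' @export
channelSchedule <- function(cfg) {
  ws <- cfg$widthScale
  conv1 <- .r4(32 * ws)
  exits <- round(c(96, 144, 208, 256) * ws)
  counts <- cfg$stageCounts
  entry <- conv1
  stages <- vector("list", 4L)
  for (s in 1:4) {
    n <- counts[s]
    if (n == 0L) {  # baseline plain second stage
      stages[[s]] <- list(plain = TRUE, conv2a = .r4(entry),
                          conv2b = .r4(exits[s]))
      entry <- .r4(exits[s])
    } else {
      outs <- entry + (exits[s] - entry) * seq_len(n) / n
      mods <- lapply(outs, .moduleSpecFromOut)
      stages[[s]] <- list(plain = FALSE, modules = mods)
      entry <- mods[[n]]$out
    }
  }
  list(conv1Width = conv1, stages = stages, finalWidth = entry)
}

# ---- parameter containers ---------------------------------------------

.newConvUnit <- function(Cin, Cout, k, s) {
  K <- Cin * prod(k)
  list(type = "convunit", Cin = Cin, Cout = Cout,
       k = as.integer(k), s = as.integer(s),
       W = matrix(0, K, Cout), b = numeric(Cout),
       gamma = rep(1, Cout), beta = numeric(Cout),
       rmean = numeric(Cout), rvar = rep(1, Cout))
}

.newInception <- function(Cin, ms) {
  list(type = "inception", out = ms$out,
       b1  = .newConvUnit(Cin, ms$b1, c(1, 1, 1), c(1, 1, 1)),
       b3a = .newConvUnit(Cin, ms$b3r, c(1, 1, 1), c(1, 1, 1)),
       b3b = .newConvUnit(ms$b3r, ms$b3, c(3, 3, 3), c(1, 1, 1)),
       b5a = .newConvUnit(Cin, ms$b5r, c(1, 1, 1), c(1, 1, 1)),
       b5b = .newConvUnit(ms$b5r, ms$b5, c(3, 3, 3), c(1, 1, 1)),
       pp  = .newConvUnit(Cin, ms$pp, c(1, 1, 1), c(1, 1, 1)))
}

#' Build a 3D convolutional clip classifier
#'
#' Constructs the full layer sequence: conv1 7x7x7 stride (2,2,2) ->
#' maxpool 1x3x3 stride (1,2,2) -> stage 2 (plain conv pair for the
#' baseline, inception modules for the proposed variant) -> maxpool
#' 1x3x3 stride (1,2,2) -> stage 3 -> maxpool 3x3x3 stride (2,2,2) ->
#' stage 4 -> maxpool 3x3x3 stride (2,2,2) -> stage 5 -> average pool
#' over the remaining 2x7x7 extent -> linear projection ->
#' softmax. Every conv is followed by batch normalization and ReLU.
#' Convolutions and pools use "same"-style padding so only strides
#' change extents; the final 3x3x3 max pool runs unpadded along time
#' (5 -> 2 for a 20-frame clip), which is what produces the 2x7x7
#' pre-avgpool extent the closing pool is sized for. The avgpool
#' stride ((2,2,2) baseline, (1,1,1) proposed) has no effect at that
#' extent, where the pool covers the whole feature map.
#'
#' Weights are He-initialized from `seed` (training re-initializes
#' from the schedule's own seed).
#'
#' @param cfg a [networkConfig()].
#' @param seed RNG seed for the initial weights.
#' @return a network object (list) for [trainNetwork()],
#'   [classifyClip()] and [countParameters()].
#' @export
buildNetwork <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "NetworkConfig"))
  sch <- channelSchedule(cfg)
  Cin <- if (cfg$stream == "rgb") 3L else 2L
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l

  # kernel/stride vectors are (h, w, t); the printed 1x3x3 stride
  # (1,2,2) pools are therefore c(3,3,1) / c(2,2,1) here
  add(.newConvUnit(Cin, sch$conv1Width, c(7, 7, 7), c(2, 2, 2)))
  add(list(type = "maxpool", k = c(3L, 3L, 1L), s = c(2L, 2L, 1L),
           valid_t = FALSE))
  entry <- sch$conv1Width
  for (s in 1:4) {
    st <- sch$stages[[s]]
    if (isTRUE(st$plain)) {
      add(.newConvUnit(entry, st$conv2a, c(1, 1, 1), c(1, 1, 1)))
      add(.newConvUnit(st$conv2a, st$conv2b, c(3, 3, 3), c(1, 1, 1)))
      entry <- st$conv2b
    } else {
      for (m in st$modules) {
        add(.newInception(entry, m))
        entry <- m$out
      }
    }
    if (s < 4) {
      pk <- if (s == 1) c(3L, 3L, 1L) else c(3L, 3L, 3L)
      ps <- if (s == 1) c(2L, 2L, 1L) else c(2L, 2L, 2L)
      add(list(type = "maxpool", k = pk, s = ps, valid_t = (s == 3)))
    }
  }
  add(list(type = "gap"))
  add(list(type = "linear", W = matrix(0, entry, cfg$numClasses),
           b = numeric(cfg$numClasses)))

  net <- list(cfg = cfg, layers = layers, finalWidth = entry)
  initNetwork(net, seed)
}

#' Re-initialize all trainable parameters
#'
#' He-normal initialization for conv and linear weights, zero biases,
#' unit batch-norm scale, reset running statistics. Deterministic
#' given `seed`; the caller's RNG state is untouched.
#'
#' @param net a network from [buildNetwork()].
#' @param seed RNG seed.
#' @return the re-initialized network.
#' @export
initNetwork <- function(net, seed) {
  initCU <- function(cu) {
    fanIn <- nrow(cu$W)
    cu$W <- matrix(rnorm(length(cu$W), 0, sqrt(2 / fanIn)),
                   nrow(cu$W), ncol(cu$W))
    cu$b <- numeric(cu$Cout)
    cu$gamma <- rep(1, cu$Cout); cu$beta <- numeric(cu$Cout)
    cu$rmean <- numeric(cu$Cout); cu$rvar <- rep(1, cu$Cout)
    cu
  }
  withSeed(seed, {
    net$layers <- lapply(net$layers, function(l) {
      switch(l$type,
        convunit = initCU(l),
        inception = {
          for (b in c("b1", "b3a", "b3b", "b5a", "b5b", "pp"))
            l[[b]] <- initCU(l[[b]])
          l
        },
        linear = {
          l$W <- matrix(rnorm(length(l$W), 0, sqrt(2 / nrow(l$W))),
                        nrow(l$W), ncol(l$W))
          l$b <- numeric(ncol(l$W))
          l
        },
        l)
    })
    net
  })
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars: conv/linear weights and biases
#' plus batch-norm scale and shift. Running statistics are not
#' trainable and are not counted.
#'
#' @param net a network from [buildNetwork()].
#' @return integer parameter count.
#' @examples
#' \donttest{
#' base <- buildNetwork(networkConfig("baseline", "rgb"))
#' prop <- buildNetwork(networkConfig("proposed", "rgb"))
#' countParameters(prop) / countParameters(base)
#' }
#' @export
countParameters <- function(net) {
  cnt <- function(l) {
    switch(l$type,
      convunit = length(l$W) + length(l$b) + length(l$gamma) + length(l$beta),
      inception = sum(vapply(c("b1", "b3a", "b3b", "b5a", "b5b", "pp"),
                             function(b) cnt(l[[b]]), numeric(1))),
      linear = length(l$W) + length(l$b),
      0)
  }
  sum(vapply(net$layers, cnt, numeric(1)))
}

# ---- forward / backward ------------------------------------------------

.cuForward <- function(cu, x, xdim, training) {
  cf <- .conv3d_forward_cpp(x, xdim, cu$W, cu$b, cu$k, cu$s)
  bn <- .bn_forward_cpp(cf$y, cu$Cout, cu$gamma, cu$beta,
                        cu$rmean, cu$rvar, training, 1e-5)
  y <- pmax(bn$y, 0)
  list(y = y, ydim = cf$dims,
       cache = if (training) list(x = x, xdim = xdim, z = cf$y,
                                  mean = bn$mean, var = bn$var, y = y)
               else NULL,
       stats = if (training) list(mean = bn$mean, var = bn$var) else NULL)
}

.cuBackward <- function(cu, cache, dy) {
  dy <- dy * (cache$y > 0)
  bnb <- .bn_backward_cpp(dy, cache$z, cu$Cout, cu$gamma,
                          cache$mean, cache$var, 1e-5)
  cb <- .conv3d_backward_cpp(bnb$dx, cache$x, cache$xdim, cu$W, cu$k, cu$s)
  list(dx = cb$dx,
       grads = list(W = cb$dW, b = cb$db,
                    gamma = bnb$dgamma, beta = bnb$dbeta))
}

.updateRunning <- function(cu, stats, momentum = 0.1) {
  cu$rmean <- (1 - momentum) * cu$rmean + momentum * stats$mean
  cu$rvar <- (1 - momentum) * cu$rvar + momentum * stats$var
  cu
}

# concat along the channel axis (layout C,H,W,T,N)
.concatChannels <- function(parts, dims) {
  Cs <- vapply(dims, `[`, integer(1), 1L)
  rest <- dims[[1]][2:5]
  Ctot <- sum(Cs)
  out <- array(0, c(Ctot, rest))
  off <- 0L
  for (i in seq_along(parts)) {
    a <- parts[[i]]; dim(a) <- dims[[i]]
    out[(off + 1L):(off + Cs[i]), , , , ] <- a
    off <- off + Cs[i]
  }
  list(y = as.numeric(out), dims = c(Ctot, rest))
}

.splitChannels <- function(dy, dims, Cs) {
  dim(dy) <- dims
  out <- vector("list", length(Cs))
  off <- 0L
  for (i in seq_along(Cs)) {
    p <- dy[(off + 1L):(off + Cs[i]), , , , , drop = FALSE]
    out[[i]] <- as.numeric(p)
    off <- off + Cs[i]
  }
  out
}

.incForward <- function(l, x, xdim, training) {
  f1 <- .cuForward(l$b1, x, xdim, training)
  f3a <- .cuForward(l$b3a, x, xdim, training)
  f3b <- .cuForward(l$b3b, f3a$y, f3a$ydim, training)
  f5a <- .cuForward(l$b5a, x, xdim, training)
  f5b <- .cuForward(l$b5b, f5a$y, f5a$ydim, training)
  mp <- .maxpool3d_forward_cpp(x, xdim, c(3L, 3L, 3L), c(1L, 1L, 1L), FALSE)
  fpp <- .cuForward(l$pp, mp$y, mp$dims, training)
  cc <- .concatChannels(list(f1$y, f3b$y, f5b$y, fpp$y),
                        list(f1$ydim, f3b$ydim, f5b$ydim, fpp$ydim))
  list(y = cc$y, ydim = cc$dims,
       cache = if (training) list(f1 = f1, f3a = f3a, f3b = f3b, f5a = f5a,
                                  f5b = f5b, fpp = fpp, mp = mp,
                                  xdim = xdim, ydim = cc$dims)
               else NULL)
}

.incBackward <- function(l, cache, dy) {
  Cs <- c(l$b1$Cout, l$b3b$Cout, l$b5b$Cout, l$pp$Cout)
  parts <- .splitChannels(dy, cache$ydim, Cs)
  g1 <- .cuBackward(l$b1, cache$f1$cache, parts[[1]])
  g3b <- .cuBackward(l$b3b, cache$f3b$cache, parts[[2]])
  g3a <- .cuBackward(l$b3a, cache$f3a$cache, g3b$dx)
  g5b <- .cuBackward(l$b5b, cache$f5b$cache, parts[[3]])
  g5a <- .cuBackward(l$b5a, cache$f5a$cache, g5b$dx)
  gpp <- .cuBackward(l$pp, cache$fpp$cache, parts[[4]])
  dxp <- .maxpool3d_backward_cpp(gpp$dx, cache$mp$arg,
                                 prod(cache$xdim))
  dx <- g1$dx + g3a$dx + g5a$dx + dxp
  list(dx = dx,
       grads = list(b1 = g1$grads, b3a = g3a$grads, b3b = g3b$grads,
                    b5a = g5a$grads, b5b = g5b$grads, pp = gpp$grads))
}

# forward through the whole network; x is a flat vector with dims
# (C,H,W,T,N)
.forwardNet <- function(net, x, xdim, training = FALSE) {
  caches <- if (training) vector("list", length(net$layers)) else NULL
  preGapDim <- NULL
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "convunit") {
      f <- .cuForward(l, x, xdim, training)
      x <- f$y; newdim <- f$ydim
      if (training) {
        caches[[i]] <- f$cache
        net$layers[[i]] <- .updateRunning(l, f$stats)
      }
      xdim <- newdim
    } else if (l$type == "inception") {
      f <- .incForward(l, x, xdim, training)
      if (training) {
        caches[[i]] <- f$cache
        for (b in c("b1", "b3a", "b3b", "b5a", "b5b", "pp"))
          net$layers[[i]][[b]] <-
            .updateRunning(net$layers[[i]][[b]], f$cache[[
              c(b1 = "f1", b3a = "f3a", b3b = "f3b", b5a = "f5a",
                b5b = "f5b", pp = "fpp")[[b]]]]$stats)
      }
      x <- f$y; xdim <- f$ydim
    } else if (l$type == "maxpool") {
      f <- .maxpool3d_forward_cpp(x, xdim, l$k, l$s, l$valid_t)
      if (training) caches[[i]] <- list(arg = f$arg, xlen = prod(xdim))
      x <- f$y; xdim <- f$dims
    } else if (l$type == "gap") {
      preGapDim <- xdim
      C <- xdim[1]; HWT <- prod(xdim[2:4]); N <- xdim[5]
      m <- matrix(x, nrow = C)
      y <- matrix(0, C, N)
      for (n in seq_len(N))
        y[, n] <- rowMeans(m[, ((n - 1) * HWT + 1):(n * HWT), drop = FALSE])
      if (training) caches[[i]] <- list(xdim = xdim)
      x <- y; xdim <- c(C, N)
    } else if (l$type == "linear") {
      if (training) caches[[i]] <- list(x = x)
      x <- crossprod(l$W, x) + l$b   # numClasses x N
      xdim <- dim(x)
    }
  }
  list(logits = x, caches = caches, net = net, preGapDim = preGapDim)
}

#' Measured feature extent entering the closing average pool
#'
#' Runs a real forward pass on a zero clip and reports the feature-map
#' extent (time x height x width) that reaches the average pool. At
#' the nominal 20 x 224 x 224 input this is 2 x 7 x 7 — the extent the
#' closing pool is sized for.
#'
#' @param net a network from [buildNetwork()].
#' @return integer vector `c(T, H, W)` of the pre-avgpool extent.
#' @export
preAvgpoolExtent <- function(net) {
  if (!is.null(net$net)) net <- net$net
  C <- if (net$cfg$stream == "rgb") 3L else 2L
  s <- net$cfg$inputSize
  x <- numeric(C * s * s * 20L)
  fw <- .forwardNet(net, x, c(C, s, s, 20L, 1L), training = FALSE)
  d <- fw$preGapDim
  c(d[4], d[2], d[3])
}

.backwardNet <- function(net, caches, dlogits) {
  grads <- vector("list", length(net$layers))
  dy <- dlogits
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    if (l$type == "linear") {
      x <- caches[[i]]$x
      grads[[i]] <- list(W = x %*% t(dy), b = rowSums(dy))
      dy <- l$W %*% dy
    } else if (l$type == "gap") {
      xdim <- caches[[i]]$xdim
      C <- xdim[1]; HWT <- prod(xdim[2:4]); N <- xdim[5]
      dx <- matrix(0, C, HWT * N)
      for (n in seq_len(N))
        dx[, ((n - 1) * HWT + 1):(n * HWT)] <- dy[, n] / HWT
      dy <- as.numeric(dx)
    } else if (l$type == "maxpool") {
      dy <- .maxpool3d_backward_cpp(dy, caches[[i]]$arg, caches[[i]]$xlen)
    } else if (l$type == "inception") {
      g <- .incBackward(l, caches[[i]], dy)
      grads[[i]] <- g$grads
      dy <- g$dx
    } else if (l$type == "convunit") {
      g <- .cuBackward(l, caches[[i]], dy)
      grads[[i]] <- g$grads
      dy <- g$dx
    }
  }
  grads
}

# SGD with momentum over the nested parameter structure
.sgdStep <- function(net, grads, vel, lr, momentum = 0.9) {
  updCU <- function(cu, g, v) {
    if (is.null(v)) v <- list(W = 0 * cu$W, b = 0 * cu$b,
                              gamma = 0 * cu$gamma, beta = 0 * cu$beta)
    for (p in c("W", "b", "gamma", "beta")) {
      v[[p]] <- momentum * v[[p]] - lr * g[[p]]
      cu[[p]] <- cu[[p]] + v[[p]]
    }
    list(cu = cu, v = v)
  }
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]; g <- grads[[i]]
    if (is.null(g)) next
    if (l$type == "convunit") {
      r <- updCU(l, g, vel[[i]])
      net$layers[[i]] <- r$cu; vel[[i]] <- r$v
    } else if (l$type == "inception") {
      if (is.null(vel[[i]])) vel[[i]] <- list()
      for (b in c("b1", "b3a", "b3b", "b5a", "b5b", "pp")) {
        r <- updCU(l[[b]], g[[b]], vel[[i]][[b]])
        net$layers[[i]][[b]] <- r$cu; vel[[i]][[b]] <- r$v
      }
    } else if (l$type == "linear") {
      if (is.null(vel[[i]])) vel[[i]] <- list(W = 0 * l$W, b = 0 * l$b)
      for (p in c("W", "b")) {
        vel[[i]][[p]] <- momentum * vel[[i]][[p]] - lr * g[[p]]
        net$layers[[i]][[p]] <- net$layers[[i]][[p]] + vel[[i]][[p]]
      }
    }
  }
  list(net = net, vel = vel)
}

# ---- schedule / training ----------------------------------------------

#' Training schedule
#'
#' Cosine learning-rate decay with linear warm-up: the rate ramps from
#' 0 to `initialLR` over `warmupIterations`, then follows
#' `initialLR * (1 + cos(pi * p)) / 2` where p is the post-warmup
#' progress fraction, reaching 0 at the final iteration. The defaults
#' (`initialLR = 0.1`, `batchSize = 6`) are the published training
#' setting for this classifier.
#'
#' @param totalIterations total SGD iterations.
#' @param warmupIterations warm-up length (`< totalIterations`).
#' @param initialLR peak learning rate.
#' @param batchSize mini-batch size.
#' @param seed seed for weight init and batch shuffling.
#' @return a `TrainSchedule` list.
#' @export
trainSchedule <- function(totalIterations, warmupIterations = 30L,
                          initialLR = 0.1, batchSize = 6L, seed = 1L) {
  totalIterations <- as.integer(totalIterations)
  warmupIterations <- as.integer(warmupIterations)
  if (warmupIterations >= totalIterations)
    stopf("warmupIterations must be < totalIterations")
  structure(list(initialLR = initialLR, batchSize = as.integer(batchSize),
                 totalIterations = totalIterations,
                 warmupIterations = warmupIterations,
                 seed = as.integer(seed)),
            class = "TrainSchedule")
}

#' Learning rate at a given iteration
#'
#' @param iteration iteration index in `0 .. totalIterations`.
#' @param sched a [trainSchedule()].
#' @return the learning rate.
#' @examples
#' s <- trainSchedule(100, 10)
#' cosineLR(10, s)   # 0.1 at the end of warm-up
#' cosineLR(55, s)   # 0.05 at the post-warmup midpoint
#' cosineLR(100, s)  # 0
#' @export
cosineLR <- function(iteration, sched) {
  stopifnot(iteration >= 0, iteration <= sched$totalIterations)
  w <- sched$warmupIterations
  if (iteration < w) return(sched$initialLR * iteration / w)
  p <- (iteration - w) / (sched$totalIterations - w)
  sched$initialLR * (1 + cos(pi * p)) / 2
}

# stack a list of Clip objects (or L x H x W x C arrays) into the
# network layout (C,H,W,T,N)
.stackClips <- function(clips) {
  arrs <- lapply(clips, function(cl) {
    a <- if (is(cl, "Clip")) cl@frames else cl
    aperm(a, c(4, 2, 3, 1))  # -> C,H,W,T
  })
  d <- dim(arrs[[1]])
  x <- array(0, c(d, length(arrs)))
  for (i in seq_along(arrs)) x[, , , , i] <- arrs[[i]]
  list(x = as.numeric(x), dims = c(d, length(arrs)))
}

.softmax <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

#' Train the clip classifier
#'
#' Cross-entropy minimization with momentum SGD (momentum 0.9) under
#' the cosine warm-up schedule. All randomness (weight initialization
#' and batch shuffling) derives from `sched$seed`, so a repeated run
#' reproduces the loss trace exactly.
#'
#' @param net a network from [buildNetwork()].
#' @param clips list of [Clip-class] objects (or `L x H' x W' x C`
#'   arrays) matching the network's stream and input size.
#' @param labels factor or character vector with exactly two classes;
#'   the positive class is `"pharyngeal"` when present, otherwise the
#'   second level.
#' @param sched a [trainSchedule()].
#' @return list with the trained `net`, the positive class name
#'   `posClass`, and the per-iteration `loss` trace.
#' @export
trainNetwork <- function(net, clips, labels, sched) {
  stopifnot(inherits(sched, "TrainSchedule"))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stopf("training set is degenerate: only one class present (%s)",
          classes[1])
  posClass <- if ("pharyngeal" %in% classes) "pharyngeal" else classes[2]
  negClass <- setdiff(classes, posClass)[1]
  yIdx <- ifelse(labels == posClass, 2L, 1L)

  net <- initNetwork(net, sched$seed)
  vel <- vector("list", length(net$layers))
  losses <- numeric(sched$totalIterations)
  n <- length(clips)
  withSeed(sched$seed + 1L, {
    order <- sample(n)
    pos <- 1L
    for (it in seq_len(sched$totalIterations)) {
      bs <- min(sched$batchSize, n)
      if (pos + bs - 1L > n) { order <- sample(n); pos <- 1L }
      idx <- order[pos:(pos + bs - 1L)]
      pos <- pos + bs
      st <- .stackClips(clips[idx])
      fw <- .forwardNet(net, st$x, st$dims, training = TRUE)
      net <- fw$net
      p <- .softmax(fw$logits)
      yb <- yIdx[idx]
      losses[it] <- -mean(log(pmax(p[cbind(yb, seq_len(bs))], 1e-12)))
      dlog <- p
      dlog[cbind(yb, seq_len(bs))] <- dlog[cbind(yb, seq_len(bs))] - 1
      dlog <- dlog / bs
      g <- .backwardNet(net, fw$caches, dlog)
      lr <- cosineLR(it, sched)
      upd <- .sgdStep(net, g, vel, lr)
      net <- upd$net; vel <- upd$vel
    }
  })
  list(net = net, posClass = posClass, negClass = negClass, loss = losses)
}

#' Pharyngeal-phase probability for one clip
#'
#' Runs a forward pass in inference mode (batch-norm running
#' statistics) and returns the softmax probability of the pharyngeal
#' class. Deterministic: identical clips get identical scores.
#'
#' @param net a (trained) network, or the list returned by
#'   [trainNetwork()].
#' @param clip a [Clip-class] or `L x H' x W' x C` array matching the
#'   network's stream and input size.
#' @return probability in `[0, 1]`.
#' @export
classifyClip <- function(net, clip) {
  if (!is.null(net$net)) net <- net$net
  a <- if (is(clip, "Clip")) clip@frames else clip
  d <- dim(a)
  wantC <- if (net$cfg$stream == "rgb") 3L else 2L
  if (length(d) != 4L || d[1] != 20L || d[2] != net$cfg$inputSize ||
      d[3] != net$cfg$inputSize || d[4] != wantC)
    stopf("clip shape (%s) does not match network input 20x%dx%dx%d",
          paste(d, collapse = "x"), net$cfg$inputSize, net$cfg$inputSize,
          wantC)
  st <- .stackClips(list(a))
  fw <- .forwardNet(net, st$x, st$dims, training = FALSE)
  p <- .softmax(fw$logits)
  as.numeric(p[2, 1])
}

#' Classify a batch of clips
#'
#' Vectorized inference over a list of clips; equivalent to calling
#' [classifyClip()] on each but batched through the network.
#'
#' @inheritParams classifyClip
#' @param clips list of clips.
#' @param batchSize forward batch size.
#' @return numeric vector of pharyngeal-class probabilities.
#' @export
classifyClips <- function(net, clips, batchSize = 8L) {
  if (!is.null(net$net)) net <- net$net
  out <- numeric(length(clips))
  i <- 1L
  while (i <= length(clips)) {
    j <- min(i + batchSize - 1L, length(clips))
    st <- .stackClips(clips[i:j])
    fw <- .forwardNet(net, st$x, st$dims, training = FALSE)
    out[i:j] <- .softmax(fw$logits)[2, ]
    i <- j + 1L
  }
  out
}

#' Save / load a model checkpoint
#'
#' The network is serialized with a JSON sidecar recording the
#' configuration and exact parameter count.
#'
#' @param net network (or [trainNetwork()] result).
#' @param path checkpoint path (`.rds`; sidecar gets `.json`).
#' @return `saveCheckpoint`: `path` invisibly; `loadCheckpoint`: the
#'   network object.
#' @export
saveCheckpoint <- function(net, path) {
  obj <- if (!is.null(net$net)) net else list(net = net)
  saveRDS(obj, path)
  side <- list(variant = obj$net$cfg$variant, stream = obj$net$cfg$stream,
               widthScale = obj$net$cfg$widthScale,
               inputSize = obj$net$cfg$inputSize,
               nParameters = countParameters(obj$net))
  jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) readRDS(path)
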