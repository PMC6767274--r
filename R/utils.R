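# Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so package functions never disturb the session RNG.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Bilinear resize of an H x W matrix to targetH x targetW.
# EBImage::resize scales dim1 -> w and dim2 -> h, so pass row/col
# targets in that order.
resizeMatrix <- function(m, targetH, targetW) {
  if (nrow(m) == targetH && ncol(m) == targetW) return(m)
  r <- EBImage::resize(EBImage::Image(m), w = targetH, h = targetW,
                       filter = "bilinear")
  EBImage::imageData(r)
}

# ITU-R BT.601 luma conversion of one T x H x W x 3 array (or a single
# H x W x 3 frame) to single-channel.
toGray <- function(a) {
  nd <- length(dim(a))
  if (nd == 3L) {  # H x W x 3
    0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  } else {         # T x H x W x 3
    g <- 0.299 * a[, , , 1] + 0.587 * a[, , , 2] + 0.114 * a[, , , 3]
    dim(g) <- c(dim(a)[1:3], 1L)
    g
  }
}

# round half away from zero (reports and annotator merging use this,
# not banker's rounding)
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
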