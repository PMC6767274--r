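# Independent reference implementations used as oracles. These share
# no code with the package internals: each re-derives the rule
# literally with a different mechanism.

# candidate selection: repeatedly take the highest remaining tally
# entry (earliest index on ties), accept when it strictly exceeds vth
# and lies in no accepted span
oracleSelectCandidates <- function(tally, vth = 2.5, maxCandidates = 5L,
                                   clipLen = 20L, seqLen) {
  processed <- rep(FALSE, length(tally))
  spans <- list()
  while (sum(!processed) > 0 && length(spans) < maxCandidates) {
    best <- NA
    for (i in seq_along(tally)) {
      if (processed[i]) next
      if (is.na(best) || tally[i] > tally[best]) best <- i
    }
    processed[best] <- TRUE
    if (tally[best] <= vth) break
    t0 <- best - 1L
    inSpan <- FALSE
    for (sp in spans) if (t0 >= sp[1] && t0 <= sp[2]) inSpan <- TRUE
    if (inSpan) next
    start <- t0 - clipLen %/% 2L
    if (start < 0) start <- 0L
    if (start > seqLen - clipLen) start <- seqLen - clipLen
    spans[[length(spans) + 1L]] <- c(start, start + clipLen - 1L)
  }
  if (length(spans) == 0)
    return(matrix(integer(), ncol = 2))
  m <- do.call(rbind, spans)
  m[order(m[, 1]), , drop = FALSE]
}

# maximal above-threshold runs by explicit frame scanning
oracleExtractIntervals <- function(s, scoreth = 0.5, frameth = 5L,
                                   lam = 0.001) {
  out <- NULL
  i <- 1L
  T <- length(s)
  while (i <= T) {
    if (s[i] > scoreth) {
      j <- i
      while (j < T && s[j + 1L] > scoreth) j <- j + 1L
      if (j - i + 1L > frameth)
        out <- rbind(out, c(i - 1L, j - 1L, mean(s[i:j]) + lam * (j - i + 1L)))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

oracleIOU <- function(a, b) {
  fa <- a[1]:a[2]; fb <- b[1]:b[2]
  length(intersect(fa, fb)) / length(union(fa, fb))
}

# literal re-derivation of the matching precedence: loop picking the
# unprocessed detection with the highest confidence (earliest start on
# ties) and resolving its ground-truth claim by enumeration
oracleMatchDetections <- function(dets, gts, iouTh = 0.3, fps = 15) {
  nd <- nrow(dets); ng <- nrow(gts)
  claimed <- rep(FALSE, ng); done <- rep(FALSE, nd)
  tp <- 0L; fp <- 0L; ign <- 0L
  terr <- function(d, g) {
    (abs(d[1] - g[1]) + abs((d[1] + d[2]) / 2 - (g[1] + g[2]) / 2) +
       abs(d[2] - g[2])) / 3 / fps
  }
  for (step in seq_len(nd)) {
    best <- NA
    for (i in seq_len(nd)) {
      if (done[i]) next
      if (is.na(best) || dets$confidence[i] > dets$confidence[best] ||
          (dets$confidence[i] == dets$confidence[best] &&
           dets$start_frame[i] < dets$start_frame[best]))
        best <- i
    }
    done[best] <- TRUE
    d <- c(dets$start_frame[best], dets$end_frame[best])
    overl <- c(); for (j in seq_len(ng)) {
      if (oracleIOU(d, c(gts$start_frame[j], gts$end_frame[j])) > iouTh)
        overl <- c(overl, j)
    }
    if (length(overl) == 0) { fp <- fp + 1L; next }
    avail <- overl[!claimed[overl]]
    if (length(avail) == 0) { ign <- ign + 1L; next }
    bj <- NA
    for (j in avail) {
      g <- c(gts$start_frame[j], gts$end_frame[j])
      if (is.na(bj)) { bj <- j; next }
      gb <- c(gts$start_frame[bj], gts$end_frame[bj])
      if (terr(d, g) < terr(d, gb) ||
          (terr(d, g) == terr(d, gb) &&
           oracleIOU(d, g) > oracleIOU(d, gb)) ||
          (terr(d, g) == terr(d, gb) &&
           oracleIOU(d, g) == oracleIOU(d, gb) &&
           gts$start_frame[j] < gts$start_frame[bj])) bj <- j
    }
    claimed[bj] <- TRUE
    tp <- tp + 1L
  }
  list(tp = tp, fp = fp, ignored = ign, fn = ng - tp)
}

# random matching instance on one video timeline
randomMatchInstance <- function() {
  nd <- sample(0:6, 1); ng <- sample(0:6, 1)
  mk <- function(n) {
    st <- sample(0:80, n, replace = TRUE)
    len <- sample(3:25, n, replace = TRUE)
    data.frame(start_frame = st, end_frame = st + len - 1L)
  }
  d <- mk(nd); g <- mk(ng)
  d$confidence <- round(runif(nd), 2)  # rounded to exercise ties
  list(dets = d, gts = g)
}
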