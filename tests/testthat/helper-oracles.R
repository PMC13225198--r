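# Independent oracles used across the suite. These deliberately avoid the
# package's analytic code paths: IoU by counting unit pixels, matching by
# exhaustive enumeration.

# Pixel set of an integer-coordinate half-open box, encoded as complex
# numbers x + iy (one per covered unit pixel).
rasterPixels <- function(b) {
  xs <- seq(b[1], b[3] - 1)
  ys <- seq(b[2], b[4] - 1)
  as.vector(outer(xs, ys, function(x, y) x + 1i * y))
}

# Rasterised IoU: |A intersect B| / |A union B| over unit pixels.
rasterIoU <- function(a, b) {
  A <- rasterPixels(a)
  B <- rasterPixels(b)
  length(intersect(A, B)) / length(union(A, B))
}

# Exhaustive maximum-cardinality one-to-one matching over event pairs with
# temporal overlap >= minOverlap. Overlap computed by intersecting frame
# sets, not by interval arithmetic.
bruteMatchTP <- function(pred, truth, minOverlap = 1L) {
  if (!nrow(pred) || !nrow(truth)) return(0L)
  ov <- matrix(0L, nrow(pred), nrow(truth))
  for (i in seq_len(nrow(pred)))
    for (j in seq_len(nrow(truth)))
      ov[i, j] <- length(intersect(seq(pred$start_frame[i], pred$end_frame[i]),
                                   seq(truth$start_frame[j], truth$end_frame[j])))
  pairs <- which(ov >= minOverlap, arr.ind = TRUE)
  best <- 0L
  recurse <- function(k, usedP, usedT, cnt) {
    if (cnt + (nrow(pairs) - k + 1L) <= best) return()
    if (k > nrow(pairs)) { best <<- max(best, cnt); return() }
    recurse(k + 1L, usedP, usedT, cnt)
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!(i %in% usedP) && !(j %in% usedT))
      recurse(k + 1L, c(usedP, i), c(usedT, j), cnt + 1L)
  }
  if (nrow(pairs)) recurse(1L, integer(), integer(), 0L)
  best
}

# Random sorted, non-overlapping event list on a frame span.
randomEventList <- function(nMax = 5, span = 120, maxDur = 20) {
  n <- sample(0:nMax, 1)
  if (n == 0)
    return(data.frame(start_frame = integer(), end_frame = integer()))
  starts <- sort(sample(0:(span - 1), n))
  ends <- starts + sample(0:maxDur, n, replace = TRUE)
  # enforce non-overlap by clipping each event before the next start
  for (i in seq_len(n - 1))
    ends[i] <- min(ends[i], starts[i + 1] - 1)
  ok <- ends >= starts
  data.frame(start_frame = starts[ok], end_frame = ends[ok])
}

# A noiseless single-pause track built directly from boxes (no simulator):
# oscillating width with a frozen stretch.
frozenBoxTrack <- function(n = 400, freezeAt = 100:130, fps = 500, f = 40) {
  phase <- 2 * pi * f * (seq_len(n) - 1) / fps
  hw <- 40 + 160 * abs(sin(phase))
  hw[freezeAt + 1] <- 120
  d <- data.frame(frame = seq_len(n) - 1L, x_min = 400 - hw, y_min = 250,
                  x_max = 400 + hw, y_max = 350)
  BirdTrack(d, frameRate = fps)
}
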