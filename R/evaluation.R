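#' @rdname ConfusionCounts-class
#' @param tp,fp,fn Non-negative integer counts.
#' @return `ConfusionCounts()` returns a validated counts object.
#' @export
ConfusionCounts <- function(tp = 0L, fp = 0L, fn = 0L) {
  new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn))
}

#' Confusion-count accessors
#'
#' @param x A [ConfusionCounts-class].
#' @return Integer count.
#' @name confusionAccessors
NULL

#' @rdname confusionAccessors
#' @export
setMethod("tp", "ConfusionCounts", function(x) x@tp)
#' @rdname confusionAccessors
#' @export
setMethod("fp", "ConfusionCounts", function(x) x@fp)
#' @rdname confusionAccessors
#' @export
setMethod("fn", "ConfusionCounts", function(x) x@fn)

#' @describeIn ConfusionCounts-class Sum confusion counts across videos.
#' @param e1,e2 `ConfusionCounts` objects to pool.
#' @export
setMethod("+", signature("ConfusionCounts", "ConfusionCounts"),
  function(e1, e2) ConfusionCounts(e1@tp + e2@tp, e1@fp + e2@fp,
                                   e1@fn + e2@fn))

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d FN=%d\n", object@tp, object@fp,
              object@fn))
  p <- suppressWarnings(precision(object))
  r <- suppressWarnings(recall(object))
  f <- suppressWarnings(f1Score(object))
  cat(sprintf("  precision=%.3f (%.0f%%)  recall=%.3f (%.0f%%)  F1=%.2f\n",
              p, 100 * p, r, 100 * r, f))
})

zeroDenom <- function(what) {
  warning(sprintf("%s undefined (zero denominator); reporting 0", what),
          call. = FALSE)
  0
}

#' @rdname detectionMetrics
#' @export
setMethod("precision", "ConfusionCounts", function(x) {
  d <- x@tp + x@fp
  if (d == 0) zeroDenom("precision") else x@tp / d
})

#' @rdname detectionMetrics
#' @export
setMethod("recall", "ConfusionCounts", function(x) {
  d <- x@tp + x@fn
  if (d == 0) zeroDenom("recall") else x@tp / d
})

#' @rdname detectionMetrics
#' @export
setMethod("f1Score", "ConfusionCounts", function(x) {
  p <- precision(x); r <- recall(x)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
})

overlapFrames <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

#' Match predicted pauses to annotated pauses
#'
#' One-to-one event matching: a predicted pause overlapping an annotated
#' pause by at least `minOverlapFrames` frames can be counted as a true
#' positive, each event matching at most once. Leftover predictions are
#' false positives, leftover annotations false negatives, so
#' `tp + fp = #predicted` and `tp + fn = #annotated` always.
#'
#' `method = "optimal"` (default) finds a maximum-cardinality one-to-one
#' matching on the overlap graph (via bipartite matching), which credits as
#' many correct detections as any matching can. `method = "greedy"` pairs
#' events in order of decreasing temporal overlap; it is simpler but can
#' under-count true positives when one long prediction overlaps an
#' annotation that a neighbouring prediction should have claimed.
#'
#' Events within each list should normally be non-overlapping; overlapping
#' entries are accepted (matching stays one-to-one) to tolerate merged
#' multi-source prediction files.
#'
#' @param predicted,truth [PauseEvents-class] objects (or data frames with
#'   `start_frame`/`end_frame` columns).
#' @param minOverlapFrames Minimum temporal overlap, in frames, for a
#'   predicted/annotated pair to count as a match (default 1 — the weakest
#'   defensible criterion; raise it for stricter matching).
#' @param minOverlapFraction Optional alternative criterion: minimum
#'   overlap as a fraction of the annotated event's duration (applied in
#'   addition to `minOverlapFrames` when non-`NULL`).
#' @param method `"optimal"` or `"greedy"`.
#' @return A [ConfusionCounts-class].
#' @examples
#' p <- PauseEvents(10, 20, 500); g <- PauseEvents(12, 18, 500)
#' matchPauses(p, g)  # TP=1
#' @export
matchPauses <- function(predicted, truth, minOverlapFrames = 1L,
                        minOverlapFraction = NULL,
                        method = c("optimal", "greedy")) {
  method <- match.arg(method)
  pd <- eventFrames(predicted)
  gt <- eventFrames(truth)
  nP <- nrow(pd); nG <- nrow(gt)
  if (!nP || !nG) return(ConfusionCounts(0L, nP, nG))
  ov <- outer(seq_len(nP), seq_len(nG), function(i, j)
    overlapFrames(pd$start[i], pd$end[i], gt$start[j], gt$end[j]))
  ok <- ov >= minOverlapFrames
  if (!is.null(minOverlapFraction)) {
    need <- ceiling(minOverlapFraction * (gt$end - gt$start + 1L))
    ok <- ok & sweep(ov, 2, need, ">=")
  }
  ov[!ok] <- 0L
  ntp <- if (method == "greedy") greedyMatchCount(ov)
         else maxMatchCount(ov)
  ConfusionCounts(tp = ntp, fp = nP - ntp, fn = nG - ntp)
}

eventFrames <- function(x) {
  if (is(x, "PauseEvents"))
    data.frame(start = startFrame(x), end = endFrame(x))
  else data.frame(start = as.integer(x$start_frame),
                  end = as.integer(x$end_frame))
}

greedyMatchCount <- function(ov) {
  ntp <- 0L
  while (any(ov > 0)) {
    k <- which.max(ov)
    i <- (k - 1L) %% nrow(ov) + 1L
    j <- (k - 1L) %/% nrow(ov) + 1L
    ntp <- ntp + 1L
    ov[i, ] <- 0L
    ov[, j] <- 0L
  }
  ntp
}

maxMatchCount <- function(ov) {
  pairs <- which(ov > 0, arr.ind = TRUE)
  if (!nrow(pairs)) return(0L)
  nP <- nrow(ov); nG <- ncol(ov)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nP), rep(TRUE, nG)),
    edges = as.vector(t(cbind(pairs[, 1], nP + pairs[, 2]))))
  as.integer(igraph::max_bipartite_match(g)$matching_size)
}

#' Frames per wingbeat
#'
#' At 500 fps a 35 Hz wingbeat spans about 14 frames — the sampling density
#' that makes pause plateaus resolvable.
#'
#' @param frameRate Frames per second.
#' @param wingbeatHz Wingbeat frequency in Hz.
#' @return Numeric, frames per full wingbeat cycle.
#' @export
framesPerWingbeat <- function(frameRate, wingbeatHz) frameRate / wingbeatHz

#' Estimate the wingbeat frequency from a Jaccard series
#'
#' Frequency of the largest non-DC peak in the discrete Fourier spectrum of
#' the mean-removed series. Pause intervals can be masked out first (their
#' samples are replaced by the series mean) so long pauses do not distort
#' the spectrum.
#'
#' Note that the IoU between consecutive frames is a *rectified* motion
#' proxy: a symmetric wing-stroke envelope produces two dissimilarity dips
#' per full wingbeat (one per stroke), so the dominant spectral peak of a
#' box-derived Jaccard series sits at twice the wingbeat frequency. Set
#' `peaksPerWingbeat = 2` to convert such a peak to wingbeats per second;
#' the default (`1`) returns the raw peak frequency.
#'
#' @param series A [JaccardSeries-class] spanning at least two full expected
#'   periods.
#' @param peaksPerWingbeat Spectral peaks per wingbeat cycle (see Details).
#' @param excludeEvents Optional [PauseEvents-class] of intervals to mask.
#' @return Estimated frequency in Hz.
#' @examples
#' fs <- 500; t <- (0:499) / fs
#' js <- new("JaccardSeries", frame = 0:499,
#'           values = 0.5 + 0.1 * sin(2 * pi * 40 * t), frameRate = fs)
#' estimateWingbeatFrequency(js)  # ~40
#' @export
estimateWingbeatFrequency <- function(series, peaksPerWingbeat = 1,
                                      excludeEvents = NULL) {
  stopifnot(is(series, "JaccardSeries"))
  v <- series@values
  if (!is.null(excludeEvents) && length(excludeEvents)) {
    inPause <- rep(FALSE, length(v))
    for (k in seq_len(length(excludeEvents)))
      inPause <- inPause | (series@frame >= startFrame(excludeEvents)[k] &
                            series@frame <= endFrame(excludeEvents)[k])
    v[inPause] <- mean(v[!inPause])
  }
  x <- v - mean(v)
  if (all(abs(x) < 1e-12))
    stop("no spectral peak: the series is constant", call. = FALSE)
  n <- length(x)
  spec <- Mod(stats::fft(x))[2:(n %/% 2 + 1)]
  peak <- which.max(spec)
  (peak * series@frameRate / n) / peaksPerWingbeat
}

#' Per-video pause statistics
#'
#' Pause frequency is the number of pauses divided by the number of
#' wingbeats in the video (a value of 0.5 means a pause roughly every two
#' wingbeats); the mean pause duration is reported in milliseconds (NA when
#' there are no pauses).
#'
#' @param events A [PauseEvents-class].
#' @param nWingbeats Positive number of wingbeats in the video (counted
#'   manually or via [estimateWingbeatFrequency()]).
#' @param frameRate Frames per second (defaults to the events' frame rate).
#' @return A one-row data frame: `n_pauses`, `n_wingbeats`,
#'   `pause_frequency`, `mean_pause_duration_ms`.
#' @examples
#' ev <- PauseEvents(c(0, 100), c(4, 104), frameRate = 500)
#' pauseStats(ev, nWingbeats = 4)  # frequency 0.5, mean duration 10 ms
#' @export
pauseStats <- function(events, nWingbeats, frameRate = NULL) {
  stopifnot(is(events, "PauseEvents"))
  if (nWingbeats <= 0)
    stop("'nWingbeats' must be > 0", call. = FALSE)
  if (is.null(frameRate)) frameRate <- events@frameRate
  nP <- length(events)
  data.frame(
    n_pauses = nP, n_wingbeats = nWingbeats,
    pause_frequency = nP / nWingbeats,
    mean_pause_duration_ms = if (nP) mean(durationFrames(events)) * 1000 /
      frameRate else NA_real_)
}

#' Evaluate predicted against annotated pauses across videos
#'
#' @param predicted,truth Named lists of [PauseEvents-class] (names are
#'   video ids; the two lists are aligned by name, missing entries count as
#'   empty).
#' @param ... Passed to [matchPauses()].
#' @return A list with `perVideo` (data frame of counts and metrics per
#'   video) and `pooled` (a [ConfusionCounts-class] over all videos).
#' @export
evaluatePauses <- function(predicted, truth, ...) {
  ids <- union(names(predicted), names(truth))
  fr <- c(vapply(predicted, frameRate, numeric(1)),
          vapply(truth, frameRate, numeric(1)), 500)[1]
  rows <- list(); pooled <- ConfusionCounts()
  for (id in ids) {
    p <- predicted[[id]] %||% PauseEvents(frameRate = fr)
    g <- truth[[id]] %||% PauseEvents(frameRate = fr)
    cc <- matchPauses(p, g, ...)
    pooled <- pooled + cc
    rows[[id]] <- data.frame(
      video_id = id, tp = tp(cc), fp = fp(cc), fn = fn(cc),
      precision = suppressWarnings(precision(cc)),
      recall = suppressWarnings(recall(cc)),
      f1 = suppressWarnings(f1Score(cc)))
  }
  list(perVideo = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       pooled = pooled)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
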