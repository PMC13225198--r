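#' @rdname PauseDetectorParam-class
#' @param thresholdFraction,minPauseFrames,gapToleranceFrames,meanWindow,thresholdReference
#'   See the class slots.
#' @return `PauseDetectorParam()` returns a parameter object with validated
#'   defaults.
#' @examples
#' PauseDetectorParam()
#' PauseDetectorParam(thresholdReference = "jaccard", minPauseFrames = 5L)
#' @export
PauseDetectorParam <- function(thresholdFraction = 0.9, minPauseFrames = 3L,
                               gapToleranceFrames = 0L, meanWindow = "global",
                               thresholdReference = c("derivative", "jaccard")) {
  new("PauseDetectorParam",
      thresholdFraction = thresholdFraction,
      minPauseFrames = as.integer(minPauseFrames),
      gapToleranceFrames = as.integer(gapToleranceFrames),
      meanWindow = if (identical(meanWindow, "global")) "global"
                   else as.integer(meanWindow),
      thresholdReference = match.arg(thresholdReference))
}

setMethod("show", "PauseDetectorParam", function(object) {
  cat(sprintf(paste0("PauseDetectorParam: fraction=%g, reference=%s, ",
                     "minPauseFrames=%d, gapTolerance=%d, meanWindow=%s\n"),
              object@thresholdFraction, object@thresholdReference,
              object@minPauseFrames, object@gapToleranceFrames,
              if (identical(object@meanWindow, "global")) "global"
              else as.character(object@meanWindow)))
})

#' Construct a PauseEvents set
#'
#' @param start,end Integer vectors of inclusive 0-based frame intervals,
#'   sorted and non-overlapping.
#' @param frameRate Frames per second, used to derive durations in ms.
#' @return A [PauseEvents-class].
#' @examples
#' ev <- PauseEvents(start = c(100, 400), end = c(129, 419), frameRate = 500)
#' durationMs(ev)  # 60, 40
#' @export
PauseEvents <- function(start = integer(), end = integer(), frameRate) {
  new("PauseEvents",
      ranges = IRanges::IRanges(start = as.integer(start),
                                end = as.integer(end)),
      frameRate = as.numeric(frameRate))
}

#' @describeIn PauseEvents-class Number of events.
#' @param x A `PauseEvents`.
#' @export
setMethod("length", "PauseEvents", function(x) length(x@ranges))

#' @rdname frameRate
#' @export
setMethod("frameRate", "PauseEvents", function(x) x@frameRate)

#' Pause-event interval accessors
#'
#' Start/end frames are inclusive, 0-based; `durationFrames` is
#' `end - start + 1`; `durationMs` converts via the frame rate
#' (`durationFrames * 1000 / frameRate`).
#'
#' @param x A [PauseEvents-class].
#' @return Integer (frames) or numeric (ms) vector, one entry per event.
#' @name pauseAccessors
NULL

#' @rdname pauseAccessors
#' @export
startFrame <- function(x) {
  stopifnot(is(x, "PauseEvents")); BiocGenerics::start(x@ranges)
}

#' @rdname pauseAccessors
#' @export
endFrame <- function(x) {
  stopifnot(is(x, "PauseEvents")); BiocGenerics::end(x@ranges)
}

#' @rdname pauseAccessors
#' @export
durationFrames <- function(x) {
  stopifnot(is(x, "PauseEvents")); BiocGenerics::width(x@ranges)
}

#' @rdname pauseAccessors
#' @export
durationMs <- function(x) durationFrames(x) * 1000 / x@frameRate

#' @describeIn PauseEvents-class Coerce to a data frame in the pause-CSV
#'   dialect (`start_frame,end_frame,duration_frames,duration_ms`).
#' @param row.names,optional,... Passed on conventions of the generic
#'   (unused).
#' @export
setMethod("as.data.frame", "PauseEvents",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(start_frame = startFrame(x), end_frame = endFrame(x),
               duration_frames = durationFrames(x), duration_ms = durationMs(x))
  })

setMethod("show", "PauseEvents", function(object) {
  cat(sprintf("PauseEvents: %d events @ %g fps\n", length(object),
              object@frameRate))
  if (length(object)) {
    df <- as.data.frame(object)
    print(utils::head(df, 8))
    if (nrow(df) > 8) cat(sprintf("... and %d more\n", nrow(df) - 8))
  }
})

#' @rdname pauseThreshold
#' @param window `"global"` (a single mean over the whole series) or an
#'   integer window length: the threshold then follows a centred running
#'   mean, with shrinking windows at the edges.
#' @section Reference signals:
#' For a [JaccardSeries-class] the threshold is `fraction * mean(J)`, the
#' literal published rule. For a [DerivativeSeries-class] it is
#' `fraction * mean(|dJ|)` — a threshold on the same scale as the quantity
#' being compared, which is the package default in [detectPauses()] (see the
#' methods vignette for why).
#' @examples
#' d <- data.frame(frame = 0:3, x_min = 0, y_min = 0, x_max = 10, y_max = 10)
#' js <- jaccardSeries(BirdTrack(d, 500))
#' pauseThreshold(js, fraction = 0.9)  # 0.9 * mean(J) = 0.9
#' @export
setMethod("pauseThreshold", "JaccardSeries",
  function(x, fraction = 0.9, window = "global", ...) {
    thresholdFromReference(x@values, fraction, window)
  })

#' @rdname pauseThreshold
#' @export
setMethod("pauseThreshold", "DerivativeSeries",
  function(x, fraction = 0.9, window = "global", ...) {
    thresholdFromReference(abs(x@values), fraction, window)
  })

thresholdFromReference <- function(ref, fraction, window) {
  if (!length(ref)) stop("insufficient data: empty series", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  if (identical(window, "global")) return(fraction * mean(ref))
  w <- as.integer(window)
  if (w < 2) stop("'window' must be \"global\" or an integer >= 2",
                  call. = FALSE)
  fraction * runningMean(ref, w)
}

## Centred running mean with shrinking (partial) windows at the edges.
runningMean <- function(x, w) {
  n <- length(x)
  half <- w %/% 2
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Flag candidate pause frames
#'
#' A frame is flagged when the absolute derivative of the Jaccard series
#' does not exceed the threshold — a derivative approaching zero indicates
#' minimal change between frames. The sign of the derivative is ignored.
#' The comparison is inclusive so that a threshold of exactly 0 flags
#' exactly-zero derivatives (the completely still limit) and nothing else.
#'
#' @param deriv A [DerivativeSeries-class].
#' @param threshold Non-negative numeric scalar, or a vector aligned to the
#'   series (from a windowed [pauseThreshold()]).
#' @return Logical mask aligned to `frameIndex(deriv)`.
#' @export
flagPauseFrames <- function(deriv, threshold) {
  stopifnot(is(deriv, "DerivativeSeries"))
  if (any(threshold < 0)) stop("'threshold' must be >= 0", call. = FALSE)
  if (!length(threshold) %in% c(1L, length(deriv@values)))
    stop("'threshold' must be scalar or aligned to the series", call. = FALSE)
  abs(deriv@values) <= threshold
}

#' Extract pause events from a flagged-frame mask
#'
#' Maximal runs of flagged frames become events, after bridging non-flagged
#' gaps of at most `gapToleranceFrames` within a contiguous stretch of
#' frames, and discarding runs shorter than `minPauseFrames`. Runs never
#' extend across detection gaps (missing frame indices). Events are
#' returned sorted and non-overlapping, labelled with original-video frame
#' indices.
#'
#' @param mask Logical vector, typically from [flagPauseFrames()].
#' @param frame Integer frame indices aligned to `mask` (default
#'   `0:(length(mask) - 1)`).
#' @param param A [PauseDetectorParam-class] supplying `minPauseFrames` and
#'   `gapToleranceFrames`.
#' @param frameRate Frames per second for the resulting events.
#' @return A [PauseEvents-class].
#' @examples
#' extractPauseEvents(c(TRUE, TRUE, FALSE, TRUE, TRUE),
#'                    param = PauseDetectorParam(minPauseFrames = 4,
#'                                               gapToleranceFrames = 1),
#'                    frameRate = 500)  # one merged 5-frame event
#' @export
extractPauseEvents <- function(mask, frame = seq_along(mask) - 1L,
                               param = PauseDetectorParam(), frameRate = 500) {
  stopifnot(is.logical(mask), length(frame) == length(mask))
  frame <- as.integer(frame)
  if (!length(mask)) return(PauseEvents(frameRate = frameRate))
  segStart <- c(1L, which(diff(frame) != 1L) + 1L)
  segEnd <- c(segStart[-1L] - 1L, length(mask))
  starts <- integer(); ends <- integer()
  for (s in seq_along(segStart)) {
    idx <- segStart[s]:segEnd[s]
    m <- bridgeGaps(mask[idx], param@gapToleranceFrames)
    r <- rle(m)
    rEnd <- cumsum(r$lengths); rStart <- rEnd - r$lengths + 1L
    keep <- r$values & r$lengths >= param@minPauseFrames
    starts <- c(starts, frame[idx[rStart[keep]]])
    ends <- c(ends, frame[idx[rEnd[keep]]])
  }
  o <- order(starts)
  PauseEvents(start = starts[o], end = ends[o], frameRate = frameRate)
}

## Turn FALSE runs of length <= tol into TRUE when they separate TRUE runs.
bridgeGaps <- function(mask, tol) {
  if (tol < 1L || !any(mask)) return(mask)
  r <- rle(mask)
  n <- length(r$values)
  fill <- !r$values & r$lengths <= tol &
    seq_len(n) > 1L & seq_len(n) < n
  r$values[fill] <- TRUE
  inverse.rle(r)
}

#' @rdname detectPauses
#' @details
#' The full composition: [jaccardSeries()] -> [finiteDifference()] ->
#' [pauseThreshold()] -> [flagPauseFrames()] -> [extractPauseEvents()].
#' With the default `thresholdReference = "derivative"` the cutoff is
#' `thresholdFraction * mean(|dJ|)`; with `"jaccard"` it is
#' `thresholdFraction * mean(J)`, the published wording. The result is
#' deterministic for a fixed track and parameter set. Event intervals are
#' labelled with the frame index of the first frame of each
#' consecutive-frame pair, so an event over derivative samples `k..m`
#' reports `start_frame = k`, `end_frame = m`.
#' @examples
#' sc <- generateBoxSequence(SceneParam(durationS = 1, jitterSd = 0,
#'                                      pauseIntervals = cbind(250, 279)))
#' detectPauses(sceneTrack(sc))
#' @export
setMethod("detectPauses", "BirdTrack", function(x, param = PauseDetectorParam(),
                                                ...) {
  if (length(x) < 3)
    stop("insufficient data: a track needs >= 3 detections", call. = FALSE)
  js <- jaccardSeries(x)
  ds <- finiteDifference(js)
  thr <- if (param@thresholdReference == "derivative")
    pauseThreshold(ds, fraction = param@thresholdFraction,
                   window = param@meanWindow)
  else {
    t_ <- pauseThreshold(js, fraction = param@thresholdFraction,
                         window = param@meanWindow)
    ## align the (possibly windowed) Jaccard-based threshold to the
    ## derivative samples, which are a subset of the Jaccard samples
    if (length(t_) > 1L) t_[match(ds@frame, js@frame)] else t_
  }
  mask <- flagPauseFrames(ds, thr)
  extractPauseEvents(mask, frame = ds@frame, param = param,
                     frameRate = x@frameRate)
})
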