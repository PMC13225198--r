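#' Per-frame signals derived from a track
#'
#' `FrameSignal` is the virtual parent of [JaccardSeries-class] and
#' [DerivativeSeries-class]: a numeric value per video frame index, at a
#' known frame rate. Frame indices are 0-based and need not be contiguous —
#' a gap marks frames where the track had no detection, and downstream
#' analyses treat the contiguous segments independently.
#'
#' @slot frame integer, 0-based frame indices (strictly increasing).
#' @slot values numeric, one value per frame index.
#' @slot frameRate numeric scalar, frames per second (> 0).
#' @name FrameSignal-class
#' @aliases FrameSignal
#' @exportClass FrameSignal
setClass("FrameSignal", representation("VIRTUAL",
  frame = "integer", values = "numeric", frameRate = "numeric"))

setValidity("FrameSignal", function(object) {
  msg <- NULL
  if (length(object@frame) != length(object@values))
    msg <- c(msg, "'frame' and 'values' must have equal length")
  if (length(object@frame) && (any(diff(object@frame) <= 0)))
    msg <- c(msg, "'frame' must be strictly increasing")
  if (length(object@frame) && any(object@frame < 0))
    msg <- c(msg, "'frame' indices must be >= 0")
  if (length(object@frameRate) != 1 || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msg <- c(msg, "'frameRate' must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' Jaccard coefficient series
#'
#' The Jaccard (intersection-over-union) coefficient between the bounding
#' boxes of a tracked bird in consecutive frames, one value per
#' consecutive-frame pair. Entry with frame index `k` compares the boxes at
#' frames `k` and `k + 1`. Values lie in \[0, 1\]: 1 means the box did not
#' move at all (a candidate pause), low values mean large apparent motion.
#'
#' @slot frame,values,frameRate See [FrameSignal-class].
#' @seealso [jaccardSeries()], [finiteDifference()]
#' @name JaccardSeries-class
#' @aliases JaccardSeries-class
#' @exportClass JaccardSeries
setClass("JaccardSeries", contains = "FrameSignal")

setValidity("JaccardSeries", function(object) {
  eps <- 1e-9
  if (length(object@values) &&
      (any(object@values < -eps) || any(object@values > 1 + eps)))
    return("Jaccard values must lie in [0, 1]")
  TRUE
})

#' Derivative of a Jaccard series
#'
#' Forward finite difference of a [JaccardSeries-class], in units of Jaccard
#' change per frame. Near-zero values indicate minimal frame-to-frame change
#' in the bounding box — the signature of a flapping pause.
#'
#' @slot frame,values,frameRate See [FrameSignal-class].
#' @name DerivativeSeries-class
#' @aliases DerivativeSeries-class
#' @exportClass DerivativeSeries
setClass("DerivativeSeries", contains = "FrameSignal")

#' A tracked bird
#'
#' One individual's per-frame detections over a video. The `detections`
#' data frame has columns `frame` (0-based, strictly increasing), `x_min`,
#' `y_min`, `x_max`, `y_max` (continuous pixel coordinates, origin at the
#' top-left corner, half-open rectangles \[x_min, x_max) x \[y_min, y_max)),
#' `score` (detector confidence in \[0, 1\]) and `label`.
#'
#' @slot trackId integer track identifier.
#' @slot detections data.frame of per-frame detections (see Details).
#' @slot frameRate numeric scalar, frames per second.
#' @seealso [BirdTrack()], [jaccardSeries()], [detectPauses()]
#' @name BirdTrack-class
#' @aliases BirdTrack-class
#' @exportClass BirdTrack
setClass("BirdTrack", representation(
  trackId = "integer", detections = "data.frame", frameRate = "numeric"))

setValidity("BirdTrack", function(object) {
  d <- object@detections
  need <- c("frame", "x_min", "y_min", "x_max", "y_max", "score")
  if (!all(need %in% names(d)))
    return(paste("detections must have columns:", paste(need, collapse = ", ")))
  msg <- NULL
  if (nrow(d)) {
    if (any(diff(d$frame) <= 0))
      msg <- c(msg, "detection frame indices must be strictly increasing")
    if (any(d$frame < 0)) msg <- c(msg, "frame indices must be >= 0")
    bad <- validateBoxes(as.matrix(d[, c("x_min", "y_min", "x_max", "y_max")]))
    if (!is.null(bad)) msg <- c(msg, bad)
    if (any(d$score < 0 | d$score > 1))
      msg <- c(msg, "scores must lie in [0, 1]")
  }
  if (length(object@frameRate) != 1 || object@frameRate <= 0)
    msg <- c(msg, "'frameRate' must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' Flapping-pause events
#'
#' A set of sorted, non-overlapping frame intervals during which the wings
#' are held still. Intervals are stored as an [IRanges::IRanges] of 0-based,
#' inclusive frame indices; durations in milliseconds follow from the frame
#' rate.
#'
#' @slot ranges an `IRanges` of inclusive frame intervals.
#' @slot frameRate numeric scalar, frames per second.
#' @seealso [PauseEvents()], [detectPauses()], [matchPauses()]
#' @name PauseEvents-class
#' @aliases PauseEvents-class
#' @exportClass PauseEvents
setClass("PauseEvents", representation(
  ranges = "IRanges", frameRate = "numeric"))

setValidity("PauseEvents", function(object) {
  r <- object@ranges
  msg <- NULL
  if (length(r) > 1) {
    s <- BiocGenerics::start(r); e <- BiocGenerics::end(r)
    if (any(diff(s) < 0)) msg <- c(msg, "events must be sorted by start frame")
    if (any(s[-1] <= e[-length(e)]))
      msg <- c(msg, "events must be pairwise non-overlapping")
  }
  if (length(r) && any(BiocGenerics::start(r) < 0))
    msg <- c(msg, "frame indices must be >= 0")
  if (length(object@frameRate) != 1 || object@frameRate <= 0)
    msg <- c(msg, "'frameRate' must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' A sequence of video frames
#'
#' Grayscale frames of uniform dimensions stored as a `height x width x n`
#' array with intensities in \[0, 1\], plus their 0-based frame indices and
#' the recording frame rate.
#'
#' @slot frames 3-d numeric array, `dim = c(height, width, n)`.
#' @slot frame integer, 0-based frame indices.
#' @slot frameRate numeric scalar, frames per second.
#' @seealso [FrameSequence()], [estimateBackground()], [detectForeground()]
#' @name FrameSequence-class
#' @aliases FrameSequence-class
#' @exportClass FrameSequence
setClass("FrameSequence", representation(
  frames = "array", frame = "integer", frameRate = "numeric"))

setValidity("FrameSequence", function(object) {
  msg <- NULL
  if (length(dim(object@frames)) != 3)
    msg <- c(msg, "'frames' must be a height x width x n array")
  else if (dim(object@frames)[3] != length(object@frame))
    msg <- c(msg, "third array dimension must match length(frame)")
  if (length(object@frame) > 1 && any(diff(object@frame) <= 0))
    msg <- c(msg, "'frame' must be strictly increasing")
  if (length(object@frameRate) != 1 || object@frameRate <= 0)
    msg <- c(msg, "'frameRate' must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' Background-subtraction detector model
#'
#' A static background image plus the two thresholds of the reference
#' detector: the absolute intensity difference above which a pixel counts
#' as foreground, and the minimum connected-component area (in px^2) kept
#' as a detection.
#'
#' @slot background numeric matrix, the background image.
#' @slot threshold numeric scalar > 0, intensity-difference threshold.
#' @slot minBlobArea numeric scalar >= 1, minimum blob area in pixels.
#' @seealso [BackgroundModel()], [detectForeground()]
#' @name BackgroundModel-class
#' @aliases BackgroundModel-class
#' @exportClass BackgroundModel
setClass("BackgroundModel", representation(
  background = "matrix", threshold = "numeric", minBlobArea = "numeric"))

setValidity("BackgroundModel", function(object) {
  msg <- NULL
  if (object@threshold <= 0) msg <- c(msg, "'threshold' must be > 0")
  if (object@minBlobArea < 1) msg <- c(msg, "'minBlobArea' must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Event-level confusion counts
#'
#' Counts of true positives (predicted pauses matched one-to-one to an
#' annotated pause), false positives (unmatched predictions) and false
#' negatives (unmatched annotations).
#'
#' @slot tp,fp,fn non-negative integers.
#' @seealso [ConfusionCounts()], [matchPauses()], [precision()]
#' @name ConfusionCounts-class
#' @aliases ConfusionCounts-class
#' @exportClass ConfusionCounts
setClass("ConfusionCounts", representation(
  tp = "integer", fp = "integer", fn = "integer"))

setValidity("ConfusionCounts", function(object) {
  if (any(c(object@tp, object@fp, object@fn) < 0))
    "counts must be non-negative" else TRUE
})

#' Pause-detector parameters
#'
#' Tuning parameters of the plateau segmentation. The threshold is
#' `thresholdFraction` times the mean of a reference signal: with
#' `thresholdReference = "derivative"` (the default) the mean absolute
#' frame-to-frame Jaccard change, with `"jaccard"` the mean Jaccard
#' coefficient itself. Frames whose absolute derivative falls below the
#' threshold are flagged; maximal flagged runs become pause events after
#' bridging non-flagged gaps of at most `gapToleranceFrames` and discarding
#' runs shorter than `minPauseFrames`.
#'
#' @slot thresholdFraction numeric in (0, 1], default 0.9.
#' @slot minPauseFrames integer >= 1, default 3 (6 ms at 500 fps).
#' @slot gapToleranceFrames integer >= 0, default 0.
#' @slot meanWindow `"global"`, or an integer window length (frames) for a
#'   running-mean threshold on long recordings with drifting scale.
#' @slot thresholdReference `"derivative"` or `"jaccard"`.
#' @seealso [PauseDetectorParam()], [detectPauses()]
#' @name PauseDetectorParam-class
#' @aliases PauseDetectorParam-class
#' @exportClass PauseDetectorParam
setClass("PauseDetectorParam", representation(
  thresholdFraction = "numeric", minPauseFrames = "integer",
  gapToleranceFrames = "integer", meanWindow = "ANY",
  thresholdReference = "character"))

setValidity("PauseDetectorParam", function(object) {
  msg <- NULL
  if (object@thresholdFraction <= 0 || object@thresholdFraction > 1)
    msg <- c(msg, "'thresholdFraction' must be in (0, 1]")
  if (object@minPauseFrames < 1) msg <- c(msg, "'minPauseFrames' must be >= 1")
  if (object@gapToleranceFrames < 0)
    msg <- c(msg, "'gapToleranceFrames' must be >= 0")
  mw <- object@meanWindow
  if (!(identical(mw, "global") ||
        (is.numeric(mw) && length(mw) == 1 && mw >= 2)))
    msg <- c(msg, "'meanWindow' must be \"global\" or an integer >= 2")
  if (!object@thresholdReference %in% c("derivative", "jaccard"))
    msg <- c(msg, "'thresholdReference' must be \"derivative\" or \"jaccard\"")
  if (is.null(msg)) TRUE else msg
})

#' Tracker parameters
#'
#' @slot minIoU numeric in \[0, 1\]: association score below which a
#'   track/detection pair is never matched (default 0.1).
#' @slot maxMissedFrames integer >= 0: a track unmatched for more than this
#'   many consecutive frames is closed (default 5).
#' @slot useAppearance logical: blend an appearance (cosine) similarity into
#'   the association score (default `FALSE`). This is the seam where an
#'   external embedding model can plug in; none is shipped.
#' @slot appearanceWeight numeric in \[0, 1\]: weight of the appearance term,
#'   score = w * cosine + (1 - w) * IoU.
#' @seealso [TrackerParam()], [trackDetections()]
#' @name TrackerParam-class
#' @aliases TrackerParam-class
#' @exportClass TrackerParam
setClass("TrackerParam", representation(
  minIoU = "numeric", maxMissedFrames = "integer",
  useAppearance = "logical", appearanceWeight = "numeric"))

setValidity("TrackerParam", function(object) {
  msg <- NULL
  if (object@minIoU < 0 || object@minIoU > 1)
    msg <- c(msg, "'minIoU' must be in [0, 1]")
  if (object@maxMissedFrames < 0) msg <- c(msg, "'maxMissedFrames' must be >= 0")
  if (object@appearanceWeight < 0 || object@appearanceWeight > 1)
    msg <- c(msg, "'appearanceWeight' must be in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Synthetic hovering-scene parameters
#'
#' Configuration of the synthetic single-bird hovering simulator. The
#' bird's apparent half-width oscillates as
#' `baseHalfWidth + wingAmplitude * |sin(phase)|` (widest at both stroke
#' extremes, emulating the projected wing envelope) with the wing phase
#' advancing at `wingbeatHz` cycles per second; the half-height is modulated
#' analogously by `heightAmplitude`. During a scheduled pause the wing phase
#' freezes and the box is held at the pause posture
#' (`baseHalfWidth + pausePostureFraction * wingAmplitude`, wings extended
#' backwards near mid-pronation) so only body jitter moves it. The body
#' centre performs a mean-reverting Gaussian jitter walk of per-frame
#' standard deviation `jitterSd`. Pauses follow `pauseIntervals` (a 2-column
#' matrix of inclusive 0-based frame intervals) when given, otherwise a
#' Poisson schedule with rate `pauseRatePerS` and uniform durations in
#' `pauseDurationRangeMs`. All randomness derives from `seed`.
#'
#' @slot frameWidth,frameHeight frame dimensions in px (default 800 x 600).
#' @slot frameRate frames per second (default 500).
#' @slot durationS scene duration in seconds.
#' @slot wingbeatHz wingbeat frequency in Hz (default 40; species band 35-45).
#' @slot baseHalfWidth,baseHalfHeight body half-extents in px.
#' @slot wingAmplitude,heightAmplitude wing-envelope modulation in px.
#' @slot pausePostureFraction fraction of `wingAmplitude` at which the box is
#'   held while paused.
#' @slot bodyCenter numeric length 2, mean body centre (px).
#' @slot jitterSd per-frame body jitter standard deviation (px).
#' @slot pixelNoiseSd additive Gaussian pixel noise for rendered frames
#'   (intensity units in \[0, 1\]).
#' @slot pauseIntervals `NULL` or 2-column matrix of frame intervals.
#' @slot pauseRatePerS Poisson rate of random pauses (per second).
#' @slot pauseDurationRangeMs numeric length 2, pause duration range (ms).
#' @slot seed integer random seed.
#' @seealso [SceneParam()], [generateBoxSequence()], [renderFrames()]
#' @name SceneParam-class
#' @aliases SceneParam-class
#' @exportClass SceneParam
setClass("SceneParam", representation(
  frameWidth = "numeric", frameHeight = "numeric", frameRate = "numeric",
  durationS = "numeric", wingbeatHz = "numeric",
  baseHalfWidth = "numeric", baseHalfHeight = "numeric",
  wingAmplitude = "numeric", heightAmplitude = "numeric",
  pausePostureFraction = "numeric", bodyCenter = "numeric",
  jitterSd = "numeric", pixelNoiseSd = "numeric",
  pauseIntervals = "ANY", pauseRatePerS = "numeric",
  pauseDurationRangeMs = "numeric", seed = "integer"))

setValidity("SceneParam", function(object) {
  msg <- NULL
  pos <- c(frameWidth = object@frameWidth, frameHeight = object@frameHeight,
           frameRate = object@frameRate, durationS = object@durationS,
           wingbeatHz = object@wingbeatHz,
           baseHalfWidth = object@baseHalfWidth,
           baseHalfHeight = object@baseHalfHeight)
  if (any(pos <= 0))
    msg <- c(msg, paste("must be > 0:",
                        paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@wingAmplitude < 0 || object@heightAmplitude < 0)
    msg <- c(msg, "amplitudes must be >= 0")
  if (object@pausePostureFraction < 0 || object@pausePostureFraction > 1)
    msg <- c(msg, "'pausePostureFraction' must be in [0, 1]")
  if (length(object@bodyCenter) != 2)
    msg <- c(msg, "'bodyCenter' must have length 2")
  if (object@jitterSd < 0 || object@pixelNoiseSd < 0)
    msg <- c(msg, "noise standard deviations must be >= 0")
  pi_ <- object@pauseIntervals
  if (!is.null(pi_)) {
    if (!is.matrix(pi_) || ncol(pi_) != 2)
      msg <- c(msg, "'pauseIntervals' must be NULL or a 2-column matrix")
    else {
      n <- round(object@frameRate * object@durationS)
      if (nrow(pi_) && (any(pi_[, 1] > pi_[, 2]) || any(pi_ < 0) ||
                        any(pi_[, 2] >= n)))
        msg <- c(msg, "pause intervals must satisfy 0 <= start <= end < nFrames")
      if (nrow(pi_) > 1) {
        o <- order(pi_[, 1])
        if (any(pi_[o, 1][-1] <= pi_[o, 2][-nrow(pi_)]))
          msg <- c(msg, "explicit pause intervals must be non-overlapping")
      }
    }
  }
  if (object@pauseRatePerS < 0) msg <- c(msg, "'pauseRatePerS' must be >= 0")
  if (length(object@pauseDurationRangeMs) != 2 ||
      any(object@pauseDurationRangeMs <= 0) ||
      diff(object@pauseDurationRangeMs) < 0)
    msg <- c(msg, "'pauseDurationRangeMs' must be an increasing positive pair")
  if (is.null(msg)) TRUE else msg
})

#' A ground-truthed synthetic hovering scene
#'
#' The output container of the simulator: the ground-truth track of the
#' bird's tight bounding boxes, the true pause events, the number of full
#' wingbeats actually performed, the generating parameters, and (for the
#' rendered tier) the frames themselves.
#'
#' @slot track [BirdTrack-class] of ground-truth boxes.
#' @slot pauseEvents [PauseEvents-class], the injected pauses.
#' @slot wingbeatCount integer, full wingbeats during active flapping.
#' @slot param the generating [SceneParam-class].
#' @slot frames a [FrameSequence-class], or `NULL` for the box-only tier.
#' @seealso [generateBoxSequence()], [renderFrames()]
#' @name SyntheticScene-class
#' @aliases SyntheticScene-class
#' @exportClass SyntheticScene
setClass("SyntheticScene", representation(
  track = "BirdTrack", pauseEvents = "PauseEvents",
  wingbeatCount = "integer", param = "SceneParam", frames = "ANY"))
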