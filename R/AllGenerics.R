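#' @import methods
NULL

#' Frame rate accessor
#'
#' Frames per second of the underlying recording.
#'
#' @param x An object carrying a frame rate (a [FrameSignal-class],
#'   [BirdTrack-class], [PauseEvents-class] or [FrameSequence-class]).
#' @return Numeric scalar, frames per second.
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' Frame index accessor
#'
#' 0-based video frame indices associated with each element of `x`.
#'
#' @param x A [FrameSignal-class], [BirdTrack-class] or
#'   [FrameSequence-class].
#' @return Integer vector of 0-based frame indices.
#' @export
setGeneric("frameIndex", function(x) standardGeneric("frameIndex"))

#' Signal values accessor
#'
#' @param x A [FrameSignal-class] (Jaccard or derivative series).
#' @return Numeric vector of per-frame signal values.
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' Jaccard coefficient series of a track
#'
#' @param x A [BirdTrack-class].
#' @param ... Further arguments (unused).
#' @return A [JaccardSeries-class].
#' @export
setGeneric("jaccardSeries", function(x, ...) standardGeneric("jaccardSeries"))

#' Detect flapping pauses
#'
#' @param x A [BirdTrack-class] (or object coercible to one).
#' @param param A [PauseDetectorParam-class].
#' @param ... Further arguments passed to methods.
#' @return A [PauseEvents-class].
#' @export
setGeneric("detectPauses", function(x, param = PauseDetectorParam(), ...)
  standardGeneric("detectPauses"))

#' Pause detection threshold
#'
#' @param x A [JaccardSeries-class] or [DerivativeSeries-class]: the
#'   reference signal whose mean sets the threshold.
#' @param fraction Fraction of the mean used as the threshold (default 0.9).
#' @param ... Further arguments passed to methods (e.g. `window`).
#' @return Numeric threshold: a scalar, or a vector aligned to the series
#'   when a finite averaging window is used.
#' @export
setGeneric("pauseThreshold", function(x, fraction = 0.9, ...)
  standardGeneric("pauseThreshold"))

#' @rdname confusionAccessors
#' @export
setGeneric("tp", function(x) standardGeneric("tp"))
#' @rdname confusionAccessors
#' @export
setGeneric("fp", function(x) standardGeneric("fp"))
#' @rdname confusionAccessors
#' @export
setGeneric("fn", function(x) standardGeneric("fn"))

#' Event-level detection metrics
#'
#' Precision is the proportion of true positives among all predicted pauses,
#' recall the proportion among all annotated pauses, and the F1 score their
#' harmonic mean. When a denominator is zero the metric is reported as 0
#' with a warning, so batch evaluation over many videos never aborts.
#'
#' @param x A [ConfusionCounts-class].
#' @return Numeric scalar in \[0, 1\].
#' @examples
#' cc <- ConfusionCounts(tp = 55, fp = 19, fn = 19)
#' precision(cc)  # 0.743...
#' recall(cc)
#' f1Score(cc)
#' @name detectionMetrics
NULL

#' @rdname detectionMetrics
#' @export
setGeneric("precision", function(x) standardGeneric("precision"))
#' @rdname detectionMetrics
#' @export
setGeneric("recall", function(x) standardGeneric("recall"))
#' @rdname detectionMetrics
#' @export
setGeneric("f1Score", function(x) standardGeneric("f1Score"))
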