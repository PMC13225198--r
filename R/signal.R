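#' @rdname frameRate
#' @export
setMethod("frameRate", "FrameSignal", function(x) x@frameRate)

#' @rdname frameIndex
#' @export
setMethod("frameIndex", "FrameSignal", function(x) x@frame)

#' @rdname signalValues
#' @export
setMethod("signalValues", "FrameSignal", function(x) x@values)

#' @describeIn FrameSignal-class Number of samples in the signal.
#' @param x A `FrameSignal`.
#' @export
setMethod("length", "FrameSignal", function(x) length(x@values))

setMethod("show", "FrameSignal", function(object) {
  cat(sprintf("%s: %d samples @ %g fps", class(object), length(object@values),
              object@frameRate))
  if (length(object@values))
    cat(sprintf(", frames %d-%d, values [%.3g, %.3g]",
                min(object@frame), max(object@frame),
                min(object@values), max(object@values)))
  cat("\n")
})

#' Jaccard series of a track
#'
#' Computes the Jaccard (IoU) coefficient between the bounding boxes of
#' every pair of consecutive frames in a track. The entry with frame index
#' `k` compares the boxes at frames `k` and `k + 1`. Pairs separated by a
#' detection gap (frames not both present in the track) produce no entry:
#' interpolating boxes across a gap would fabricate motion evidence, so the
#' series simply splits into contiguous segments that downstream steps
#' analyse independently.
#'
#' @param x A [BirdTrack-class] with at least 2 detections.
#' @param ... Unused.
#' @return A [JaccardSeries-class] with one value per consecutive-frame pair.
#' @examples
#' d <- data.frame(frame = 0:2, x_min = c(0, 5, 5), y_min = 0,
#'                 x_max = c(10, 15, 15), y_max = 10)
#' jaccardSeries(BirdTrack(d, frameRate = 500))  # values 1/3, 1
#' @export
setMethod("jaccardSeries", "BirdTrack", function(x, ...) {
  d <- x@detections
  if (nrow(d) < 2)
    stop("insufficient data: a track needs >= 2 detections", call. = FALSE)
  b <- trackBoxes(x)
  consec <- which(diff(d$frame) == 1L)
  if (!length(consec))
    stop("insufficient data: no consecutive-frame detection pairs",
         call. = FALSE)
  new("JaccardSeries", frame = d$frame[consec],
      values = boxJaccard(b[consec, , drop = FALSE],
                          b[consec + 1L, , drop = FALSE]),
      frameRate = x@frameRate)
})

#' Forward finite difference of a Jaccard series
#'
#' The per-frame change `values[k + 1] - values[k]` between successive
#' samples of the series, in Jaccard units per frame (dimensionless, so it
#' is directly comparable with thresholds derived from the Jaccard scale).
#' Differences are only formed within contiguous segments of the series;
#' each difference is labelled with the frame index of its first sample.
#'
#' @param series A [JaccardSeries-class] with at least 2 samples.
#' @return A [DerivativeSeries-class].
#' @examples
#' d <- data.frame(frame = 0:3, x_min = 0, y_min = 0, x_max = 10, y_max = 10)
#' finiteDifference(jaccardSeries(BirdTrack(d, 500)))  # 0, 0
#' @export
finiteDifference <- function(series) {
  stopifnot(is(series, "JaccardSeries"))
  if (length(series@values) < 2)
    stop("insufficient data: need a series of length >= 2", call. = FALSE)
  ok <- which(diff(series@frame) == 1L)
  if (!length(ok))
    stop("insufficient data: no adjacent sample pairs in the series",
         call. = FALSE)
  new("DerivativeSeries", frame = series@frame[ok],
      values = series@values[ok + 1L] - series@values[ok],
      frameRate = series@frameRate)
}
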