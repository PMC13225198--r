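#' Construct a BirdTrack
#'
#' @param detections A data frame with columns `frame`, `x_min`, `y_min`,
#'   `x_max`, `y_max` and optionally `score` (default 1) and `label`
#'   (default `"hummingbird"`). Frames are 0-based and must be strictly
#'   increasing.
#' @param frameRate Frames per second of the recording.
#' @param trackId Integer identifier (default 1).
#' @return A [BirdTrack-class].
#' @examples
#' d <- data.frame(frame = 0:2, x_min = 0, y_min = 0, x_max = 10, y_max = 10)
#' BirdTrack(d, frameRate = 500)
#' @export
BirdTrack <- function(detections, frameRate, trackId = 1L) {
  detections <- as.data.frame(detections)
  if (is.null(detections$score)) detections$score <- 1
  if (is.null(detections$label)) detections$label <- "hummingbird"
  detections$frame <- as.integer(detections$frame)
  ord <- c("frame", "x_min", "y_min", "x_max", "y_max", "score", "label")
  detections <- detections[, ord]
  rownames(detections) <- NULL
  new("BirdTrack", trackId = as.integer(trackId), detections = detections,
      frameRate = as.numeric(frameRate))
}

#' @describeIn BirdTrack-class Number of detections in the track.
#' @param x A `BirdTrack`.
#' @export
setMethod("length", "BirdTrack", function(x) nrow(x@detections))

#' Detections accessor
#'
#' @param x A [BirdTrack-class].
#' @return The per-frame detection data frame.
#' @export
detections <- function(x) {
  stopifnot(is(x, "BirdTrack"))
  x@detections
}

#' Track identifier accessor
#'
#' @param x A [BirdTrack-class].
#' @return Integer track id.
#' @export
trackId <- function(x) {
  stopifnot(is(x, "BirdTrack"))
  x@trackId
}

#' Bounding boxes of a track
#'
#' @param x A [BirdTrack-class].
#' @return An `n x 4` box matrix (see [boundingBox()]).
#' @export
trackBoxes <- function(x) {
  stopifnot(is(x, "BirdTrack"))
  as.matrix(x@detections[, c("x_min", "y_min", "x_max", "y_max")])
}

#' @rdname frameRate
#' @export
setMethod("frameRate", "BirdTrack", function(x) x@frameRate)

#' @rdname frameIndex
#' @export
setMethod("frameIndex", "BirdTrack", function(x) x@detections$frame)

setMethod("show", "BirdTrack", function(object) {
  d <- object@detections
  cat(sprintf("BirdTrack #%d: %d detections", object@trackId, nrow(d)))
  if (nrow(d))
    cat(sprintf(", frames %d-%d", d$frame[1], d$frame[nrow(d)]))
  cat(sprintf(" @ %g fps\n", object@frameRate))
})
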