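#' Construct a FrameSequence
#'
#' @param frames A `height x width x n` numeric array of grayscale
#'   intensities in \[0, 1\], or a list of equally sized matrices.
#' @param frameRate Frames per second.
#' @param frame Integer 0-based frame indices (default `0:(n-1)`).
#' @return A [FrameSequence-class].
#' @export
FrameSequence <- function(frames, frameRate, frame = NULL) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
      stop("all frames must have identical dimensions", call. = FALSE)
    frames <- array(unlist(frames), dim = c(d, length(frames)))
  }
  if (is.null(frame)) frame <- seq_len(dim(frames)[3]) - 1L
  new("FrameSequence", frames = frames, frame = as.integer(frame),
      frameRate = as.numeric(frameRate))
}

#' @describeIn FrameSequence-class Number of frames.
#' @param x A `FrameSequence`.
#' @export
setMethod("length", "FrameSequence", function(x) dim(x@frames)[3])

#' @rdname frameRate
#' @export
setMethod("frameRate", "FrameSequence", function(x) x@frameRate)

#' @rdname frameIndex
#' @export
setMethod("frameIndex", "FrameSequence", function(x) x@frame)

#' Extract a single frame image
#'
#' @param x A [FrameSequence-class].
#' @param i Position (1-based) within the sequence.
#' @return Numeric matrix (height x width).
#' @export
getFrame <- function(x, i) {
  stopifnot(is(x, "FrameSequence"))
  x@frames[, , i]
}

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameSequence: %d frames of %d x %d px @ %g fps\n",
              d[3], d[2], d[1], object@frameRate))
})

#' Convert an RGB raster to grayscale
#'
#' Standard luma weights (0.299 R + 0.587 G + 0.114 B). Wing motion at
#' 500 fps is essentially a luminance phenomenon, and grayscale differencing
#' halves the work of the background subtractor.
#'
#' @param img A `height x width x 3` array, or a matrix (returned as is).
#' @return Numeric matrix.
#' @export
rgbToGray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3, dim(img)[3] >= 3)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Estimate a static background image
#'
#' Per-pixel median across frames. The median (rather than the mean) is
#' robust to the bird's transient presence at any one location, which
#' suppresses ghosting in the background estimate.
#'
#' @param frames A [FrameSequence-class] with at least 3 frames.
#' @return Numeric matrix of the same dimensions as one frame.
#' @export
estimateBackground <- function(frames) {
  stopifnot(is(frames, "FrameSequence"))
  n <- length(frames)
  if (n < 3) stop("insufficient data: need >= 3 frames", call. = FALSE)
  d <- dim(frames@frames)
  m <- matrix(aperm(frames@frames, c(3, 1, 2)), nrow = n)
  matrix(apply(m, 2, stats::median), nrow = d[1], ncol = d[2])
}

#' @rdname BackgroundModel-class
#' @param background Background image matrix (e.g. from
#'   [estimateBackground()]).
#' @param threshold Absolute intensity difference above which a pixel is
#'   foreground (intensity units; default 0.15).
#' @param minBlobArea Minimum connected-component pixel count kept as a
#'   detection (default 20 px^2, rejecting isolated noise pixels).
#' @return `BackgroundModel()` returns a validated model object.
#' @export
BackgroundModel <- function(background, threshold = 0.15, minBlobArea = 20) {
  new("BackgroundModel", background = background, threshold = threshold,
      minBlobArea = minBlobArea)
}

setMethod("show", "BackgroundModel", function(object) {
  cat(sprintf("BackgroundModel: %d x %d px background, threshold=%g, minBlobArea=%g\n",
              ncol(object@background), nrow(object@background),
              object@threshold, object@minBlobArea))
})

#' Detect foreground blobs in one frame
#'
#' Thresholds the absolute difference between a frame and the background,
#' extracts 8-connected components, discards components smaller than
#' `minBlobArea`, and returns the tight bounding box of each remaining
#' component with score 1. This is the reference implementation of the
#' pluggable detector interface (a stand-in a neural detector can replace,
#' see [frameDetector()]).
#'
#' @param frame Numeric matrix (grayscale) or RGB array, same dimensions as
#'   the model background.
#' @param model A [BackgroundModel-class].
#' @param frame_index 0-based frame index recorded in the output.
#' @param singleSubject If `TRUE`, keep only the largest-area component
#'   (each analysed video contains a single bird in flight).
#' @return Detection data frame (`frame`, `x_min`, `y_min`, `x_max`,
#'   `y_max`, `score`, `label`), 0 rows when nothing is found. Boxes use
#'   half-open pixel coordinates, so a blob covering pixel columns
#'   `51..70` (1-based) has `x_min = 50`, `x_max = 70`.
#' @export
detectForeground <- function(frame, model, frame_index = 0L,
                             singleSubject = FALSE) {
  stopifnot(is(model, "BackgroundModel"))
  frame <- rgbToGray(frame)
  if (!identical(dim(frame), dim(model@background)))
    stop("frame dimensions do not match the background", call. = FALSE)
  fg <- abs(frame - model@background) > model@threshold
  comp <- connectedComponents(fg)
  empty <- data.frame(frame = integer(), x_min = numeric(), y_min = numeric(),
                      x_max = numeric(), y_max = numeric(), score = numeric(),
                      label = character())
  if (!length(comp)) return(empty)
  comp <- comp[vapply(comp, length, integer(1)) >= model@minBlobArea]
  if (!length(comp)) return(empty)
  nr <- nrow(fg)
  boxes <- t(vapply(comp, function(idx) {
    row <- (idx - 1L) %% nr + 1L
    col <- (idx - 1L) %/% nr + 1L
    c(min(col) - 1, min(row) - 1, max(col), max(row))
  }, numeric(4)))
  if (singleSubject && nrow(boxes) > 1) {
    area <- (boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2])
    boxes <- boxes[which.max(area), , drop = FALSE]
  }
  data.frame(frame = as.integer(frame_index), x_min = boxes[, 1],
             y_min = boxes[, 2], x_max = boxes[, 3], y_max = boxes[, 4],
             score = 1, label = "foreground")
}

## 8-connected components of a logical matrix. Foreground pixels become
## vertices of an adjacency graph (edges to the 4 forward neighbours:
## right, down, down-right, down-left); components come from igraph.
## Returns a list of linear-index vectors, one per component.
connectedComponents <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  nr <- nrow(mask); nc <- ncol(mask)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + off[1]; c2 <- col + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[nb]
    if (any(hit)) {
      a <- match(idx[ok][hit], idx)
      b <- match(nb[hit], idx)
      edges <- c(edges, rbind(a, b))
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  split(idx, memb)
}

#' Pluggable per-frame detectors
#'
#' A *detector* is any function `f(frame, frame_index)` returning a
#' detection data frame in frame pixel coordinates (the contract satisfied
#' by [detectForeground()]). `frameDetector()` wraps a
#' [BackgroundModel-class] into that shape; an adapter around an external
#' neural detector can be supplied anywhere a detector is accepted.
#'
#' @param model A [BackgroundModel-class].
#' @param singleSubject Passed to [detectForeground()].
#' @return A function `(frame, frame_index) -> detection data frame`.
#' @seealso [detectAllFrames()]
#' @export
frameDetector <- function(model, singleSubject = TRUE) {
  function(frame, frame_index) {
    detectForeground(frame, model, frame_index = frame_index,
                     singleSubject = singleSubject)
  }
}

#' Run a detector over a frame sequence
#'
#' @param frames A [FrameSequence-class].
#' @param detector A detector function (see [frameDetector()]); by default a
#'   background model is estimated from the sequence itself.
#' @return A detection data frame covering all frames.
#' @export
detectAllFrames <- function(frames, detector = NULL) {
  stopifnot(is(frames, "FrameSequence"))
  if (is.null(detector))
    detector <- frameDetector(BackgroundModel(estimateBackground(frames)))
  out <- lapply(seq_len(length(frames)), function(i)
    detector(getFrame(frames, i), frames@frame[i]))
  do.call(rbind, out)
}
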