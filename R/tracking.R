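#' @rdname TrackerParam-class
#' @param minIoU,maxMissedFrames,useAppearance,appearanceWeight See the
#'   class slots.
#' @return `TrackerParam()` returns a validated parameter object.
#' @export
TrackerParam <- function(minIoU = 0.1, maxMissedFrames = 5L,
                         useAppearance = FALSE, appearanceWeight = 0.5) {
  new("TrackerParam", minIoU = minIoU,
      maxMissedFrames = as.integer(maxMissedFrames),
      useAppearance = useAppearance, appearanceWeight = appearanceWeight)
}

setMethod("show", "TrackerParam", function(object) {
  cat(sprintf("TrackerParam: minIoU=%g, maxMissedFrames=%d, appearance=%s (w=%g)\n",
              object@minIoU, object@maxMissedFrames,
              if (object@useAppearance) "on" else "off",
              object@appearanceWeight))
})

newTrackerState <- function(param = TrackerParam()) {
  list(param = param, active = list(), closed = list(), nextId = 1L)
}

cosineSim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Associate one frame of detections with active tracks
#'
#' Greedy association by descending score: pairs of (active track, new
#' detection) are ranked by the IoU between the detection and the track's
#' last box — optionally blended with an appearance cosine similarity as
#' `w * cos + (1 - w) * IoU` — and matched one-to-one in rank order. Pairs
#' scoring below `minIoU` are never matched. Unmatched detections open new
#' tracks; tracks unmatched for more than `maxMissedFrames` frames are
#' closed. With at most one or two birds per scene, greedy matching is
#' deterministic, easy to verify, and equivalent in practice to optimal
#' assignment.
#'
#' @param state A tracker state, initially from `trackDetections()`'s
#'   internals or a previous `associateDetections()` call (a list with
#'   elements `param`, `active`, `closed`, `nextId`).
#' @param dets Detection data frame, all rows from one frame index strictly
#'   later than every active track's last frame.
#' @param features Optional numeric matrix of appearance features, one row
#'   per detection row (the hook where an external embedder plugs in).
#' @return The updated state.
#' @export
associateDetections <- function(state, dets, features = NULL) {
  param <- state$param
  if (nrow(dets)) {
    f <- unique(dets$frame)
    if (length(f) != 1L)
      stop("detections must all come from a single frame", call. = FALSE)
    last <- vapply(state$active, function(tr) tr$lastFrame, numeric(1))
    if (length(last) && any(last >= f))
      stop("out-of-order frame index: detections must be strictly later ",
           "than every active track", call. = FALSE)
  } else {
    return(state)
  }
  ## tracks whose gap already exceeds the tolerance are closed before
  ## matching: a reappearance after maxMissedFrames starts a new identity
  f <- dets$frame[1]
  stale <- vapply(state$active, function(tr)
    f - tr$lastFrame - 1L > param@maxMissedFrames, logical(1))
  state$closed <- c(state$closed, state$active[stale])
  state$active <- state$active[!stale]
  nA <- length(state$active); nD <- nrow(dets)
  detBoxes <- as.matrix(dets[, c("x_min", "y_min", "x_max", "y_max")])
  matchedDet <- rep(FALSE, nD)
  matchedTrk <- rep(FALSE, nA)
  if (nA && nD) {
    score <- matrix(0, nA, nD)
    for (i in seq_len(nA)) {
      tr <- state$active[[i]]
      iou <- boxJaccard(matrix(tr$lastBox, nrow = nD, ncol = 4, byrow = TRUE),
                        detBoxes)
      if (param@useAppearance && !is.null(features) && !is.null(tr$lastFeature)) {
        cs <- apply(features, 1, cosineSim, a = tr$lastFeature)
        score[i, ] <- param@appearanceWeight * cs +
          (1 - param@appearanceWeight) * iou
      } else score[i, ] <- iou
    }
    ord <- order(score, decreasing = TRUE)
    for (k in ord) {
      if (score[k] < param@minIoU) break
      i <- (k - 1L) %% nA + 1L
      j <- (k - 1L) %/% nA + 1L
      if (matchedTrk[i] || matchedDet[j]) next
      matchedTrk[i] <- TRUE; matchedDet[j] <- TRUE
      tr <- state$active[[i]]
      tr$rows[[length(tr$rows) + 1L]] <- dets[j, ]
      tr$lastBox <- detBoxes[j, ]
      tr$lastFrame <- dets$frame[j]
      if (!is.null(features)) tr$lastFeature <- features[j, ]
      state$active[[i]] <- tr
    }
  }
  for (j in which(!matchedDet)) {
    state$active[[length(state$active) + 1L]] <- list(
      id = state$nextId, rows = list(dets[j, ]), lastBox = detBoxes[j, ],
      lastFrame = dets$frame[j],
      lastFeature = if (!is.null(features)) features[j, ] else NULL)
    state$nextId <- state$nextId + 1L
  }
  keep <- logical(length(state$active))
  for (i in seq_along(state$active)) {
    missed <- dets$frame[1] - state$active[[i]]$lastFrame
    if (missed > param@maxMissedFrames) {
      state$closed[[length(state$closed) + 1L]] <- state$active[[i]]
    } else keep[i] <- TRUE
  }
  state$active <- state$active[keep]
  state
}

#' Build tracks from per-frame detections
#'
#' Processes detections frame by frame through [associateDetections()] and
#' returns the finished tracks.
#'
#' @param dets Detection data frame (columns `frame`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, `score`, optionally `label`) covering any number of
#'   frames.
#' @param frameRate Frames per second.
#' @param param A [TrackerParam-class].
#' @param features Optional appearance-feature matrix, one row per row of
#'   `dets`.
#' @return A list of [BirdTrack-class] objects, ordered by track id.
#' @examples
#' sc <- generateBoxSequence(SceneParam(durationS = 0.2))
#' tracks <- trackDetections(detections(sceneTrack(sc)), frameRate = 500)
#' length(tracks)  # 1
#' @export
trackDetections <- function(dets, frameRate, param = TrackerParam(),
                            features = NULL) {
  state <- newTrackerState(param)
  for (f in sort(unique(dets$frame))) {
    sel <- dets$frame == f
    state <- associateDetections(state, dets[sel, , drop = FALSE],
                                 features = if (!is.null(features))
                                   features[sel, , drop = FALSE])
  }
  raw <- c(state$closed, state$active)
  raw <- raw[order(vapply(raw, function(tr) tr$id, integer(1)))]
  lapply(raw, function(tr)
    BirdTrack(do.call(rbind, tr$rows), frameRate = frameRate,
              trackId = tr$id))
}

#' Select the primary (analysis) track
#'
#' The flying bird of interest is the track covering the most frames; ties
#' break by larger mean box area, then by lower track id. Perched birds at
#' a feeder form short or small secondary tracks and are excluded this way.
#'
#' @param tracks A non-empty list of [BirdTrack-class] objects.
#' @return A single [BirdTrack-class].
#' @export
selectPrimaryTrack <- function(tracks) {
  if (!length(tracks)) stop("no subject: no tracks to select", call. = FALSE)
  nFrames <- vapply(tracks, length, integer(1))
  meanArea <- vapply(tracks, function(tr) mean(boxArea(trackBoxes(tr))),
                     numeric(1))
  ids <- vapply(tracks, trackId, integer(1))
  tracks[[order(-nFrames, -meanArea, ids)[1]]]
}
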